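## The universal genetic code, taken from Biostrings::GENETIC_CODE, plus the
## per-amino-acid codon multiplicities used to normalise composition vectors.

.CTD_HEPTAD <- "YSPTSPS"

#' The universal genetic code and codon multiplicities
#'
#' \code{geneticCode()} returns the 64-entry codon -> amino-acid map (DNA
#' codons; stop = \code{"*"}). \code{codonMultiplicity()} returns, for each
#' of the 20 standard amino acids, the number of sense codons encoding it
#' (e.g. L/S/R = 6, M/W = 1); the multiplicities sum to 61. These
#' multiplicities divide out the genetic code's redundancy when amino-acid
#' compositions of translated nucleotide sequences are compared
#' (see [codonNormalize()]).
#'
#' @return \code{geneticCode()}: named character vector of length 64.
#'   \code{codonMultiplicity()}: named integer vector of length 20 (names in
#'   alphabetical amino-acid order). \code{senseCodons()}: the 61 non-stop
#'   codons.
#' @examples
#' codonMultiplicity()[c("L", "M", "Y")]
#' sum(codonMultiplicity())  # 61
#' @export
geneticCode <- function() {
    Biostrings::GENETIC_CODE
}

#' @rdname geneticCode
#' @export
codonMultiplicity <- function() {
    gc <- geneticCode()
    tab <- table(gc[gc != "*"])
    m <- setNames(as.integer(tab[.AA20]), .AA20)
    stopifnot(sum(m) == 61L)
    m
}

#' @rdname geneticCode
#' @export
senseCodons <- function() {
    gc <- geneticCode()
    names(gc)[gc != "*"]
}

#' Pol II CTD consensus heptad
#'
#' The carboxy-terminal domain of the Pol II largest subunit (RPB1) is a
#' tandem array of the heptapeptide YSPTSPS. \code{ctdHeptad()} returns one
#' unit, \code{ctdRepeat(n)} an n-unit tandem array as an \code{AAString}.
#'
#' @param n number of heptad repeats.
#' @examples
#' ctdHeptad()
#' ctdRepeat(4)
#' @export
ctdHeptad <- function() .CTD_HEPTAD

#' @rdname ctdHeptad
#' @export
ctdRepeat <- function(n) {
    stopifnot(n >= 1)
    Biostrings::AAString(strrep(.CTD_HEPTAD, n))
}

## codon index (1..64) of a base triplet coded A=1, C=2, G=3, T=4, matching
## the row order of sort(names(GENETIC_CODE))
.codonIndex <- function(b1, b2, b3) 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3

## lookup: codon index -> amino-acid index 1..20 (alphabetical) or 21 (stop)
.aaLookup <- local({
    built <- NULL
    function() {
        if (is.null(built)) {
            gc <- geneticCode()
            codons <- sort(names(gc))  # ACGT order == .codonIndex order
            aa <- gc[codons]
            built <<- ifelse(aa == "*", 21L, match(aa, .AA20))
        }
        built
    }
})
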