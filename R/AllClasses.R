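## Central S4 classes. Sequence collections themselves live in Biostrings
## containers (DNAStringSet / AAStringSet) and repeat annotations in GRanges;
## the classes here hold derived results.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid frequency distribution
#'
#' A normalised frequency vector over the 20 standard amino acids, the unit
#' of comparison for the composition bias test. Entries are non-negative and
#' sum to one; names are the one-letter codes in alphabetical order.
#'
#' @slot .Data numeric vector of length 20.
#' @seealso [aaFrequencies()], [codonNormalize()], [jsDivergence()]
#' @export
setClass("AAFreqDist", contains = "numeric", validity = function(object) {
    v <- object@.Data
    if (length(v) != 20L)
        return("must have exactly 20 entries (standard amino acids)")
    if (!identical(names(object), .AA20))
        return("names must be the 20 standard amino acids in alphabetical order")
    if (any(v < 0))
        return("frequencies must be non-negative")
    if (abs(sum(v) - 1) > 1e-9)
        return("frequencies must sum to 1 (within 1e-9)")
    TRUE
})

#' Construct an amino-acid frequency distribution
#'
#' @param x named numeric vector of counts or frequencies; names must be
#'   standard one-letter amino-acid codes (any subset; missing ones get 0).
#' @return An [AAFreqDist-class] object (normalised to sum 1).
#' @examples
#' AAFreqDist(c(Y = 1, S = 3, P = 2, T = 1))
#' @export
AAFreqDist <- function(x) {
    if (is.null(names(x)))
        stop("'x' must be a named vector of amino-acid counts/frequencies")
    bad <- setdiff(names(x), .AA20)
    if (length(bad))
        stop("unknown amino-acid letters: ", paste(bad, collapse = ", "))
    v <- setNames(numeric(20L), .AA20)
    v[names(x)] <- v[names(x)] + as.numeric(x)
    tot <- sum(v)
    if (tot <= 0) stop("empty composition: no positive amino-acid mass")
    new("AAFreqDist", v / tot)
}

## bare named frequency vector of an AAFreqDist
.freqVec <- function(x) setNames(as.numeric(x@.Data), .AA20)

setMethod("show", "AAFreqDist", function(object) {
    cat("AAFreqDist (20 standard amino acids, sums to 1)\n")
    v <- sort(.freqVec(object), decreasing = TRUE)
    top <- v[v > 0][seq_len(min(6L, sum(v > 0)))]
    cat("  top:", paste(sprintf("%s=%.4f", names(top), top), collapse = " "), "\n")
})

#' Background nucleotide model
#'
#' Mononucleotide frequencies of the sequence background against which
#' enrichment and composition statistics are judged. The default mirrors the
#' approximate A/C/G/T composition of the human genome (GC ~ 41%).
#'
#' @param freqs numeric vector of 4 non-negative frequencies in A, C, G, T
#'   order (names optional); normalised to sum 1.
#' @param source free-text provenance label.
#' @return Named numeric vector of class \code{backgroundModel} with a
#'   \code{source} attribute.
#' @examples
#' humanBackground()
#' backgroundModel(c(0.25, 0.25, 0.25, 0.25), source = "uniform")
#' @export
backgroundModel <- function(freqs, source = "") {
    freqs <- as.numeric(freqs)
    if (length(freqs) != 4L || any(freqs < 0) || sum(freqs) <= 0)
        stop("'freqs' must be 4 non-negative values (A, C, G, T)")
    v <- freqs / sum(freqs)
    names(v) <- c("A", "C", "G", "T")
    attr(v, "source") <- source
    class(v) <- "backgroundModel"
    v
}

#' @rdname backgroundModel
#' @export
humanBackground <- function() {
    backgroundModel(c(0.295, 0.205, 0.205, 0.295),
                    source = "human genome mononucleotide background")
}

#' @export
print.backgroundModel <- function(x, ...) {
    cat("backgroundModel:",
        paste(sprintf("%s=%.3f", names(x), unclass(x)), collapse = " "),
        "\n  source:", attr(x, "source"), "\n")
    invisible(x)
}

#' Pairwise alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties for global protein
#' alignment. The default reproduces the published comparison: BLOSUM62 with
#' gap opening 12 and gap extension 2 under the lalign/FASTA convention in
#' which a gap of length L costs \code{gapOpen + L * gapExtend}. The
#' alternative dialect \code{"open-plus-size-minus-one"} charges
#' \code{gapOpen + (L - 1) * gapExtend}.
#'
#' @slot matrix symmetric integer substitution matrix over the 20 standard
#'   amino acids.
#' @slot gapOpen,gapExtend non-negative gap penalties (entered as positive
#'   numbers, subtracted from the score).
#' @slot gapDialect \code{"open-plus-size"} (default) or
#'   \code{"open-plus-size-minus-one"}.
#' @slot endGaps logical; \code{TRUE} (default) penalises terminal gaps
#'   (strict global alignment), \code{FALSE} gives semiglobal alignment.
#' @export
setClass("ScoringScheme",
    representation(matrix = "matrix", gapOpen = "numeric",
                   gapExtend = "numeric", gapDialect = "character",
                   endGaps = "logical"),
    validity = function(object) {
        m <- object@matrix
        if (!all(.AA20 %in% rownames(m)) || !all(.AA20 %in% colnames(m)))
            return("substitution matrix must cover the 20 standard amino acids")
        mm <- m[.AA20, .AA20]
        if (!isTRUE(all.equal(mm, t(mm))))
            return("substitution matrix must be symmetric")
        if (object@gapOpen < object@gapExtend || object@gapExtend < 0)
            return("need gapOpen >= gapExtend >= 0")
        if (!object@gapDialect %in% c("open-plus-size", "open-plus-size-minus-one"))
            return("unknown gapDialect")
        TRUE
    })

#' @param matrix substitution matrix (default: packaged BLOSUM62).
#' @param gapOpen,gapExtend positive gap penalties (defaults 12 and 2).
#' @param gapDialect,endGaps see slots.
#' @return A [ScoringScheme-class] object.
#' @rdname ScoringScheme-class
#' @examples
#' scoringScheme()
#' @export
scoringScheme <- function(matrix = blosum62(), gapOpen = 12, gapExtend = 2,
                          gapDialect = c("open-plus-size",
                                         "open-plus-size-minus-one"),
                          endGaps = TRUE) {
    new("ScoringScheme", matrix = matrix, gapOpen = gapOpen,
        gapExtend = gapExtend, gapDialect = match.arg(gapDialect),
        endGaps = endGaps)
}

setMethod("show", "ScoringScheme", function(object) {
    cat("ScoringScheme: ", nrow(object@matrix), "x", ncol(object@matrix),
        " matrix, gapOpen=", object@gapOpen, ", gapExtend=", object@gapExtend,
        " (", object@gapDialect, "), endGaps=", object@endGaps, "\n", sep = "")
})

#' Result of a global pairwise alignment
#'
#' @slot alignedA,alignedB equal-length gapped strings (gap = \code{"-"}).
#' @slot score alignment score.
#' @slot identities number of columns with identical residues.
#' @slot alignedLength number of alignment columns.
#' @seealso [needlemanWunsch()], [countIdentities()]
#' @export
setClass("AlignmentResult",
    representation(alignedA = "character", alignedB = "character",
                   score = "numeric", identities = "integer",
                   alignedLength = "integer"),
    validity = function(object) {
        if (nchar(object@alignedA) != nchar(object@alignedB))
            return("aligned strings must have equal length")
        if (nchar(object@alignedA) != object@alignedLength)
            return("alignedLength inconsistent with aligned strings")
        TRUE
    })

setMethod("show", "AlignmentResult", function(object) {
    cat("AlignmentResult: score=", object@score,
        ", identities=", object@identities, "/", object@alignedLength,
        "\n  ", object@alignedA, "\n  ", object@alignedB, "\n", sep = "")
})

#' @param x an \code{AlignmentResult}.
#' @describeIn AlignmentResult-class alignment score.
#' @export
alignmentScore <- function(x) x@score

#' @describeIn AlignmentResult-class the two gapped strings as a character
#'   vector of length 2.
#' @export
alignedSeqs <- function(x) c(a = x@alignedA, b = x@alignedB)

#' Monte-Carlo null distribution of divergence values
#'
#' @slot samples JSD values of the null replicates.
#' @slot nSets number of replicates.
#' @slot seed RNG seed used.
#' @slot mean,sd summary statistics of \code{samples}.
#' @seealso [sampleNull()]
#' @export
setClass("NullDistribution",
    representation(samples = "numeric", nSets = "integer", seed = "integer",
                   mean = "numeric", sd = "numeric"),
    validity = function(object) {
        if (length(object@samples) != object@nSets)
            return("length(samples) must equal nSets")
        if (any(object@samples < 0 | object@samples > 1))
            return("JSD samples must lie in [0, 1]")
        if (object@sd < 0) return("sd must be >= 0")
        TRUE
    })

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution: n=", object@nSets, ", mean=",
        signif(object@mean, 5), ", sd=", signif(object@sd, 5),
        ", seed=", object@seed, "\n", sep = "")
})

#' Composition bias test result
#'
#' Output of [biasTest()]: the observed codon-normalised Jensen-Shannon
#' divergence to the reference composition, its standardised distance from
#' the Monte-Carlo null, and lower-tail p-values (low divergence = reference-
#' like composition = the enrichment signal).
#'
#' @slot observedJSD observed divergence.
#' @slot z (observed - null mean) / null sd; \code{NA} when sd = 0.
#' @slot pEmpirical (m + 1) / (n + 1) with m = number of null samples <=
#'   observed.
#' @slot pGaussian lower-tail normal probability at z.
#' @slot null the [NullDistribution-class] used.
#' @export
setClass("BiasTestResult",
    representation(observedJSD = "numeric", z = "numeric",
                   pEmpirical = "numeric", pGaussian = "numeric",
                   null = "NullDistribution"),
    validity = function(object) {
        if (object@pEmpirical < 0 || object@pEmpirical > 1)
            return("pEmpirical must lie in [0, 1]")
        TRUE
    })

setMethod("show", "BiasTestResult", function(object) {
    cat("BiasTestResult\n",
        "  observed JSD : ", signif(object@observedJSD, 6), "\n",
        "  null mean/sd : ", signif(object@null@mean, 6), " / ",
        signif(object@null@sd, 6), " (n=", object@null@nSets, ")\n",
        "  z            : ", signif(object@z, 6), "\n",
        "  p empirical  : ", signif(object@pEmpirical, 6), "\n",
        "  p Gaussian   : ", format(object@pGaussian, digits = 4), "\n",
        sep = "")
})

#' Simulation configuration for the synthetic SELEX experiment
#'
#' @slot genomeLength background genome size in bp.
#' @slot bg background mononucleotide model ([backgroundModel()]).
#' @slot families list of repeat-family descriptions ([repeatFamily()]).
#' @slot readCount number of selected reads to draw.
#' @slot readLengthRange inclusive read-length range in nt (default 30-400,
#'   the insert range of the transcript library).
#' @slot noise per-base substitution probability applied to planted repeat
#'   copies and sampled reads.
#' @slot seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @seealso [simConfig()], [buildGenome()], [sampleReads()]
#' @export
setClass("SimConfig",
    representation(genomeLength = "integer", bg = "numeric",
                   families = "list", readCount = "integer",
                   readLengthRange = "integer", noise = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (object@genomeLength < 1L) return("genomeLength must be positive")
        if (length(object@readLengthRange) != 2L ||
            object@readLengthRange[1L] < 1L ||
            object@readLengthRange[2L] > object@genomeLength ||
            object@readLengthRange[1L] > object@readLengthRange[2L])
            return("readLengthRange must be within [1, genomeLength]")
        if (object@noise < 0 || object@noise > 1)
            return("noise must be a probability")
        tot <- sum(vapply(object@families, function(f)
            f$unitLength * f$copies, numeric(1)))
        if (tot > object@genomeLength)
            return("planted copies do not fit in the genome")
        if (any(vapply(object@families, function(f) f$weight, numeric(1)) < 0))
            return("affinity weights must be >= 0")
        TRUE
    })

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: genome ", object@genomeLength, " bp, ",
        length(object@families), " famil",
        if (length(object@families) == 1L) "y" else "ies",
        ", ", object@readCount, " reads (",
        object@readLengthRange[1], "-", object@readLengthRange[2],
        " nt), noise=", object@noise, ", seed=", object@seed, "\n", sep = "")
    for (f in object@families)
        cat("  - ", f$name, ": ", f$copies, " x ", f$unitLength, " bp, ",
            f$builder, ", strand=", f$strand, ", weight=", f$weight,
            "\n", sep = "")
})

#' Ground truth emitted by the simulator
#'
#' @slot annotation [GenomicRanges::GRanges] of planted repeat copies with a
#'   \code{family} metadata column.
#' @slot affinityMap named numeric: per-family selection weight (background
#'   weight is 1).
#' @slot unitSeqs consensus unit of each family (pre-noise) as a
#'   \code{DNAStringSet}.
#' @slot config the generating [SimConfig-class].
#' @export
setClass("GroundTruth",
    representation(annotation = "GRanges", affinityMap = "numeric",
                   unitSeqs = "DNAStringSet", config = "SimConfig"))

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth: ", length(object@annotation), " planted copies, ",
        length(object@affinityMap), " famil",
        if (length(object@affinityMap) == 1L) "y" else "ies",
        " (weights: ",
        paste(sprintf("%s=%g", names(object@affinityMap), object@affinityMap),
              collapse = ", "),
        ")\n", sep = "")
})
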