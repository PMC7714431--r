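## Sequence ingestion, frame-wise translation, density profiles, and the
## FASTA/BED/TSV I/O shared by all stages. Heavy lifting is delegated to
## Biostrings and rtracklayer; these wrappers pin down the package's
## conventions (DNA-internal alphabet, U -> T on ingest, N-codon handling,
## 0-based half-open coordinates on disk).

#' Ingest nucleotide sequences
#'
#' Normalises input into the package's internal representation: a named
#' \code{DNAStringSet} over \{A, C, G, T, N\}. RNA input is accepted and
#' \code{U} is mapped to \code{T} (the selected molecules are RNA but the
#' library and genome are handled as DNA). Lower case is raised; any other
#' letter is an error.
#'
#' @param x character vector, \code{DNAStringSet}, or \code{RNAStringSet};
#'   names become sequence ids (generated as \code{seq1, seq2, ...} when
#'   absent) and must be unique.
#' @return A named \code{DNAStringSet}.
#' @examples
#' ingestDNA(c(rap1 = "caucgu", rap2 = "ACGTN"))
#' @export
ingestDNA <- function(x) {
    if (is(x, "RNAStringSet") || is(x, "DNAStringSet"))
        x <- as.character(x)
    if (is(x, "XString")) x <- as.character(x)
    if (!is.character(x)) stop("'x' must be sequences or a character vector")
    s <- chartr("u", "t", toupper(x))
    s <- chartr("U", "T", s)
    if (any(nchar(s) == 0L)) stop("empty sequence after ingest")
    bad <- grepl("[^ACGTN]", s)
    if (any(bad))
        stop("invalid characters (alphabet is A/C/G/T/N, U allowed on input) in: ",
             paste(which(bad), collapse = ", "))
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    if (anyDuplicated(names(s))) stop("sequence ids must be unique")
    DNAStringSet(s)
}

#' Translate in a fixed reading frame
#'
#' Translates each sequence with the universal genetic code starting at
#' offset \code{frame} (0, 1 or 2) on the given strand; the trailing partial
#' codon is dropped. Stop codons are emitted as \code{"*"}; codons containing
#' \code{N} are emitted as \code{"X"} and reported via a warning tally. Both
#' are excluded downstream from every composition vector.
#'
#' @param x sequences acceptable to [ingestDNA()].
#' @param frame integer offset in \{0, 1, 2\}.
#' @return An \code{AAStringSet}.
#' @examples
#' as.character(translateFrame("TATTCTCCTACTTCTCCTTCT", 0))  # "YSPTSPS"
#' as.character(translateFrame("AATG", 1))                   # "M"
#' @export
translateFrame <- function(x, frame = 0L) {
    x <- ingestDNA(x)
    frame <- as.integer(frame)
    stopifnot(length(frame) == 1L, frame %in% 0:2)
    L <- width(x)
    if (any(L - frame < 3L))
        stop("sequence(s) too short for frame ", frame,
             ": ", paste(names(x)[L - frame < 3L], collapse = ", "))
    ncod <- (L - frame) %/% 3L
    sub <- subseq(x, start = frame + 1L, end = frame + 3L * ncod)
    p <- suppressWarnings(translate(sub, if.fuzzy.codon = "X"))
    nx <- sum(Biostrings::letterFrequency(p, "X"))
    if (nx > 0L)
        warning(nx, " codon(s) containing N translated as 'X' and excluded ",
                "from composition statistics")
    p
}

#' Translate all three 5'->3' reading frames
#'
#' Returns translations at frames 0, 1 and 2 of the given strand only: no
#' reverse complement is taken, because frames are read 5'->3' on the
#' selected RNA itself.
#'
#' @inheritParams translateFrame
#' @return A list of 3 \code{AAStringSet} objects named \code{frame0},
#'   \code{frame1}, \code{frame2}.
#' @examples
#' lapply(translateThreeFrames("TATTCTC"), as.character)
#' @export
translateThreeFrames <- function(x) {
    x <- ingestDNA(x)
    if (any(width(x) < 5L))
        stop("too short for three frames: ",
             paste(names(x)[width(x) < 5L], collapse = ", "))
    out <- lapply(0:2, function(f) translateFrame(x, f))
    names(out) <- paste0("frame", 0:2)
    out
}

#' Sliding-window nucleobase density profile
#'
#' Fraction of a given base in every window of fixed width, one value per
#' window start. Used to compare the base-density landscape of a repeat unit
#' with that of the CTD mRNA (satellite units that bind Pol II show an
#' adenine-density profile inverse to the CTD message).
#'
#' @param x a single sequence (character or \code{DNAString(Set)}).
#' @param base one of \code{"A"}, \code{"C"}, \code{"G"}, \code{"T"}.
#' @param window window width in nt (1 <= window <= sequence length).
#' @return Numeric vector of length \code{len - window + 1}, values in
#'   \[0, 1\].
#' @examples
#' baseDensityProfile("ACGT", "A", 4)  # 0.25
#' @export
baseDensityProfile <- function(x, base = c("A", "C", "G", "T"), window) {
    base <- match.arg(base)
    x <- ingestDNA(x)
    if (length(x) != 1L) stop("'x' must be a single sequence")
    s <- strsplit(as.character(x[[1L]]), "", fixed = TRUE)[[1L]]
    L <- length(s)
    window <- as.integer(window)
    if (window < 1L || window > L)
        stop("'window' must be in [1, sequence length]")
    ind <- cumsum(c(0L, as.integer(s == base)))
    (ind[(window + 1L):(L + 1L)] - ind[1:(L - window + 1L)]) / window
}

## ---------------------------------------------------------------- I/O ----

#' FASTA input and output
#'
#' Thin wrappers around Biostrings readers/writers fixing the package
#' conventions: DNA is passed through [ingestDNA()] (U -> T, alphabet check,
#' unique ids), and FASTA is written wrapped at 60 columns. Round trips are
#' lossless for id and sequence.
#'
#' @param path file path.
#' @param x a \code{DNAStringSet} or \code{AAStringSet} (or character input
#'   acceptable to [ingestDNA()] for DNA).
#' @return \code{readDnaFasta}: a named \code{DNAStringSet};
#'   \code{readProteinFasta}: a named \code{AAStringSet}.
#' @export
readDnaFasta <- function(path) {
    if (file.size(path) %in% c(0L, NA))
        return(DNAStringSet())
    ingestDNA(readDNAStringSet(path))
}

#' @rdname readDnaFasta
#' @export
readProteinFasta <- function(path) {
    if (file.size(path) %in% c(0L, NA))
        return(AAStringSet())
    readAAStringSet(path)
}

#' @rdname readDnaFasta
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- ingestDNA(x)
    writeXStringSet(x, path, width = 60L)
    invisible(path)
}

#' Repeat annotations as BED6
#'
#' Repeat-family annotations travel as BED6: 0-based half-open intervals
#' with the family label in the name column and the strand in column 6
#' (in-memory they are \code{GRanges}, 1-based closed, with a \code{family}
#' metadata column). Intervals of one family may not overlap each other on
#' the same strand.
#'
#' @param path BED file path.
#' @param gr a \code{GRanges} with a \code{family} (or \code{name}) metadata
#'   column.
#' @return \code{readRepeatBed}: a \code{GRanges} with \code{family} in
#'   \code{mcols}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 147),
#'                              strand = "+", family = "ACRO1")
#' f <- tempfile(fileext = ".bed")
#' writeRepeatBed(gr, f)
#' readRepeatBed(f)
#' @export
readRepeatBed <- function(path) {
    if (file.size(path) %in% c(0L, NA)) {
        gr <- GRanges()
        mcols(gr)$family <- character(0)
        return(gr)
    }
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("malformed BED file '", path,
                                            "': ", conditionMessage(e)))
    fam <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
        rep(NA_character_, length(gr))
    mcols(gr) <- NULL
    mcols(gr)$family <- fam
    .checkFamilyOverlap(gr)
    gr
}

#' @rdname readRepeatBed
#' @export
writeRepeatBed <- function(gr, path) {
    stopifnot(is(gr, "GRanges"))
    fam <- mcols(gr)$family
    if (is.null(fam)) fam <- mcols(gr)$name
    if (is.null(fam)) stop("'gr' needs a 'family' metadata column")
    .checkFamilyOverlap(gr)
    out <- gr
    mcols(out) <- NULL
    mcols(out)$name <- fam
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

.checkFamilyOverlap <- function(gr) {
    fam <- mcols(gr)$family
    for (f in unique(fam)) {
        sub <- gr[fam %in% f]
        hits <- findOverlaps(sub, sub, ignore.strand = FALSE)
        if (any(queryHits(hits) != subjectHits(hits)))
            stop("intervals of family '", f,
                 "' overlap on the same strand")
    }
    invisible(TRUE)
}

#' Write a table with fixed numeric formatting
#'
#' Tab-separated with a header line; numeric columns rendered with 6
#' significant digits so that identical runs produce byte-identical files.
#'
#' @param df a data.frame.
#' @param path output path.
#' @export
writeTsv <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- formatC(signif(out[[j]], 6L),
                                                     format = "g", digits = 6L)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
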