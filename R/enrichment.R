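## Strand-aware assignment of selected reads to repeat families, fold
## enrichment normalised to genomic abundance, 400-nt contig stacks, and the
## CA-richness statistic.

## placements are GRanges (1-based closed) with read ids as names; on disk
## they are 6-column TSVs with 0-based half-open coordinates:
## read_id  chrom  start  end  strand  family-or-.

#' Read placements as a 6-column TSV
#'
#' @param path TSV path (columns read_id, chrom, start, end, strand,
#'   family; start/end 0-based half-open; family "." when unknown).
#' @param gr placements as a named \code{GRanges} (optional \code{family}
#'   metadata column).
#' @return \code{readPlacements}: a named \code{GRanges} with a
#'   \code{family} metadata column.
#' @export
readPlacements <- function(path) {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("read_id", "chrom", "start", "end", "strand", "family")
    if (!all(need %in% names(df)))
        stop("placement table must have columns: ",
             paste(need, collapse = ", "))
    if (any(df$start >= df$end))
        stop("placement with start >= end at line ",
             which(df$start >= df$end)[1L] + 1L)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = df$strand)
    names(gr) <- df$read_id
    mcols(gr)$family <- df$family
    gr
}

#' @rdname readPlacements
#' @export
writePlacements <- function(gr, path) {
    stopifnot(is(gr, "GRanges"))
    fam <- mcols(gr)$family
    if (is.null(fam)) fam <- rep(".", length(gr))
    df <- data.frame(read_id = if (is.null(names(gr)))
                         paste0("read", seq_along(gr)) else names(gr),
                     chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     strand = as.character(strand(gr)),
                     family = fam, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.midpoints <- function(gr) {
    ## 0-based midpoint floor((start0 + end0)/2), returned 1-based
    mid0 <- (start(gr) - 1L + end(gr)) %/% 2L
    GRanges(seqnames(gr), IRanges(mid0 + 1L, mid0 + 1L))
}

#' Assign reads to repeat families, strand-aware
#'
#' A read belongs to a family when its midpoint falls inside one of the
#' family's annotated intervals (midpoints avoid double counting at
#' boundaries). The read's strand relative to the repeat's annotated strand
#' decides sense vs antisense. Reads whose midpoint hits no interval are
#' tallied as unannotated.
#'
#' @param placements named \code{GRanges} of read placements (see
#'   [readPlacements()]).
#' @param annot repeat annotation \code{GRanges} with a \code{family}
#'   metadata column (see [readRepeatBed()]).
#' @return A data.frame with one row per family: \code{family},
#'   \code{sense}, \code{antisense}, \code{genomic_bp} (total annotated
#'   bases of the family), plus an \code{"unannotated"} attribute with the
#'   leftover read count.
#' @export
assignReads <- function(placements, annot) {
    stopifnot(is(placements, "GRanges"), is(annot, "GRanges"))
    fam <- mcols(annot)$family
    if (is.null(fam)) stop("'annot' needs a 'family' metadata column")
    unknown <- setdiff(as.character(unique(seqnames(placements))),
                       seqlevels(annot))
    if (length(unknown))
        stop("placements on chromosome(s) absent from the annotation: ",
             paste(unknown, collapse = ", "))
    mid <- .midpoints(placements)
    hit <- findOverlaps(mid, annot, select = "first", ignore.strand = TRUE)
    families <- unique(fam)
    readStrand <- as.character(strand(placements))
    annStrand <- as.character(strand(annot))
    annStrand[annStrand == "*"] <- "+"
    readStrand[readStrand == "*"] <- "+"
    sense <- antisense <- setNames(integer(length(families)), families)
    ok <- !is.na(hit)
    hf <- fam[hit[ok]]
    same <- readStrand[ok] == annStrand[hit[ok]]
    ts <- table(factor(hf[same], levels = families))
    ta <- table(factor(hf[!same], levels = families))
    sense[] <- as.integer(ts)
    antisense[] <- as.integer(ta)
    bp <- vapply(families, function(f)
        sum(width(annot)[fam == f]), numeric(1))
    out <- data.frame(family = families, sense = unname(sense),
                      antisense = unname(antisense),
                      genomic_bp = as.integer(unname(bp)),
                      stringsAsFactors = FALSE)
    attr(out, "unannotated") <- sum(!ok)
    out
}

#' Fold enrichment of the dominant strand over genomic abundance
#'
#' The dominant strand is the one with more assigned reads (ties go to
#' sense). Fold enrichment compares the family's share of selected reads on
#' that strand with its share of strand-specific genomic positions:
#' \deqn{fold = \frac{dominant/total}{family\_bp/(2 \cdot genome\_bp)}}
#' The factor 2 reflects that reads are sampled from both strands while the
#' family annotation occupies one; with it, uniform random sampling gives
#' fold = 1 for every family. The per-base denominator (rather than a
#' per-locus one) is used because locus counts are ill-defined when source
#' and reference genomes differ.
#'
#' @param counts data.frame from [assignReads()] (or with the same columns).
#' @param totalReads total number of placed reads (> 0).
#' @param genomeBp genome length in bp.
#' @return A data.frame with \code{family}, \code{sense}, \code{antisense},
#'   \code{dominant_strand}, \code{dominant_count}, \code{fold}.
#' @export
foldEnrichment <- function(counts, totalReads, genomeBp) {
    stopifnot(totalReads > 0, genomeBp > 0)
    need <- c("family", "sense", "antisense", "genomic_bp")
    if (!all(need %in% names(counts)))
        stop("'counts' must have columns: ", paste(need, collapse = ", "))
    if (any(counts$genomic_bp <= 0))
        stop("family absent from annotation: ",
             paste(counts$family[counts$genomic_bp <= 0], collapse = ", "))
    dominant <- ifelse(counts$antisense > counts$sense, "antisense", "sense")
    domCount <- pmax(counts$sense, counts$antisense)
    fold <- (domCount / totalReads) /
        (counts$genomic_bp / (2 * genomeBp))
    data.frame(family = counts$family, sense = counts$sense,
               antisense = counts$antisense, dominant_strand = dominant,
               dominant_count = domCount, fold = fold,
               stringsAsFactors = FALSE)
}

#' Stack reads into fixed-width genomic contigs
#'
#' Tiles each chromosome with non-overlapping windows of fixed width
#' (default 400 nt, the contig size used to aggregate selected reads) from
#' position 0 and counts each read in the window containing its midpoint.
#' Windows with zero reads are omitted.
#'
#' @param placements named \code{GRanges} of read placements.
#' @param chromLengths optional named vector of chromosome lengths; when
#'   given, the last window of each chromosome is truncated to it.
#' @param window window width in nt (>= 1).
#' @return A data.frame with \code{chrom}, \code{window_start} (0-based),
#'   \code{window_end} (exclusive), \code{read_count}.
#' @export
contigStacks <- function(placements, chromLengths = NULL, window = 400L) {
    stopifnot(is(placements, "GRanges"), window >= 1L)
    window <- as.integer(window)
    if (length(placements) == 0L)
        return(data.frame(chrom = character(0), window_start = integer(0),
                          window_end = integer(0), read_count = integer(0)))
    mid0 <- (start(placements) - 1L + end(placements)) %/% 2L
    chrom <- as.character(seqnames(placements))
    bin <- mid0 %/% window
    tab <- table(chrom, bin)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0L, ]
    ws <- as.integer(df$bin) * window
    we <- ws + window
    if (!is.null(chromLengths)) {
        lim <- chromLengths[df$chrom]
        we <- pmin(we, as.integer(lim))
    }
    out <- data.frame(chrom = df$chrom, window_start = ws, window_end = we,
                      read_count = as.integer(df$Freq),
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$window_start), , drop = FALSE]
}

#' CA-richness of a sequence set against a background model
#'
#' Pooled fraction of C and A bases across the set, with an upper-tail
#' Monte-Carlo p-value against i.i.d. background sequences of the same
#' lengths (selected Pol II binders are characteristically CA-rich). The CA
#' dinucleotide frequency (fraction of adjacent positions reading "CA") is
#' reported as a secondary statistic with its own null summary.
#'
#' @param seqs sequences acceptable to [ingestDNA()].
#' @param bg a [backgroundModel()].
#' @param nPerm number of null replicates (>= 100).
#' @param seed integer seed.
#' @return A list: \code{observedFraction}, \code{z}, \code{pEmpirical}
#'   (upper tail, (m + 1)/(n + 1)), \code{nullMean}, \code{nullSd},
#'   \code{dinucleotide} (observed CA-dinucleotide frequency),
#'   \code{dinucleotideNullMean}.
#' @export
caRichness <- function(seqs, bg = humanBackground(), nPerm = 1000L, seed) {
    seqs <- ingestDNA(seqs)
    if (length(seqs) == 0L) stop("empty sequence set")
    nPerm <- as.integer(nPerm)
    if (nPerm < 100L) stop("'nPerm' must be >= 100")
    if (missing(seed)) stop("'seed' is required")
    lf <- Biostrings::letterFrequency(seqs, c("C", "A"))
    total <- sum(Biostrings::width(seqs))
    obs <- sum(lf) / total
    di <- Biostrings::dinucleotideFrequency(seqs)
    nDi <- sum(Biostrings::width(seqs) - 1L)
    obsDi <- sum(di[, "CA"]) / nDi
    lens <- Biostrings::width(seqs)
    ends <- cumsum(lens)
    bgProbs <- as.numeric(bg)
    res <- withSeed(as.integer(seed), {
        nullFrac <- numeric(nPerm); nullDi <- numeric(nPerm)
        for (i in seq_len(nPerm)) {
            b <- .sampleBases(total, bgProbs)
            nullFrac[i] <- sum(b <= 2L) / total      # codes 1=A, 2=C
            isCA <- b[-total] == 2L & b[-1L] == 1L
            isCA[ends[-length(ends)]] <- FALSE       # don't span sequences
            nullDi[i] <- sum(isCA) / nDi
        }
        list(frac = nullFrac, di = nullDi)
    })
    m <- sum(res$frac >= obs)
    z <- if (sd(res$frac) > 0) (obs - mean(res$frac)) / sd(res$frac)
         else NA_real_
    list(observedFraction = obs, z = z,
         pEmpirical = (m + 1) / (nPerm + 1),
         nullMean = mean(res$frac), nullSd = sd(res$frac),
         dinucleotide = obsDi, dinucleotideNullMean = mean(res$di))
}
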