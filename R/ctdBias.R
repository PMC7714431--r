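## The composition statistic: pooled 3-frame amino-acid frequencies of the
## selected sequences, codon-multiplicity normalisation, Jensen-Shannon
## divergence to the CTD composition, and a Monte-Carlo null built from
## background-frequency random RNA of matched lengths.

## counts of the 20 standard amino acids in an AAStringSet ('*' and 'X'
## tallied separately and excluded)
.aaCountsFromPeptides <- function(p) {
    lf <- Biostrings::letterFrequency(p, c(.AA20, "X", "*"))
    cs <- colSums(lf)
    counts <- cs[.AA20]
    attr(counts, "nStop") <- unname(cs["*"])
    attr(counts, "nAmbiguous") <- unname(cs["X"])
    counts
}

#' Pooled amino-acid composition of translated sequences
#'
#' Translates every sequence in the requested reading frames (all three
#' 5'->3' frames by default, matching how the selected pool is scored),
#' pools the amino-acid counts over all sequences and frames into a single
#' vector, excludes stop codons and N-containing codons, and normalises to
#' sum 1.
#'
#' @param seqs sequences acceptable to [ingestDNA()]; each must be long
#'   enough for the requested frames (>= 5 nt for all three).
#' @param frames integer offsets to pool over (default \code{0:2}).
#' @return An [AAFreqDist-class].
#' @examples
#' aaFrequencies("TATTCTCCTACTTCTCCTTCT", frames = 0)  # composition of YSPTSPS
#' @export
aaFrequencies <- function(seqs, frames = 0:2) {
    seqs <- ingestDNA(seqs)
    stopifnot(all(frames %in% 0:2), length(frames) >= 1L)
    counts <- setNames(numeric(20L), .AA20)
    for (f in frames) {
        p <- suppressWarnings(translateFrame(seqs, f))
        counts <- counts + .aaCountsFromPeptides(p)
    }
    if (sum(counts) <= 0) stop("empty composition: no scorable codons")
    AAFreqDist(counts)
}

#' Divide out the genetic code's redundancy
#'
#' Amino acids encoded by many codons are over-represented in translations
#' of random nucleotide sequence for purely combinatorial reasons. Dividing
#' each frequency by the amino acid's codon multiplicity (and renormalising)
#' removes that artefact, so that a uniformly random codon stream maps to
#' the uniform composition 1/20. Observed sequences, random-null sequences
#' and the CTD reference are all normalised by the same rule before
#' divergences are taken.
#'
#' @param dist an [AAFreqDist-class].
#' @param multiplicity named integer vector of codon multiplicities
#'   (default [codonMultiplicity()]).
#' @return A codon-normalised [AAFreqDist-class].
#' @examples
#' codonNormalize(AAFreqDist(c(Y = 1, S = 3, P = 2, T = 1)))
#' @export
codonNormalize <- function(dist, multiplicity = codonMultiplicity()) {
    stopifnot(is(dist, "AAFreqDist"))
    v <- .freqVec(dist) / multiplicity[.AA20]
    AAFreqDist(setNames(v, .AA20))
}

#' Codon-normalised CTD reference composition
#'
#' Amino-acid composition of the Pol II CTD, codon-normalised by the same
#' rule as the query sequences. The default is the consensus heptad YSPTSPS
#' (any number of perfect repeats gives the same composition); a full RPB1
#' CTD protein sequence may be supplied instead.
#'
#' @param ctd optional peptide (character or \code{AAString}); default
#'   consensus heptad.
#' @return An [AAFreqDist-class].
#' @examples
#' ctdReference()  # Y 2/7, S 2/7, P 2/7, T 1/7
#' @export
ctdReference <- function(ctd = NULL) {
    if (is.null(ctd)) ctd <- ctdHeptad()
    if (is(ctd, "AAString") || is(ctd, "AAStringSet"))
        ctd <- paste(as.character(ctd), collapse = "")
    if (!nzchar(ctd)) stop("empty CTD sequence")
    aa <- strsplit(toupper(ctd), "", fixed = TRUE)[[1L]]
    aa <- aa[aa %in% .AA20]
    if (!length(aa)) stop("CTD sequence has no standard residues")
    codonNormalize(AAFreqDist(table(factor(aa, levels = .AA20))))
}

## fast JSD on two bare probability vectors (base-2 logs)
.jsd2 <- function(p, q) {
    m <- (p + q) / 2
    h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
    v <- h(m) - (h(p) + h(q)) / 2
    min(max(v, 0), 1)  # clamp numerical noise at the boundaries
}

#' Jensen-Shannon divergence between two compositions
#'
#' \code{JSD(p, q) = H((p + q)/2) - (H(p) + H(q))/2} with base-2 logarithms
#' (so the statistic is bounded by 1; the base rescales JSD, null mean and
#' null sd identically, leaving z and p-values invariant). Symmetric,
#' non-negative, and zero iff the distributions are equal.
#'
#' @param p,q [AAFreqDist-class] objects, or bare normalised numeric vectors
#'   over a common index set.
#' @return Numeric in \[0, 1\].
#' @examples
#' jsDivergence(c(0.5, 0.5), c(1, 0))  # 0.31128
#' @export
jsDivergence <- function(p, q) {
    pv <- if (is(p, "AAFreqDist")) .freqVec(p) else as.numeric(p)
    qv <- if (is(q, "AAFreqDist")) .freqVec(q) else as.numeric(q)
    if (length(pv) != length(qv))
        stop("'p' and 'q' must share an index set")
    if (any(pv < 0) || any(qv < 0) ||
        abs(sum(pv) - 1) > 1e-9 || abs(sum(qv) - 1) > 1e-9)
        stop("'p' and 'q' must be normalised distributions")
    .jsd2(pv, qv)
}

## ----------------------------------------------------------- the null ----

## Pooled 3-frame codon counts of a sequence equal the counts over ALL
## consecutive trinucleotide windows (each window is a codon of exactly one
## frame). The null sampler exploits this with integer-coded bases.
.nullJsdSamples <- function(lengths, bgProbs, refVec, nSets) {
    lengths <- as.integer(lengths)
    total <- sum(lengths)
    ends <- cumsum(lengths)
    w <- seq_len(total - 2L)
    bad <- c(ends - 1L, ends)            # windows crossing a boundary
    w <- w[!w %in% bad[bad <= total - 2L]]
    w1 <- w + 1L; w2 <- w + 2L
    lut <- .aaLookup()
    mult <- as.numeric(codonMultiplicity())
    samples <- numeric(nSets)
    for (i in seq_len(nSets)) {
        b <- sample.int(4L, total, replace = TRUE, prob = bgProbs)
        code <- .codonIndex(b[w], b[w1], b[w2])
        cnt <- tabulate(lut[code], 21L)[1:20]
        tot <- sum(cnt)
        if (tot == 0L) { samples[i] <- NA_real_; next }
        v <- cnt / tot
        v <- v / mult
        v <- v / sum(v)
        samples[i] <- .jsd2(v, refVec)
    }
    samples
}

#' Monte-Carlo null distribution of the composition divergence
#'
#' For each replicate, draws i.i.d. random sequences from the background
#' model with lengths matched sequence-by-sequence to the observed set,
#' computes the pooled 3-frame codon-normalised amino-acid composition, and
#' records its Jensen-Shannon divergence to the reference. The published
#' analysis used 1e6 replicate sets; the desk default is 1e4 (configurable).
#'
#' @param lengths integer lengths (nt) of the observed sequences.
#' @param bg a [backgroundModel()].
#' @param reference codon-normalised reference composition
#'   ([AAFreqDist-class]), default [ctdReference()].
#' @param nSets number of replicates (>= 100; the sd of the null is
#'   unreliable below that).
#' @param seed integer seed (mandatory for reproducibility).
#' @return A [NullDistribution-class].
#' @export
sampleNull <- function(lengths, bg = humanBackground(),
                       reference = ctdReference(), nSets = 10000L, seed) {
    nSets <- as.integer(nSets)
    if (nSets < 100L) stop("'nSets' must be >= 100 (sd unreliable)")
    if (missing(seed)) stop("'seed' is required")
    stopifnot(all(lengths >= 5L))
    refVec <- if (is(reference, "AAFreqDist")) .freqVec(reference) else
        as.numeric(reference)
    samples <- withSeed(as.integer(seed),
        .nullJsdSamples(lengths, as.numeric(bg), refVec, nSets))
    if (anyNA(samples)) stop("null replicate with no scorable codons")
    new("NullDistribution", samples = samples, nSets = nSets,
        seed = as.integer(seed), mean = mean(samples), sd = sd(samples))
}

#' Lower-tail Gaussian probability at a z-score
#'
#' The published significance argument: when the observed divergence sits
#' many null standard deviations below the null mean, the empirical p-value
#' saturates at 1/(n + 1) and the tail is extrapolated with a normal
#' approximation. At z = -10 this gives about 7.6e-24, i.e. below 1e-23.
#'
#' @param z standardised score.
#' @return \code{pnorm(z)}.
#' @examples
#' gaussianTailP(-10)  # < 1e-23
#' @export
gaussianTailP <- function(z) pnorm(z)

#' Codon-normalised composition bias test
#'
#' The package's headline statistic. Translates the observed sequences in
#' all three 5'->3' frames, pools and codon-normalises the amino-acid
#' composition, and measures its Jensen-Shannon divergence to the reference
#' (CTD) composition. Significance comes from a Monte-Carlo null of
#' background random RNA with matched lengths; because a CTD-like pool shows
#' unusually LOW divergence, the test is lower-tailed: the empirical p-value
#' is (m + 1)/(n + 1) with m the number of null divergences at or below the
#' observed one, and the Gaussian p-value is the lower normal tail at
#' z = (observed - null mean) / null sd.
#'
#' @param observed sequences acceptable to [ingestDNA()].
#' @param bg a [backgroundModel()].
#' @param reference codon-normalised reference composition, default
#'   [ctdReference()].
#' @param nSets,seed passed to [sampleNull()].
#' @return A [BiasTestResult-class].
#' @examples
#' set.seed(1)
#' raps <- makeRapSet(20, 90, ctdFraction = 1, seed = 1)
#' biasTest(raps, nSets = 200, seed = 7)
#' @export
biasTest <- function(observed, bg = humanBackground(),
                     reference = ctdReference(), nSets = 10000L, seed) {
    observed <- ingestDNA(observed)
    refVec <- if (is(reference, "AAFreqDist")) reference else
        AAFreqDist(reference)
    obsDist <- codonNormalize(aaFrequencies(observed, frames = 0:2))
    obsJsd <- jsDivergence(obsDist, refVec)
    null <- sampleNull(Biostrings::width(observed), bg = bg,
                       reference = refVec, nSets = nSets, seed = seed)
    m <- sum(null@samples <= obsJsd)
    pEmp <- (m + 1) / (null@nSets + 1)
    if (null@sd > 0) {
        z <- (obsJsd - null@mean) / null@sd
        pG <- gaussianTailP(z)
    } else {
        warning("null sd is zero; z undefined")
        z <- NA_real_; pG <- NA_real_
    }
    new("BiasTestResult", observedJSD = obsJsd, z = z,
        pEmpirical = pEmp, pGaussian = pG, null = null)
}

#' Codon usage across all three reading frames
#'
#' Counts every complete codon in all three 5'->3' frames of every sequence
#' (the codon-frequency panel of a selected pool). Stop codons are counted
#' and flagged.
#'
#' @param seqs sequences acceptable to [ingestDNA()] (each >= 5 nt).
#' @return A data.frame with columns \code{codon}, \code{aa}, \code{count},
#'   \code{is_stop}, one row per codon of the genetic code (64 rows).
#' @examples
#' head(subset(codonUsage("TCTTCT"), count > 0))
#' @export
codonUsage <- function(seqs) {
    seqs <- ingestDNA(seqs)
    if (any(Biostrings::width(seqs) < 5L))
        stop("sequences must be >= 5 nt")
    gc <- geneticCode()
    codons <- sort(names(gc))
    counts <- setNames(integer(64L), codons)
    for (f in 0:2) {
        L <- Biostrings::width(seqs)
        ncod <- (L - f) %/% 3L
        keep <- ncod >= 1L
        if (!any(keep)) next
        sub <- subseq(seqs[keep], start = f + 1L,
                      end = f + 3L * ncod[keep])
        tri <- Biostrings::trinucleotideFrequency(sub, step = 3L)
        cs <- colSums(tri)
        counts[names(cs)] <- counts[names(cs)] + as.integer(cs)
    }
    data.frame(codon = codons, aa = unname(gc[codons]),
               count = unname(counts),
               is_stop = unname(gc[codons] == "*"),
               stringsAsFactors = FALSE)
}
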