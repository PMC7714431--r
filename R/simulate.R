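## Synthetic SELEX experiment with full ground truth: background genome,
## planted repeat families (one optionally a CTD-codon-like satellite), and
## affinity-weighted read selection. Every generator is a pure function of
## (config, seed).

#' Describe one repeat family to plant
#'
#' @param name family label.
#' @param unitLength length of the repeat unit in bp (for the
#'   \code{"ctd"} builder this should be a multiple of 21, e.g. 147 = 7
#'   reverse-translated heptads, the unit length of the CTD-like satellite).
#' @param copies number of planted copies.
#' @param strand placement rule: all copies \code{"sense"} (+), all
#'   \code{"antisense"} (-), or \code{"both"} (random per copy).
#' @param weight selection affinity weight (>= 0; background positions have
#'   weight 1).
#' @param builder how the consensus unit is built: \code{"random"} (i.i.d.
#'   background bases), \code{"ctd"} (tandem reverse-translated YSPTSPS
#'   heptads, codons drawn uniformly per amino acid -- the frame-0
#'   translation at noise 0 is exact heptads), or \code{"simple"} (a short
#'   motif tiled to length, e.g. "CA").
#' @param motif motif for the \code{"simple"} builder.
#' @return A list describing the family (consumed by [simConfig()]).
#' @export
repeatFamily <- function(name, unitLength, copies, strand = c("both",
                         "sense", "antisense"), weight = 1,
                         builder = c("random", "ctd", "simple"),
                         motif = NULL) {
    strand <- match.arg(strand)
    builder <- match.arg(builder)
    if (builder == "simple" && (is.null(motif) || !nzchar(motif)))
        stop("'simple' builder needs a motif")
    list(name = name, unitLength = as.integer(unitLength),
         copies = as.integer(copies), strand = strand,
         weight = as.numeric(weight), builder = builder, motif = motif)
}

#' Build a simulation configuration
#'
#' @param genomeLength background genome size in bp.
#' @param bg background model ([backgroundModel()]).
#' @param families list of [repeatFamily()] descriptions.
#' @param readCount number of selected reads.
#' @param readLengthRange inclusive read-length range in nt; the default
#'   30-400 mirrors the short-transcript library screened in the selection.
#' @param noise per-base substitution probability.
#' @param seed integer seed.
#' @return A [SimConfig-class].
#' @examples
#' simConfig(10000, families = list(
#'   repeatFamily("ACRO1like", 147, 3, builder = "ctd", weight = 20)),
#'   readCount = 500, seed = 1)
#' @export
simConfig <- function(genomeLength, bg = humanBackground(),
                      families = list(), readCount = 1000L,
                      readLengthRange = c(30L, 400L), noise = 0,
                      seed = 1L) {
    readLengthRange <- pmin(as.integer(readLengthRange),
                            as.integer(genomeLength))
    new("SimConfig", genomeLength = as.integer(genomeLength),
        bg = as.numeric(bg), families = families,
        readCount = as.integer(readCount),
        readLengthRange = readLengthRange,
        noise = as.numeric(noise), seed = as.integer(seed))
}

## consensus unit for one family description (integer base codes)
.buildUnit <- function(fam, bgProbs) {
    n <- fam$unitLength
    switch(fam$builder,
        random = .sampleBases(n, bgProbs),
        simple = {
            mb <- match(strsplit(toupper(fam$motif), "",
                                 fixed = TRUE)[[1L]], .BASES)
            if (anyNA(mb)) stop("motif must be over A/C/G/T")
            rep_len(mb, n)
        },
        ctd = {
            nHept <- n %/% 21L
            if (nHept < 1L) stop("'ctd' builder needs unitLength >= 21")
            aa <- rep(strsplit(.CTD_HEPTAD, "", fixed = TRUE)[[1L]], nHept)
            u <- unlist(lapply(aa, .sampleCodonFor))
            rep_len(u, n)  # pad (never needed when n %% 21 == 0)
        })
}

## uniform codon (integer base codes) for one amino-acid letter
.sampleCodonFor <- function(aa) {
    gc <- geneticCode()
    codons <- names(gc)[gc == aa]
    cod <- codons[sample.int(length(codons), 1L)]
    match(strsplit(cod, "", fixed = TRUE)[[1L]], .BASES)
}

## per-base substitution noise on integer base codes
.addNoise <- function(b, p) {
    if (p <= 0) return(b)
    hit <- which(runif(length(b)) < p)
    if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        b[hit] <- ((b[hit] - 1L + shift) %% 4L) + 1L
    }
    b
}

.revcompCodes <- function(b) rev(5L - b)

#' Generate a synthetic genome with planted repeat families
#'
#' Draws a background genome i.i.d. from the background model and plants
#' each family's copies at non-overlapping random positions on the
#' configured strands (antisense copies insert the reverse complement of
#' the unit). Per-base substitution noise is applied to each copy
#' independently. Deterministic given \code{(cfg, cfg@seed)}.
#'
#' @param cfg a [SimConfig-class].
#' @return A list: \code{genome} (named \code{DNAStringSet}, one chromosome
#'   \code{"chr1"}), \code{annotation} (\code{GRanges} with \code{family}),
#'   \code{truth} ([GroundTruth-class]).
#' @export
buildGenome <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    withSeed(cfg@seed, {
        G <- cfg@genomeLength
        bgProbs <- cfg@bg
        b <- .sampleBases(G, bgProbs)
        occupied <- logical(G)
        starts <- integer(0); ends <- integer(0)
        famLab <- character(0); strands <- character(0)
        units <- list()
        for (fam in cfg@families) {
            unit <- .buildUnit(fam, bgProbs)
            units[[fam$name]] <- unit
            for (k in seq_len(fam$copies)) {
                placed <- FALSE
                for (try in seq_len(1000L)) {
                    s <- sample.int(G - fam$unitLength + 1L, 1L)
                    e <- s + fam$unitLength - 1L
                    if (!any(occupied[s:e])) {
                        occupied[s:e] <- TRUE
                        st <- switch(fam$strand,
                                     sense = "+", antisense = "-",
                                     both = sample(c("+", "-"), 1L))
                        u <- .addNoise(unit, cfg@noise)
                        if (st == "-") u <- .revcompCodes(u)
                        b[s:e] <- u
                        starts <- c(starts, s); ends <- c(ends, e)
                        famLab <- c(famLab, fam$name)
                        strands <- c(strands, st)
                        placed <- TRUE
                        break
                    }
                }
                if (!placed)
                    stop("could not place copy ", k, " of family '",
                         fam$name, "' without overlap")
            }
        }
        genome <- DNAStringSet(setNames(.basesToString(b), "chr1"))
        ord <- order(starts)
        annotation <- if (length(starts))
            GRanges("chr1", IRanges(starts[ord], ends[ord]),
                    strand = strands[ord])
        else GRanges()
        mcols(annotation)$family <- famLab[ord]
        affinity <- vapply(cfg@families, function(f) f$weight, numeric(1))
        names(affinity) <- vapply(cfg@families, function(f) f$name, "")
        unitSet <- DNAStringSet(vapply(units, .basesToString, ""))
        truth <- new("GroundTruth", annotation = annotation,
                     affinityMap = affinity, unitSeqs = unitSet,
                     config = cfg)
        list(genome = genome, annotation = annotation, truth = truth)
    })
}

## per-position selection weight vector implied by the ground truth
.weightVector <- function(truth) {
    G <- truth@config@genomeLength
    w <- rep(1, G)
    ann <- truth@annotation
    fam <- mcols(ann)$family
    for (i in seq_along(ann))
        w[start(ann)[i]:end(ann)[i]] <- truth@affinityMap[[fam[i]]]
    w
}

#' Sample an affinity-weighted read pool (SELEX emulation)
#'
#' Read start positions are drawn with probability proportional to the
#' local affinity weight (positions inside a planted family carry that
#' family's weight, background positions weight 1), emulating the
#' over-recovery of high-affinity sequences across selection cycles with a
#' single weighted draw. Read lengths are uniform in the configured range
#' (reads running off the genome end are truncated), strands uniform, and
#' per-base substitution noise is applied. True placements are recorded.
#'
#' @param genome \code{DNAStringSet} from [buildGenome()].
#' @param truth [GroundTruth-class] from [buildGenome()].
#' @param cfg the [SimConfig-class].
#' @param seed integer seed (default \code{cfg@seed + 1} so that genome and
#'   reads use distinct streams).
#' @return A list: \code{reads} (named \code{DNAStringSet}),
#'   \code{placements} (named \code{GRanges} with true \code{family}
#'   metadata, \code{"."} for background).
#' @export
sampleReads <- function(genome, truth, cfg, seed = cfg@seed + 1L) {
    stopifnot(is(truth, "GroundTruth"), is(cfg, "SimConfig"))
    withSeed(as.integer(seed), {
        G <- cfg@genomeLength
        N <- cfg@readCount
        w <- .weightVector(truth)
        starts <- sample.int(G, N, replace = TRUE, prob = w)
        lens <- sample.int(cfg@readLengthRange[2L] -
                           cfg@readLengthRange[1L] + 1L, N,
                           replace = TRUE) + cfg@readLengthRange[1L] - 1L
        ends <- pmin(starts + lens - 1L, G)
        strands <- sample(c("+", "-"), N, replace = TRUE)
        seqs <- extractAt(genome[[1L]], IRanges(starts, ends))
        seqs <- DNAStringSet(seqs)
        minus <- strands == "-"
        if (any(minus))
            seqs[minus] <- reverseComplement(seqs[minus])
        if (cfg@noise > 0) {
            ks <- rbinom(N, Biostrings::width(seqs), cfg@noise)
            idx <- which(ks > 0L)
            if (length(idx)) {
                ch <- as.character(seqs[idx])
                for (j in seq_along(idx)) {
                    v <- match(strsplit(ch[j], "", fixed = TRUE)[[1L]],
                               .BASES)
                    pos <- sample.int(length(v), ks[idx[j]])
                    v[pos] <- ((v[pos] - 1L +
                                sample.int(3L, length(pos),
                                           replace = TRUE)) %% 4L) + 1L
                    ch[j] <- .basesToString(v)
                }
                seqs[idx] <- DNAStringSet(ch)
            }
        }
        ids <- sprintf("read%06d", seq_len(N))
        names(seqs) <- ids
        placements <- GRanges("chr1", IRanges(starts, ends),
                              strand = strands)
        names(placements) <- ids
        mid <- .midpoints(placements)
        hit <- findOverlaps(mid, truth@annotation, select = "first",
                            ignore.strand = TRUE)
        famAnn <- mcols(truth@annotation)$family
        mcols(placements)$family <- ifelse(is.na(hit), ".", famAnn[hit])
        list(reads = seqs, placements = placements)
    })
}

#' Build a CTD-mosaic sequence set
#'
#' Fixture generator for the composition bias test: each sequence is a
#' codon mosaic where every codon is, with probability \code{ctdFraction},
#' a reverse-translated codon of the CTD heptad cycle (uniform over the
#' amino acid's codons) and otherwise three i.i.d. background bases.
#' \code{ctdFraction = 0} reduces to pure background;
#' \code{ctdFraction = 1} at frame 0 translates to exact heptads.
#'
#' @param n number of sequences.
#' @param length sequence length in nt (codon count = \code{length %/% 3};
#'   a remainder is filled with background bases).
#' @param ctdFraction probability that a codon is CTD-derived.
#' @param bg a [backgroundModel()].
#' @param seed integer seed.
#' @return A named \code{DNAStringSet}.
#' @export
makeRapSet <- function(n, length, ctdFraction, bg = humanBackground(),
                       seed) {
    stopifnot(ctdFraction >= 0, ctdFraction <= 1, n >= 1, length >= 3)
    if (missing(seed)) stop("'seed' is required")
    bgProbs <- as.numeric(bg)
    hept <- strsplit(.CTD_HEPTAD, "", fixed = TRUE)[[1L]]
    withSeed(as.integer(seed), {
        out <- character(n)
        nCod <- length %/% 3L
        rest <- length - 3L * nCod
        for (i in seq_len(n)) {
            useCtd <- runif(nCod) < ctdFraction
            codons <- vector("list", nCod)
            for (k in seq_len(nCod)) {
                codons[[k]] <- if (useCtd[k])
                    .sampleCodonFor(hept[(k - 1L) %% 7L + 1L])
                else .sampleBases(3L, bgProbs)
            }
            tail <- if (rest > 0L) .sampleBases(rest, bgProbs) else integer(0)
            out[i] <- .basesToString(c(unlist(codons), tail))
        }
        DNAStringSet(setNames(out, sprintf("rap%04d", seq_len(n))))
    })
}

#' Exact expected per-strand fold enrichment under the sampling rule
#'
#' Closed-form expectation of the dominant-strand fold enrichment that
#' [sampleReads()] + [assignReads()] + [foldEnrichment()] estimate: for
#' every start position (weighted by local affinity) and every read length
#' (uniform), the read midpoint is computed exactly as the assignment step
#' computes it (including truncation at the genome end), and the
#' probability that it lands in the family is converted to the per-strand
#' fold. Serves as the analytic oracle for enrichment recovery.
#'
#' @param truth [GroundTruth-class].
#' @param family family name.
#' @return Expected per-strand fold enrichment (numeric).
#' @export
expectedFamilyFold <- function(truth, family) {
    cfg <- truth@config
    G <- cfg@genomeLength
    w <- .weightVector(truth)
    ann <- truth@annotation
    sel <- mcols(ann)$family == family
    if (!any(sel)) stop("unknown family: ", family)
    mask <- logical(G)
    for (i in which(sel)) mask[start(ann)[i]:end(ann)[i]] <- TRUE
    famBp <- sum(mask)
    lens <- cfg@readLengthRange[1L]:cfg@readLengthRange[2L]
    sw <- sum(w)
    pAcc <- 0
    s <- seq_len(G)
    for (L in lens) {
        e <- pmin(s + L - 1L, G)
        mid <- ((s - 1L + e) %/% 2L) + 1L
        pAcc <- pAcc + sum(w[mask[mid]])
    }
    pMid <- pAcc / (length(lens) * sw)
    ## per-strand read share pMid/2 over per-strand abundance famBp/(2G)
    (pMid / 2) / (famBp / (2 * G))
}
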