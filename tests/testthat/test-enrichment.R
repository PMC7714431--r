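## small fixture: one sense ACRO1 locus and one antisense CA locus on chr1
makeAnnot <- function() {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(101, 501), c(200, 560)),
                                 strand = c("+", "-"))
    S4Vectors::mcols(gr)$family <- c("ACRO1", "CA")
    gr
}

placeRead <- function(start, end, strand, id = "r1") {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                                 strand = strand)
    names(gr) <- id
    gr
}

test_that("midpoint rule and relative strand decide family assignment", {
    annot <- makeAnnot()
    cs <- assignReads(placeRead(120, 180, "+"), annot)
    expect_equal(cs$sense[cs$family == "ACRO1"], 1L)
    expect_equal(cs$antisense[cs$family == "ACRO1"], 0L)
    cs <- assignReads(placeRead(120, 180, "-"), annot)
    expect_equal(cs$antisense[cs$family == "ACRO1"], 1L)
    ## a minus read over a minus-annotated repeat is sense
    cs <- assignReads(placeRead(510, 550, "-"), annot)
    expect_equal(cs$sense[cs$family == "CA"], 1L)
    ## midpoint outside every interval -> unannotated, even if the read
    ## overlaps an interval edge
    cs <- assignReads(placeRead(190, 350, "+"), annot)  # midpoint 270
    expect_equal(sum(cs$sense) + sum(cs$antisense), 0L)
    expect_equal(attr(cs, "unannotated"), 1L)
    expect_error(assignReads(placeRead(1, 10, "+") |>
        (\(g) { GenomeInfoDb::seqlevels(g) <- "chrX"; g })(), annot),
        "chrX")
})

test_that("read counting conserves the total across sense/antisense/unannotated", {
    set.seed(61)
    annot <- makeAnnot()
    n <- 500
    starts <- sample(1:900, n, TRUE)
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(starts, starts + sample(20:80, n, TRUE)),
        strand = sample(c("+", "-"), n, TRUE))
    names(gr) <- paste0("r", seq_len(n))
    cs <- assignReads(gr, annot)
    expect_equal(sum(cs$sense) + sum(cs$antisense) +
                 attr(cs, "unannotated"), n)
    expect_equal(cs$genomic_bp, c(100L, 60L))
})

test_that("fold enrichment normalises the dominant strand by strand-specific abundance", {
    ## family covering 1% of the genome taking 50% of all reads on its
    ## dominant strand: share 0.5 over per-strand abundance 0.005 -> 100
    counts <- data.frame(family = "F", sense = 500L, antisense = 100L,
                         genomic_bp = 1000L)
    enr <- foldEnrichment(counts, totalReads = 1000L, genomeBp = 100000L)
    expect_equal(enr$dominant_strand, "sense")
    expect_equal(enr$dominant_count, 500L)
    expect_equal(enr$fold, (500 / 1000) / (1000 / (2 * 100000)))
    ## strand dominance as reported for the top CA-repeat counts
    t2 <- data.frame(family = "(CACAC)n", sense = 1393L, antisense = 2652L,
                     genomic_bp = 5000L)
    expect_equal(foldEnrichment(t2, 10000L, 1e6)$dominant_strand,
                 "antisense")
    ## ties break toward sense
    tie <- data.frame(family = "T", sense = 5L, antisense = 5L,
                      genomic_bp = 10L)
    expect_equal(foldEnrichment(tie, 10L, 1000L)$dominant_strand, "sense")
    expect_error(foldEnrichment(
        data.frame(family = "Z", sense = 1L, antisense = 0L,
                   genomic_bp = 0L), 10L, 1000L), "absent")
})

test_that("uniform random placement gives fold near 1", {
    set.seed(62)
    G <- 50000L
    annot <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 20500),
                                    strand = "+")
    S4Vectors::mcols(annot)$family <- "F"
    n <- 20000L
    starts <- sample.int(G - 100L, n, TRUE)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, starts + 50L),
                                 strand = sample(c("+", "-"), n, TRUE))
    names(gr) <- paste0("r", seq_len(n))
    enr <- foldEnrichment(assignReads(gr, annot), n, G)
    p <- 500 / (2 * G)
    se <- sqrt(p * (1 - p) / n) / p
    expect_lt(abs(enr$fold - 1), 3 * se + 0.1)
})

test_that("contig stacks tile from zero, count by midpoint, and conserve reads", {
    ## 0-based midpoints 10, 350, 420 with window 400
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(11, 341, 411), c(11, 361, 431)), strand = "+")
    names(gr) <- paste0("r", 1:3)
    st <- contigStacks(gr, window = 400)
    expect_equal(st$window_start, c(0L, 400L))
    expect_equal(st$read_count, c(2L, 1L))
    expect_equal(sum(st$read_count), 3L)
    ## empty input
    empty <- GenomicRanges::GRanges()
    expect_equal(nrow(contigStacks(empty)), 0L)
    ## conservation on random placements, multiple chromosomes
    set.seed(63)
    n <- 300
    gr2 <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), n, TRUE),
        IRanges::IRanges(sample(1:5000, n, TRUE), width = 30))
    names(gr2) <- paste0("r", seq_len(n))
    st2 <- contigStacks(gr2, window = 250)
    expect_equal(sum(st2$read_count), n)
    expect_true(all(st2$window_end - st2$window_start <= 250))
})

test_that("CA-richness statistic has the stated extremes and calibration", {
    unif <- backgroundModel(rep(0.25, 4), source = "uniform")
    allCA <- setNames(rep("CACACACACACACACACACA", 5), paste0("s", 1:5))
    r <- caRichness(allCA, bg = unif, nPerm = 200, seed = 3)
    expect_equal(r$observedFraction, 1)
    expect_equal(r$pEmpirical, 1 / 201)
    expect_gt(r$z, 5)
    expect_gt(r$dinucleotide, 0.4)
    ## sequences drawn from the background itself are unremarkable
    bgSeqs <- makeRapSet(10, 200, 0, bg = unif, seed = 4)
    r0 <- caRichness(bgSeqs, bg = unif, nPerm = 200, seed = 5)
    expect_lt(abs(r0$z), 4)
    expect_gt(r0$pEmpirical, 0.01)
    expect_equal(r0$observedFraction, 0.5, tolerance = 0.1)
    expect_true(r0$observedFraction >= 0 && r0$observedFraction <= 1)
})
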