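test_that("translation follows the universal genetic code and frame rules", {
    expect_equal(as.character(translateFrame("TATTCTCCTACTTCTCCTTCT", 0)),
                 c(seq1 = "YSPTSPS"))
    expect_equal(as.character(translateFrame("ATG", 0)), c(seq1 = "M"))
    expect_equal(as.character(translateFrame("AATG", 1)), c(seq1 = "M"))
    expect_error(translateFrame("AT", 0), "too short")
    expect_error(translateFrame("ATGC", 2), "too short")
})

test_that("N-containing codons become X, are warned about, and are excluded", {
    expect_warning(p <- translateFrame("ATGNNNTGG", 0), "excluded")
    expect_equal(as.character(p), c(seq1 = "MXW"))
    f <- suppressWarnings(aaFrequencies("ATGNNNTGG", frames = 0))
    expect_equal(unname(f[c("M", "W")]), c(0.5, 0.5))
})

test_that("three-frame translation covers frames 0..2 of the given strand only", {
    tr <- lapply(translateThreeFrames("TATTCTC"), function(x)
        unname(as.character(x)))
    expect_equal(tr, list(frame0 = "YS", frame1 = "IL", frame2 = "F"))
    expect_length(translateThreeFrames("TATTC"), 3L)
    expect_error(translateThreeFrames("TATT"), "too short")
})

test_that("translation lengths satisfy floor((L - frame)/3) for random input", {
    set.seed(7)
    for (k in 1:25) {
        L <- sample(5:60, 1)
        s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
        for (f in 0:2)
            expect_equal(unname(nchar(as.character(translateFrame(s, f)))),
                         (L - f) %/% 3L)
    }
})

test_that("genetic-code table checksum: 61 sense codons, known multiplicities", {
    expect_length(senseCodons(), 61L)
    m <- codonMultiplicity()
    expect_equal(sum(m), 61L)
    expect_true(all(m[c("L", "S", "R")] == 6L))
    expect_true(all(m[c("A", "G", "P", "T", "V")] == 4L))
    expect_equal(unname(m["I"]), 3L)
    expect_true(all(m[c("C", "D", "E", "F", "H", "K", "N", "Q", "Y")] == 2L))
    expect_true(all(m[c("M", "W")] == 1L))
})

test_that("reverse complement is an involution and maps N to N", {
    expect_equal(as.character(reverseComplement(Biostrings::DNAString("CACAC"))),
                 "GTGTG")
    expect_equal(as.character(reverseComplement(Biostrings::DNAString("N"))),
                 "N")
    set.seed(11)
    for (k in 1:10) {
        s <- paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE), collapse = "")
        x <- Biostrings::DNAString(s)
        expect_equal(as.character(reverseComplement(reverseComplement(x))), s)
    }
})

test_that("RNA input is accepted with U mapped to T and alphabet enforced", {
    expect_equal(as.character(ingestDNA("caucgu")), c(seq1 = "CATCGT"))
    expect_error(ingestDNA("ACGB"), "invalid characters")
    expect_error(ingestDNA(c(a = "ACGT", a = "ACGT")), "unique")
})

test_that("base density profile computes sliding-window fractions", {
    expect_equal(baseDensityProfile("AAAA", "A", 2), c(1, 1, 1))
    expect_equal(baseDensityProfile("ACGT", "A", 4), 0.25)
    expect_error(baseDensityProfile("ACGT", "A", 5), "window")
    ## complementary-base mirror: A-profile of x == reversed T-profile of rc(x)
    set.seed(3)
    s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    rc <- as.character(reverseComplement(Biostrings::DNAString(s)))
    expect_equal(baseDensityProfile(s, "A", 10),
                 rev(baseDensityProfile(rc, "T", 10)))
    ## long-run mean tracks the background frequency of the base
    set.seed(4)
    u <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
    expect_equal(mean(baseDensityProfile(u, "C", 50)), 0.25, tolerance = 0.02)
})

test_that("FASTA write/read round trip is lossless", {
    x <- ingestDNA(c(r1 = "ACGTACGT", r2 = "TTTT", r3 = "ACGTN"))
    f <- tempfile(fileext = ".fasta")
    writeFasta(x, f)
    y <- readDnaFasta(f)
    expect_equal(as.character(y), as.character(x))
    ## empty file -> empty collection, no error
    f0 <- tempfile(fileext = ".fasta")
    file.create(f0)
    expect_length(readDnaFasta(f0), 0L)
})

test_that("BED6 round trip preserves interval, family and strand", {
    f <- tempfile(fileext = ".bed")
    writeLines("chr1\t0\t147\tACRO1\t0\t+", f)
    gr <- readRepeatBed(f)
    expect_equal(BiocGenerics::start(gr), 1L)     # 1-based in memory
    expect_equal(BiocGenerics::end(gr), 147L)     # == 0-based half-open [0,147)
    expect_equal(S4Vectors::mcols(gr)$family, "ACRO1")
    expect_equal(as.character(BiocGenerics::strand(gr)), "+")
    f2 <- tempfile(fileext = ".bed")
    writeRepeatBed(gr, f2)
    gr2 <- readRepeatBed(f2)
    expect_equal(BiocGenerics::start(gr2), BiocGenerics::start(gr))
    expect_equal(S4Vectors::mcols(gr2)$family, "ACRO1")
    ## empty file
    f3 <- tempfile(fileext = ".bed")
    file.create(f3)
    expect_length(readRepeatBed(f3), 0L)
    ## same-family same-strand overlap rejected
    bad <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1, 50), c(100, 160)),
                                  strand = "+")
    S4Vectors::mcols(bad)$family <- "F1"
    expect_error(writeRepeatBed(bad, tempfile()), "overlap")
})

test_that("placement TSV round trip is lossless and 0-based on disk", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 60),
                                 strand = "-")
    names(gr) <- "readA"
    S4Vectors::mcols(gr)$family <- "ACRO1"
    f <- tempfile(fileext = ".tsv")
    writePlacements(gr, f)
    raw <- read.delim(f)
    expect_equal(raw$start, 10L)  # 0-based on disk
    expect_equal(raw$end, 60L)
    gr2 <- readPlacements(f)
    expect_equal(BiocGenerics::start(gr2), 11L)
    expect_equal(names(gr2), "readA")
    expect_equal(S4Vectors::mcols(gr2)$family, "ACRO1")
})
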