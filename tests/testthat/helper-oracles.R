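## Independent oracles and small generators used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Independent affine-gap global alignment score by direct recursion on the
## alignment definition (gap runs charged open + run-length * extend, or the
## open + (L-1) * extend dialect), memoised on (i, j, previous-move). This
## never touches the package's DP matrices.
bruteAlignScore <- function(a, b, mat, go, ge, extendFirst = TRUE) {
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    na <- length(av); nb <- length(bv)
    g1 <- if (extendFirst) go + ge else go
    memo <- new.env(hash = TRUE, parent = emptyenv())
    rec <- function(i, j, prev) {
        key <- paste(i, j, prev)
        v <- memo[[key]]
        if (!is.null(v)) return(v)
        if (i > na && j > nb) v <- 0
        else {
            v <- -Inf
            if (i <= na && j <= nb)
                v <- max(v, mat[av[i], bv[j]] + rec(i + 1L, j + 1L, 0L))
            if (i <= na)
                v <- max(v, -(if (prev == 1L) ge else g1) + rec(i + 1L, j, 1L))
            if (j <= nb)
                v <- max(v, -(if (prev == 2L) ge else g1) + rec(i, j + 1L, 2L))
        }
        memo[[key]] <- v
        v
    }
    rec(1L, 1L, 0L)
}

## Explicit enumeration of every global alignment as a move string (no
## memoisation, no recursion sharing) -- tractable only for tiny inputs.
enumAlignScore <- function(a, b, mat, go, ge, extendFirst = TRUE) {
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    na <- length(av); nb <- length(bv)
    g1 <- if (extendFirst) go + ge else go
    best <- -Inf
    walk <- function(i, j, prev, acc) {
        if (i > na && j > nb) {
            best <<- max(best, acc)
            return(invisible())
        }
        if (i <= na && j <= nb)
            walk(i + 1L, j + 1L, 0L, acc + mat[av[i], bv[j]])
        if (i <= na)
            walk(i + 1L, j, 1L, acc - (if (prev == 1L) ge else g1))
        if (j <= nb)
            walk(i, j + 1L, 2L, acc - (if (prev == 2L) ge else g1))
    }
    walk(1L, 1L, 0L, 0)
    best
}

randomPeptide <- function(maxLen = 6L, alphabet = AA20) {
    paste(sample(alphabet, sample.int(maxLen, 1L), replace = TRUE),
          collapse = "")
}

randomDistribution <- function(k = 20L) {
    v <- stats::rexp(k)
    v / sum(v)
}

## Biostrings' BLOSUM62 (full matrix) for cross-checks
biostringsBlosum62 <- function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
}
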