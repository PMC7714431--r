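#' Reverse complement (re-exported from Biostrings)
#'
#' @name reverseComplement
#' @importFrom Biostrings reverseComplement
#' @export reverseComplement
NULL

#' The packaged BLOSUM62 substitution matrix
#'
#' Reads the canonical BLOSUM62 matrix shipped with the package as a plain
#' text file (20 x 20 block over the standard amino acids, symmetric,
#' half-bit integer scores).
#'
#' @return Integer matrix with amino-acid row/column names.
#' @examples
#' blosum62()["Y", "Y"]  # 7
#' @export
blosum62 <- function() {
    path <- system.file("extdata", "BLOSUM62.txt", package = "rapscan",
                        mustWork = TRUE)
    m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
    storage.mode(m) <- "integer"
    m
}

.checkPeptide <- function(x, what) {
    if (is(x, "AAString") || is(x, "AAStringSet")) x <- as.character(x)
    if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
        stop("'", what, "' must be a single non-empty peptide")
    x <- toupper(x)
    if (grepl("[*X]", x))
        stop("'", what, "' contains '*' or 'X'; strip stops/ambiguous ",
             "residues or segment the sequence before aligning")
    if (grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), x))
        stop("'", what, "' contains non-standard amino-acid letters")
    x
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Strict global alignment of two peptides under an affine gap model
#' (Gotoh's three-state dynamic programme). With the default
#' [scoringScheme()] a gap run of length L costs
#' \code{gapOpen + L * gapExtend} -- the lalign/FASTA reading of "opening
#' penalty 12, extension penalty 2" -- and terminal gaps are penalised.
#' The traceback is deterministic: on ties, substitution is preferred over a
#' gap in the second sequence, which is preferred over a gap in the first.
#'
#' @param a,b peptides (character or \code{AAString}); \code{"*"}/\code{"X"}
#'   are rejected.
#' @param scheme a [ScoringScheme-class].
#' @return An [AlignmentResult-class].
#' @examples
#' needlemanWunsch("YSPTSPS", "YSPTSPS")  # score 38, identities 7
#' @export
needlemanWunsch <- function(a, b, scheme = scoringScheme()) {
    a <- .checkPeptide(a, "a"); b <- .checkPeptide(b, "b")
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    n <- length(av); m <- length(bv)
    S <- scheme@matrix[.AA20, .AA20]
    sub <- S[av, bv, drop = FALSE]
    ge <- scheme@gapExtend
    g1 <- if (scheme@gapDialect == "open-plus-size")
        scheme@gapOpen + ge else scheme@gapOpen

    NEG <- -1e18
    ## state matrices, (n+1) x (m+1); M: ends in substitution,
    ## X: ends with gap in b (consumes a), Y: ends with gap in a (consumes b)
    M <- matrix(NEG, n + 1L, m + 1L)
    X <- matrix(NEG, n + 1L, m + 1L)
    Y <- matrix(NEG, n + 1L, m + 1L)
    pM <- matrix(0L, n + 1L, m + 1L)  # predecessor state: 1=M 2=X 3=Y
    pX <- matrix(0L, n + 1L, m + 1L)
    pY <- matrix(0L, n + 1L, m + 1L)
    M[1L, 1L] <- 0
    free <- !scheme@endGaps
    if (n >= 1L) {
        X[2:(n + 1L), 1L] <- if (free) 0 else -(g1 + (0:(n - 1L)) * ge)
        pX[2:(n + 1L), 1L] <- c(1L, rep(2L, n - 1L))
    }
    if (m >= 1L) {
        Y[1L, 2:(m + 1L)] <- if (free) 0 else -(g1 + (0:(m - 1L)) * ge)
        pY[1L, 2:(m + 1L)] <- c(1L, rep(3L, m - 1L))
    }
    for (i in seq_len(n)) {
        ii <- i + 1L
        for (j in seq_len(m)) {
            jj <- j + 1L
            cand <- c(M[i, j], X[i, j], Y[i, j])
            k <- which.max(cand)          # tie order M > X > Y
            M[ii, jj] <- cand[k] + sub[i, j]
            pM[ii, jj] <- k
            cand <- c(M[i, jj] - g1, X[i, jj] - ge, Y[i, jj] - g1)
            k <- which.max(cand)
            X[ii, jj] <- cand[k]
            pX[ii, jj] <- k
            cand <- c(M[ii, j] - g1, X[ii, j] - g1, Y[ii, j] - ge)
            k <- which.max(cand)
            Y[ii, jj] <- cand[k]
            pY[ii, jj] <- k
        }
    }
    if (free) {
        ## semiglobal: trailing gaps are free; exit at the best cell on the
        ## last row or column and pad with gaps
        besti <- n; bestj <- m; bestv <- -Inf; state <- 1L
        for (jj in 1:(m + 1L)) for (st in 1:3) {
            v <- switch(st, M, X, Y)[n + 1L, jj]
            if (v > bestv) { bestv <- v; besti <- n; bestj <- jj - 1L; state <- st }
        }
        for (ii in 1:(n + 1L)) for (st in 1:3) {
            v <- switch(st, M, X, Y)[ii, m + 1L]
            if (v > bestv) { bestv <- v; besti <- ii - 1L; bestj <- m; state <- st }
        }
        score <- bestv
        ga <- c(rep("-", m - bestj), if (besti < n) av[(besti + 1L):n])
        gb <- c(if (bestj < m) bv[(bestj + 1L):m], rep("-", n - besti))
        i <- besti; j <- bestj
    } else {
        finals <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
        state <- which.max(finals)
        score <- finals[state]
        i <- n; j <- m
        ga <- character(0); gb <- character(0)
    }
    while (i > 0L || j > 0L) {
        if (state == 1L) {
            ga <- c(av[i], ga); gb <- c(bv[j], gb)
            state <- pM[i + 1L, j + 1L]
            i <- i - 1L; j <- j - 1L
        } else if (state == 2L) {
            ga <- c(av[i], ga); gb <- c("-", gb)
            state <- pX[i + 1L, j + 1L]
            i <- i - 1L
        } else {
            ga <- c("-", ga); gb <- c(bv[j], gb)
            state <- pY[i + 1L, j + 1L]
            j <- j - 1L
        }
    }
    ids <- sum(ga == gb & ga != "-")
    new("AlignmentResult", alignedA = paste(ga, collapse = ""),
        alignedB = paste(gb, collapse = ""), score = score,
        identities = as.integer(ids), alignedLength = length(ga))
}

#' Count identical alignment columns
#'
#' Number of columns in which both sequences carry the same residue (gap
#' columns never count). This is the "x out of y amino acids identical"
#' statistic of a translated-repeat vs CTD comparison.
#'
#' @param r an [AlignmentResult-class].
#' @return Integer count.
#' @export
countIdentities <- function(r) {
    stopifnot(is(r, "AlignmentResult"))
    ga <- strsplit(r@alignedA, "", fixed = TRUE)[[1L]]
    gb <- strsplit(r@alignedB, "", fixed = TRUE)[[1L]]
    as.integer(sum(ga == gb & ga != "-"))
}

#' Best equal-length CTD fragment for a query peptide
#'
#' Scans every contiguous window of the CTD of the same length as the query,
#' aligns the query globally against each window, and returns the
#' best-scoring window (ties broken toward the smallest start). This
#' reproduces the comparison of a translated repeat unit against "a fragment
#' of the CTD of equivalent length" when the fragment is not specified.
#'
#' @param query peptide to place.
#' @param ctd CTD (or any reference) peptide, at least as long as the query.
#' @param scheme a [ScoringScheme-class].
#' @return A list with \code{fragmentStart} (0-based offset of the chosen
#'   window) and \code{alignment} (an [AlignmentResult-class]).
#' @examples
#' bestCtdFragment("YSPTSPS", ctdRepeat(4))$fragmentStart  # 0
#' @export
bestCtdFragment <- function(query, ctd, scheme = scoringScheme()) {
    query <- .checkPeptide(query, "query")
    ctd <- .checkPeptide(ctd, "ctd")
    lq <- nchar(query); lc <- nchar(ctd)
    if (lc < lq) stop("'ctd' must be at least as long as 'query'")
    best <- NULL; bestStart <- NA_integer_
    for (s in 0:(lc - lq)) {
        frag <- substr(ctd, s + 1L, s + lq)
        r <- needlemanWunsch(query, frag, scheme)
        if (is.null(best) || r@score > best@score) {
            best <- r; bestStart <- s
        }
    }
    list(fragmentStart = bestStart, alignment = best)
}
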