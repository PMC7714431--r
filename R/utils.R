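#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' seeded package operations do not perturb the user's random stream.
#'
#' @param seed integer seed (\code{NULL} = use the current stream).
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

## sample A/C/G/T integer codes (1..4) from a background model
.sampleBases <- function(n, bgProbs) {
    sample.int(4L, n, replace = TRUE, prob = bgProbs)
}

.BASES <- c("A", "C", "G", "T")

## integer base codes -> one sequence string
.basesToString <- function(b) paste(.BASES[b], collapse = "")
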