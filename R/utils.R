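#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded at \code{seed}, restoring
#' the caller's RNG state afterwards, so seeded package functions never
#' perturb the user's random stream. A \code{NULL} seed evaluates the
#' code under the current stream.
#'
#' @param seed integer seed or \code{NULL}.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

#' Derive a deterministic per-stage child seed
#'
#' Hashes a stage name into the master seed so that adding or reordering
#' pipeline stages never perturbs the random stream of other stages.
#' The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed in [0, 2^31 - 2].
#' @export
stageSeed <- function(master, stage) {
    h <- 0
    for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483629
    as.integer((as.numeric(master) %% 2147483629 * 7919 + h) %% 2147483629)
}

#' Numerator/denominator/fraction triple with one-decimal percentage
#'
#' Every fraction the pipeline reports carries its numerator and
#' denominator; the percentage is rounded half-to-even to one decimal
#' (R's \code{round}), one fixed convention for all printed shares.
#'
#' @param num,den non-negative numerator and positive denominator.
#' @param label optional description.
#' @return list with \code{numerator}, \code{denominator},
#'   \code{fraction}, \code{pct} and \code{label}.
#' @examples
#' fractionTriple(2172, 7862)$pct  # 27.6
#' @export
fractionTriple <- function(num, den, label = NA_character_) {
    stopifnot(den > 0, num >= 0)
    list(numerator = num, denominator = den, fraction = num / den,
         pct = round(100 * num / den, 1), label = label)
}

# row-wise minimum of a numeric matrix, C-speed via pmin
rowMins_ <- function(m) {
    if (ncol(m) == 1L) return(m[, 1L])
    do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# enumerate all distinct permutations of a label vector (multiset
# permutations); used by the exhaustive modes of the permutation tests
allLabelPermutations <- function(labels) {
    labels <- as.character(labels)
    rec <- function(remaining) {
        if (length(remaining) == 0L) return(list(character(0)))
        out <- list()
        for (u in unique(remaining)) {
            rest <- remaining[-match(u, remaining)]
            for (tail in rec(rest)) out[[length(out) + 1L]] <- c(u, tail)
        }
        out
    }
    rec(labels)
}
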