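#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so package functions never leak RNG state into the
#' caller's session.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a consistent prefix for user-input contract violations
abort_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] used throughout the package so every
#' module corrects for multiple testing the same way.
#'
#' @param p numeric vector of raw p-values.
#' @return numeric vector of BH-adjusted p-values.
#' @keywords internal
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
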