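# Internal helpers: seeded evaluation, seed streams, Fermi switch.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so library calls do not disturb user randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic seed stream: hashes a master seed together with integer
# labels into a positive 32-bit integer, so every sub-computation (cycle,
# population entry, mutation, trajectory) owns a reproducible sub-seed.
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + (abs(as.numeric(k)) %% 2147483647) + 1) %% 2147483629
  }
  as.integer(h %% 2147483562 + 1)
}

#' Fermi switching function
#'
#' Smooth step `1 / (1 + exp(-z / w))`, rising from 0 to 1 around `z = 0`
#' over a width `w`. Used both for the folding-probability proxy (switching
#' on the MSD threshold margin) and for the geometric switches of the
#' continuous lasso variable.
#'
#' @param z numeric margin(s).
#' @param w switching width (same units as `z`), default 0.2.
#' @return values in (0, 1).
#' @examples
#' fermi(0)        # 0.5 at the threshold
#' fermi(1, 0.2)   # ~1 well past it
#' @export
fermi <- function(z, w = 0.2) {
  1 / (1 + exp(-z / w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
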