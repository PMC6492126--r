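#' Population reference distribution of the incomplete covariate
#'
#' The marginal distribution of the incomplete covariate in the target
#' population, used to calibrate the imputation model. In `"fixed"` mode
#' the distribution is treated as known without error (a census or
#' equivalent) and is used as-is in every imputation. In `"estimated"`
#' mode it was estimated in an external sample of size `n_ex`, and each
#' imputation draws a fresh value from the normal approximation
#' \eqn{N(\hat p,\; \hat p (1 - \hat p)/n^{ex})} so that reference
#' uncertainty propagates into the between-imputation variance.
#'
#' @param proportions named probability vector over the levels of the
#'   incomplete covariate; must sum to 1 within `1e-6` (then renormalised
#'   exactly).
#' @param mode `"fixed"` or `"estimated"`.
#' @param n_ex external sample size (required in `"estimated"` mode).
#' @return An object of class `"population_reference"` with fields
#'   `proportions`, `mode`, `n_ex` and per-level `se` (zero in fixed mode).
#' @examples
#' population_reference(c("0" = 0.3, "1" = 0.7))
#' population_reference(c("0" = 0.3, "1" = 0.7), mode = "estimated", n_ex = 10000)
#' @export
population_reference <- function(proportions, mode = c("fixed", "estimated"),
                                 n_ex = NULL) {
  mode <- match.arg(mode)
  if (is.list(proportions)) proportions <- unlist(proportions)
  if (is.null(names(proportions)) && length(proportions) == 2L)
    names(proportions) <- c("0", "1")
  if (is.null(names(proportions)))
    stop("proportions must be named by the levels of the incomplete covariate")
  if (!is.numeric(proportions) || any(!is.finite(proportions)) ||
      any(proportions <= 0) || any(proportions >= 1))
    stop("reference proportions must lie strictly in (0, 1)")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("reference proportions must sum to 1 within 1e-6 (got ",
         format(sum(proportions)), ")")
  proportions <- proportions / sum(proportions)
  if (mode == "estimated") {
    if (is.null(n_ex)) stop("estimated mode requires the external sample size n_ex")
    stopifnot(is.numeric(n_ex), length(n_ex) == 1L, n_ex >= 2)
    se <- sqrt(proportions * (1 - proportions) / n_ex)
  } else {
    if (!is.null(n_ex)) stop("fixed mode does not take n_ex")
    se <- proportions * 0
  }
  structure(list(proportions = proportions, mode = mode,
                 n_ex = n_ex, se = se),
            class = "population_reference")
}

#' @export
print.population_reference <- function(x, ...) {
  cat("Population reference (", x$mode,
      if (x$mode == "estimated") paste0(", n_ex = ", x$n_ex), "):\n", sep = "")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Draw the reference proportions used in one imputation
#'
#' In fixed mode the stored proportions are returned unchanged: the
#' reference is treated as invariant so no extra uncertainty is injected.
#' In estimated mode each level's proportion is drawn as
#' \eqn{\tilde p = \hat p + \tilde z \cdot SE(\hat p)} with
#' \eqn{\tilde z \sim N(0,1)}; draws with any component outside (0, 1) are
#' rejected and redrawn. For more than two levels the drawn vector is
#' renormalised onto the simplex; for two levels only the second level is
#' drawn and the first is its complement.
#'
#' @param ref a [population_reference()].
#' @param max_tries rejection-sampling cap.
#' @return Named probability vector over the levels.
#' @export
draw_population_proportion <- function(ref, max_tries = 1000L) {
  stopifnot(inherits(ref, "population_reference"))
  p <- ref$proportions
  if (ref$mode == "fixed") return(p)
  K <- length(p)
  for (i in seq_len(max_tries)) {
    if (K == 2L) {
      d2 <- p[2L] + stats::rnorm(1L) * ref$se[2L]
      draw <- c(1 - d2, d2)
      names(draw) <- names(p)
    } else {
      draw <- p + stats::rnorm(K) * ref$se
    }
    if (all(draw > 0 & draw < 1)) {
      if (K > 2L) draw <- draw / sum(draw)
      return(draw)
    }
  }
  stop("could not draw reference proportions inside (0, 1) after ",
       max_tries, " tries")
}
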