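#' Selection-model specification for missingness in x
#'
#' Describes the logistic selection model
#' \deqn{\mathrm{logit}\, p(r = 1 \mid x, y) = \alpha_0 + \alpha_x x + \alpha_y y,}
#' where \eqn{r} is the response indicator of the incomplete covariate
#' \eqn{x} (1 = observed). The four mechanisms of increasing complexity are
#' \describe{
#'   \item{M1}{MCAR: \eqn{\alpha_x = \alpha_y = 0}.}
#'   \item{M2}{MAR conditional on the outcome: \eqn{\alpha_x = 0}.}
#'   \item{M3}{MNAR dependent on \eqn{x}: \eqn{\alpha_y = 0}.}
#'   \item{M4}{MNAR dependent on \eqn{x} and \eqn{y}.}
#' }
#'
#' @param mechanism one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param alpha0 intercept of the selection model (log-odds scale).
#' @param alpha_x coefficient of the incomplete covariate. For a binary
#'   covariate, a scalar multiplying the 0/1 indicator of the second level.
#'   For a categorical covariate, a named vector of per-level log-odds
#'   (levels not named get 0). Must be zero/absent under M1 and M2.
#' @param alpha_y coefficient of the binary outcome. Must be zero under M1
#'   and M3.
#' @return An object of class `"selection_spec"`.
#' @examples
#' selection_spec("M1", alpha0 = log(0.55 / 0.45))
#' selection_spec("M4", alpha0 = 0.75, alpha_x = -1.5, alpha_y = 1.5)
#' @export
selection_spec <- function(mechanism = c("M1", "M2", "M3", "M4"),
                           alpha0, alpha_x = 0, alpha_y = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(alpha0), length(alpha0) == 1L, is.finite(alpha0),
            is.numeric(alpha_x), all(is.finite(alpha_x)),
            is.numeric(alpha_y), length(alpha_y) == 1L, is.finite(alpha_y))
  if (mechanism %in% c("M1", "M2") && any(alpha_x != 0))
    stop("alpha_x must be 0 under ", mechanism, " (missingness cannot depend on x)")
  if (mechanism %in% c("M1", "M3") && alpha_y != 0)
    stop("alpha_y must be 0 under ", mechanism, " (missingness cannot depend on y)")
  structure(list(mechanism = mechanism, alpha0 = alpha0,
                 alpha_x = alpha_x, alpha_y = alpha_y),
            class = "selection_spec")
}

#' @export
print.selection_spec <- function(x, ...) {
  cat(sprintf("Selection model %s: logit p(r=1) = %.4g", x$mechanism, x$alpha0))
  if (any(x$alpha_x != 0)) cat(sprintf(" + (%s) x", paste(format(x$alpha_x), collapse = ", ")))
  if (x$alpha_y != 0) cat(sprintf(" + (%.4g) y", x$alpha_y))
  cat("\n")
  invisible(x)
}

#' Default selection-model parameterisations of the simulation studies
#'
#' Returns the four selection specifications used throughout the binary
#' simulation design: strong response odds ratios `alpha_y = 1.5`
#' (OR 4.5) and `alpha_x = -1.5` (OR 0.2), with intercepts chosen so that
#' roughly 45% of `x` is set to missing. For M1 the intercept is exactly
#' `log(0.55/0.45)`; for M2--M4 the intercepts are -0.2, 1.35 and 0.75.
#'
#' @return Named list of [selection_spec()] objects `M1`..`M4`.
#' @export
default_selection_specs <- function() {
  list(M1 = selection_spec("M1", alpha0 = log(0.55 / 0.45)),
       M2 = selection_spec("M2", alpha0 = -0.2, alpha_y = 1.5),
       M3 = selection_spec("M3", alpha0 = 1.35, alpha_x = -1.5),
       M4 = selection_spec("M4", alpha0 = 0.75, alpha_x = -1.5, alpha_y = 1.5))
}

check_probs <- function(p, what = "probabilities", tol = 1e-6) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop(what, " must lie strictly in (0, 1)")
  if (length(p) > 1 && abs(sum(p) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

#' Simulate a full (completely observed) dataset
#'
#' Draws the incomplete-to-be covariate `x` from a Bernoulli or categorical
#' distribution with population proportions `p_x`, and the binary outcome
#' `y` from the logistic analysis model
#' \deqn{\mathrm{logit}\, p(y = 1 \mid x) = \beta_0 + \beta_x x.}
#' The default parameters are the simulation-design values
#' \eqn{p(x{=}1) = 0.7}, \eqn{\beta_0 = \ln 0.5}, \eqn{\beta_x = \ln 1.5}.
#'
#' @param n sample size.
#' @param p_x scalar probability of `x = "1"` (binary case), or a named
#'   probability vector over K declared levels. Categorical draws use the
#'   inverse-CDF on the declared level order.
#' @param beta0 log-odds of `y = 1` at the base level of `x`.
#' @param beta_x log odds ratio for the second level (scalar, binary) or a
#'   vector of per-level log odds ratios for levels 2..K.
#' @param levels level labels; defaults to `c("0", "1")` for scalar `p_x`
#'   or `names(p_x)` otherwise. The first level is the base level of the
#'   analysis model.
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   first so the dataset is reproducible in isolation.
#' @return A `data.frame` with columns `x` (factor) and `y` (integer 0/1),
#'   fully observed.
#' @examples
#' d <- simulate_full_data(1000, seed = 1)
#' mean(d$x == "1")
#' @export
simulate_full_data <- function(n, p_x = 0.7, beta0 = log(0.5), beta_x = log(1.5),
                               levels = NULL, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (length(p_x) == 1L) {
    check_probs(p_x, "p_x")
    levels <- levels %||% c("0", "1")
    stopifnot(length(levels) == 2L)
    p_vec <- stats::setNames(c(1 - p_x, p_x), levels)
  } else {
    levels <- levels %||% names(p_x)
    if (is.null(levels)) stop("categorical p_x must be named or levels supplied")
    check_probs(p_x, "p_x")
    p_vec <- stats::setNames(as.numeric(p_x), levels)
  }
  K <- length(levels)
  stopifnot(length(beta_x) == K - 1L, all(is.finite(c(beta0, beta_x))))
  # inverse-CDF draw on the declared level order
  u <- stats::runif(n)
  idx <- findInterval(u, cumsum(p_vec)[-K]) + 1L
  x <- factor(levels[idx], levels = levels)
  eta <- beta0 + c(0, beta_x)[idx]
  y <- stats::rbinom(n, 1L, expit(eta))
  data.frame(x = x, y = y)
}

#' Apply a selection model to blank out values of x
#'
#' Simulates the response indicator `r` from the selection model and sets
#' `x` to `NA` where `r = 0`. The input must have no prior missingness in
#' `x`.
#'
#' @param data data frame with columns `x` (factor) and `y` (0/1).
#' @param spec a [selection_spec()].
#' @param x_var name of the incomplete covariate column.
#' @param seed optional integer seed.
#' @return The data frame with `x` partially blanked and an integer column
#'   `r` added (1 = observed).
#' @examples
#' d <- simulate_full_data(1000, seed = 1)
#' d <- apply_selection(d, selection_spec("M1", log(0.55 / 0.45)))
#' mean(d$r == 0)
#' @export
apply_selection <- function(data, spec, x_var = "x", seed = NULL) {
  stopifnot(inherits(spec, "selection_spec"), x_var %in% names(data))
  if (anyNA(data[[x_var]])) stop("data already contains missing values in ", x_var)
  if (!is.null(seed)) set.seed(seed)
  x <- data[[x_var]]
  if (!is.factor(x)) x <- factor(x)
  lev <- levels(x)
  if (length(spec$alpha_x) == 1L && is.null(names(spec$alpha_x))) {
    # scalar: coefficient of the indicator of the second level (binary coding)
    ax <- stats::setNames(c(0, rep(spec$alpha_x, length(lev) - 1L)), lev)
  } else {
    ax <- stats::setNames(rep(0, length(lev)), lev)
    unknown <- setdiff(names(spec$alpha_x), lev)
    if (length(unknown)) stop("alpha_x names not levels of x: ", paste(unknown, collapse = ", "))
    ax[names(spec$alpha_x)] <- spec$alpha_x
  }
  eta <- spec$alpha0 + ax[as.integer(x)] + spec$alpha_y * data$y
  r <- stats::rbinom(nrow(data), 1L, expit(eta))
  data[[x_var]][r == 0L] <- NA
  data$r <- r
  data
}

#' Simulate an external reference sample for the population distribution
#'
#' Emulates estimating the population marginal distribution of `x` in an
#' external dataset of size `n_ex` drawn from the same population: the
#' reference proportions are the external empirical proportions and each
#' level's standard error is \eqn{\sqrt{\hat p (1-\hat p)/n^{ex}}}.
#'
#' @param n_ex external sample size (at least 2).
#' @param p_x_pop true population proportion of `x = "1"` (scalar) or a
#'   named probability vector over levels.
#' @param levels optional level labels (as in [simulate_full_data()]).
#' @param seed optional integer seed.
#' @return A [population_reference()] in `"estimated"` mode.
#' @examples
#' simulate_external_reference(10000, 0.7, seed = 1)
#' @export
simulate_external_reference <- function(n_ex, p_x_pop = 0.7, levels = NULL, seed = NULL) {
  stopifnot(n_ex >= 2)
  if (!is.null(seed)) set.seed(seed)
  d <- simulate_full_data(n_ex, p_x = p_x_pop, beta0 = 0,
                          beta_x = rep(0, max(1L, length(p_x_pop) - 1L)),
                          levels = levels)
  p_hat <- prop.table(table(d$x))
  if (any(p_hat == 0) || any(p_hat == 1))
    stop("degenerate external sample: a level has proportion 0 or 1, ",
         "its sampling standard error is undefined for calibration draws")
  population_reference(stats::setNames(as.numeric(p_hat), names(p_hat)),
                       mode = "estimated", n_ex = n_ex)
}

#' Simulate a case-study-like cohort with a 4-level incomplete covariate
#'
#' Builds a synthetic dataset with the structure of an electronic-health-
#' records prevalence study: a categorical covariate with four levels
#' (such as ethnic group), independent categorical confounders (age group,
#' sex, deprivation quintile by default), a binary outcome generated from a
#' logistic model on all covariates, and MNAR selection on the covariate's
#' level and the outcome. This is synthetic plumbing for exercising the
#' multinomial calibration path end to end; it makes no claim to emulate
#' any real database beyond the categorical structure.
#'
#' @param n sample size.
#' @param level_probs named probability vector over the 4 covariate levels.
#' @param confounders named list of named probability vectors, one per
#'   categorical confounder (generated independently of each other and of
#'   the covariate).
#' @param outcome list with `intercept`, `x` (named log-OR vector over
#'   non-base covariate levels) and optionally one named log-OR vector per
#'   confounder (non-base levels).
#' @param selection a [selection_spec()] with a named `alpha_x`; default is
#'   MNAR on the covariate level and the outcome.
#' @param seed optional integer seed.
#' @return A `data.frame` with columns `x`, the confounders, `y` and `r`.
#' @export
simulate_casestudy_cohort <- function(n,
  level_probs = c(White = 0.60, Asian = 0.18, Black = 0.13, Other = 0.09),
  confounders = list(
    age_group = c("40-49" = 0.30, "50-59" = 0.28, "60-69" = 0.24, "70+" = 0.18),
    sex       = c(male = 0.49, female = 0.51),
    townsend  = c(q1 = 0.2, q2 = 0.2, q3 = 0.2, q4 = 0.2, q5 = 0.2)),
  outcome = list(intercept = -3,
                 x = c(Asian = 1.3, Black = 0.8, Other = 0.4),
                 age_group = c("50-59" = 0.5, "60-69" = 1.0, "70+" = 1.4),
                 sex = c(female = -0.2),
                 townsend = c(q2 = 0.1, q3 = 0.2, q4 = 0.3, q5 = 0.45)),
  selection = selection_spec("M4", alpha0 = 1.6,
                             alpha_x = c(Asian = -1.0, Black = -0.9, Other = -1.2),
                             alpha_y = 0.3),
  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_probs(level_probs, "level_probs")
  if (length(level_probs) != 4L) stop("level_probs must have 4 levels")
  lev <- names(level_probs)
  u <- stats::runif(n)
  x <- factor(lev[findInterval(u, cumsum(level_probs)[-4]) + 1L], levels = lev)
  d <- data.frame(x = x)
  for (nm in names(confounders)) {
    p <- check_probs(confounders[[nm]], nm)
    ul <- names(p)
    d[[nm]] <- factor(ul[findInterval(stats::runif(n), cumsum(p)[-length(p)]) + 1L],
                      levels = ul)
  }
  eta <- rep(outcome$intercept, n)
  add_effect <- function(eta, col, coefs) {
    v <- stats::setNames(rep(0, nlevels(col)), levels(col))
    v[names(coefs)] <- coefs
    eta + v[as.integer(col)]
  }
  eta <- add_effect(eta, d$x, outcome$x)
  for (nm in names(confounders))
    if (!is.null(outcome[[nm]])) eta <- add_effect(eta, d[[nm]], outcome[[nm]])
  d$y <- stats::rbinom(n, 1L, expit(eta))
  apply_selection(d, selection)
}
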