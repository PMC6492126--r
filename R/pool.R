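#' Fit the substantive analysis model to a completed dataset
#'
#' ML logistic regression of the binary outcome on the covariates, as
#' applied to each completed dataset (or to the full data / complete
#' records for the comparator analyses).
#'
#' @param data a (completed) data frame.
#' @param formula analysis-model formula, e.g. `y ~ x` or
#'   `y ~ x + age_group + sex + townsend`.
#' @return An object of class `"analysis_fit"`: `estimates` (named
#'   coefficient vector), `vcov`, `df_residual`, and the `glm` fit.
#' @export
fit_analysis_model <- function(data, formula) {
  y_var <- all.vars(formula[[2]])
  yv <- data[[y_var]]
  if (is.null(yv) || !all(yv %in% c(0L, 1L)))
    stop("outcome ", y_var, " must be binary 0/1 with no missing values")
  fit <- tryCatch(
    stats::glm(formula, family = stats::binomial(), data = data),
    error = function(e) stop("analysis model inestimable (degenerate design: ",
                             conditionMessage(e), ")", call. = FALSE))
  est <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(est)) || anyNA(est))
    stop("analysis model did not converge or has an inestimable term ",
         "(empty cell or constant covariate)")
  if (any(abs(est) > 15))
    stop("analysis model shows signs of separation (|coefficient| > 15)")
  structure(list(estimates = est, vcov = stats::vcov(fit),
                 df_residual = fit$df.residual, fit = fit),
            class = "analysis_fit")
}

#' Combine per-imputation estimates with Rubin's rules
#'
#' Pools M per-imputation estimates of each parameter: pooled point
#' estimate \eqn{\bar Q} (mean), within-imputation variance W (mean of the
#' squared model SEs), between-imputation variance B (sample variance of
#' the estimates), total variance \eqn{T = W + (1 + 1/M) B}, degrees of
#' freedom, t-based confidence intervals, fraction of missing information,
#' relative efficiency versus infinite imputations, and the Monte Carlo
#' standard error of the pooled point estimate.
#'
#' @param estimates M x p matrix (or list of length-M vectors) of
#'   per-imputation coefficient estimates.
#' @param variances M x p matrix (or list) of their squared model SEs.
#' @param conf_level confidence level for the intervals.
#' @param df_method `"barnard-rubin"` (small-sample adjusted, the default
#'   of mainstream MI software) or `"rubin"` (the classical
#'   \eqn{(M-1)(1 + W/((1+1/M)B))^2}).
#' @param df_complete complete-data residual degrees of freedom, used by
#'   the Barnard-Rubin adjustment; `Inf` recovers the classical rule.
#' @param fmi_method `"variance"` for \eqn{(B + B/M)/T} or
#'   `"df-adjusted"` for \eqn{(r + 2/(\nu+3))/(r+1)} with
#'   \eqn{r = (1+1/M)B/W}.
#' @return A data frame of class `"pooled_mi"` with one row per parameter:
#'   `term`, `estimate`, `W`, `B`, `T`, `se`, `df`, `conf_low`,
#'   `conf_high`, `fmi`, `re`, `mcse`, `M`.
#' @examples
#' pool_rubin(cbind(c(1, 2, 3)), cbind(c(1, 1, 1)))
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95,
                       df_method = c("barnard-rubin", "rubin"),
                       df_complete = Inf,
                       fmi_method = c("variance", "df-adjusted")) {
  df_method <- match.arg(df_method)
  fmi_method <- match.arg(fmi_method)
  if (is.list(estimates)) estimates <- do.call(rbind, estimates)
  if (is.list(variances)) variances <- do.call(rbind, variances)
  estimates <- as.matrix(estimates); variances <- as.matrix(variances)
  M <- nrow(estimates)
  if (M < 2L) stop("Rubin's rules need M >= 2 (between-imputation variance ",
                   "is undefined for M = 1)")
  stopifnot(all(dim(estimates) == dim(variances)),
            all(is.finite(estimates)), all(is.finite(variances)),
            all(variances >= 0), conf_level > 0, conf_level < 1)

  qbar <- colMeans(estimates)
  W <- colMeans(variances)
  B <- apply(estimates, 2L, stats::var)
  Tv <- W + (1 + 1 / M) * B

  lambda <- ifelse(Tv > 0, (B + B / M) / Tv, 0)
  df <- ifelse(B > 0, (M - 1) * (1 + W / ((1 + 1 / M) * B))^2, Inf)
  if (df_method == "barnard-rubin" && is.finite(df_complete)) {
    df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
    df <- 1 / (1 / df + 1 / df_obs)
  }

  r <- ifelse(W > 0, (1 + 1 / M) * B / W, Inf)
  fmi <- switch(fmi_method,
                "variance" = lambda,
                "df-adjusted" = ifelse(is.finite(r), (r + 2 / (df + 3)) / (r + 1), 1))
  if (any(Tv == 0 & B > 0)) stop("total variance is 0: FMI undefined")
  re <- 1 / (1 + fmi / M)
  mcse <- sqrt(B / M)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  se <- sqrt(Tv)
  out <- data.frame(term = colnames(estimates) %||% paste0("par", seq_along(qbar)),
                    estimate = qbar, W = W, B = B, T = Tv, se = se, df = df,
                    conf_low = qbar - tq * se, conf_high = qbar + tq * se,
                    fmi = fmi, re = re, mcse = mcse, M = M,
                    row.names = NULL)
  class(out) <- c("pooled_mi", "data.frame")
  out
}

#' Recompute FMI, relative efficiency and Monte Carlo error on a pooled result
#'
#' Augments (or recomputes on) a [pool_rubin()] result: FMI under the
#' chosen estimator, relative efficiency \eqn{(1 + FMI/M)^{-1}} versus an
#' infinite number of imputations, and the Monte Carlo standard error of
#' the pooled point estimate, \eqn{\sqrt{B/M}}.
#'
#' @param pooled a `"pooled_mi"` data frame.
#' @param fmi_method see [pool_rubin()].
#' @return The pooled data frame with `fmi`, `re`, `mcse` recomputed.
#' @export
fmi_and_efficiency <- function(pooled, fmi_method = c("variance", "df-adjusted")) {
  fmi_method <- match.arg(fmi_method)
  stopifnot(inherits(pooled, "pooled_mi"))
  if (any(pooled$T == 0 & pooled$B > 0)) stop("total variance is 0: FMI undefined")
  M <- pooled$M
  if (fmi_method == "variance") {
    pooled$fmi <- ifelse(pooled$T > 0, (pooled$B + pooled$B / M) / pooled$T, 0)
  } else {
    r <- ifelse(pooled$W > 0, (1 + 1 / M) * pooled$B / pooled$W, Inf)
    pooled$fmi <- ifelse(is.finite(r), (r + 2 / (pooled$df + 3)) / (r + 1), 1)
  }
  pooled$re <- 1 / (1 + pooled$fmi / M)
  pooled$mcse <- sqrt(pooled$B / M)
  pooled
}

#' Fit the analysis model to every completed dataset and pool
#'
#' Convenience wrapper: applies [fit_analysis_model()] to each imputation
#' of an [multiply_impute()] result and combines with [pool_rubin()].
#'
#' @param mi an `"mi_result"`.
#' @param formula analysis-model formula.
#' @param ... passed to [pool_rubin()].
#' @return A `"pooled_mi"` data frame.
#' @export
pool_completed <- function(mi, formula, ...) {
  stopifnot(inherits(mi, "mi_result"))
  fits <- lapply(mi$imputations, fit_analysis_model, formula = formula)
  est <- do.call(rbind, lapply(fits, function(f) f$estimates))
  va <- do.call(rbind, lapply(fits, function(f) diag(f$vcov)))
  args <- list(...)
  if (is.null(args$df_complete)) args$df_complete <- fits[[1L]]$df_residual
  do.call(pool_rubin, c(list(estimates = est, variances = va), args))
}

#' @export
print.pooled_mi <- function(x, digits = 4, ...) {
  cat("Rubin's-rules pooled estimates (M =", x$M[1L], "imputations)\n")
  print(format(as.data.frame(x)[c("term", "estimate", "se", "df",
                                  "conf_low", "conf_high", "fmi", "re", "mcse")],
               digits = digits), row.names = FALSE)
  invisible(x)
}
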