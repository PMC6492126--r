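#' Target marginal distribution of x among nonrespondents
#'
#' By the law of total probability the population proportion of a level j
#' decomposes over respondents and nonrespondents,
#' \deqn{p(x = j) = p(x = j \mid r = 1)\, p(r = 1) + p(x = j \mid r = 0)\, p(r = 0),}
#' so the proportion that the nonrespondents must carry is
#' \deqn{p(x = j \mid r = 0) = \frac{p(x = j) - p(x = j \mid r = 1)\, p(r = 1)}{1 - p(r = 1)}.}
#' This is the quantity the calibrated delta adjustment is solved to
#' reproduce. Applied componentwise for a categorical covariate.
#'
#' @param p_pop population proportion(s) of the level(s), possibly named.
#' @param p_obs observed-data proportion(s) of the level(s) among complete
#'   records.
#' @param p_r probability of response (x observed), strictly in (0, 1).
#' @return The implied nonrespondent proportion(s), same shape as `p_pop`.
#'   If any component falls outside (0, 1) a calibration-infeasibility
#'   error is raised naming the offending level: no data on the
#'   nonrespondents can reconcile that population figure with what was
#'   observed at this response rate.
#' @examples
#' target_missing_proportion(0.7, 0.8, 0.55)  # 0.5778
#' @export
target_missing_proportion <- function(p_pop, p_obs, p_r) {
  stopifnot(length(p_r) == 1L, is.finite(p_r))
  if (p_r <= 0 || p_r >= 1) stop("p_r must lie strictly in (0, 1)")
  stopifnot(length(p_pop) == length(p_obs))
  tgt <- (p_pop - p_obs * p_r) / (1 - p_r)
  bad <- !is.finite(tgt) | tgt <= 0 | tgt >= 1
  if (any(bad)) {
    lab <- if (!is.null(names(tgt))) names(tgt)[bad] else which(bad)
    stop("calibration infeasible for level(s) ", paste(lab, collapse = ", "),
         ": implied nonrespondent proportion(s) ",
         paste(format(tgt[bad], digits = 4), collapse = ", "),
         " outside (0, 1); the population distribution is incompatible with ",
         "the observed data and response rate")
  }
  tgt
}

#' Model-implied marginal proportion of x = 1 among nonrespondents
#'
#' For a binary incomplete covariate, the proportion of x = 1 the
#' imputation model implies for the nonrespondents once its intercept is
#' shifted by `delta`:
#' \deqn{\frac{1}{n_{mis}} \sum_i \mathrm{expit}(\eta_i + \delta),}
#' where \eqn{\eta_i} is the (unshifted) linear predictor of nonrespondent
#' i under the imputation model. Strictly increasing in `delta`.
#'
#' @param delta intercept offset.
#' @param eta numeric vector of linear predictors for the nonrespondents.
#' @return Scalar proportion in (0, 1).
#' @export
predicted_missing_proportion <- function(delta, eta) {
  if (length(eta) == 0L) stop("no nonrespondent rows: nothing to calibrate")
  stopifnot(length(delta) == 1L, is.finite(delta), all(is.finite(eta)))
  mean(expit(eta + delta))
}

new_delta_solution <- function(delta, residual, iterations, converged) {
  structure(list(delta = delta, residual = residual,
                 iterations = iterations, converged = converged),
            class = "delta_solution")
}

#' @export
print.delta_solution <- function(x, ...) {
  cat("delta:", format(x$delta, digits = 8),
      "| max |residual|:", format(max(abs(x$residual)), digits = 3),
      "| iterations:", x$iterations,
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Solve the binary calibration equation by interval bisection
#'
#' Finds the intercept offset `delta` such that
#' [predicted_missing_proportion()] equals `target`. The left-hand side is
#' strictly increasing in `delta`, so the root is unique; it is bracketed
#' (expanding the initial bracket geometrically up to +/-100 if needed,
#' beyond which expit is flat at double precision) and found by bisection
#' to a tolerance on the proportion scale.
#'
#' @param eta linear predictors of the nonrespondents under the imputation
#'   model (without the offset).
#' @param target required nonrespondent proportion of x = 1, in (0, 1);
#'   see [target_missing_proportion()].
#' @param tol convergence tolerance on the proportion scale.
#' @param bracket initial search interval for delta.
#' @return A `"delta_solution"`: `delta`, `residual` (achieved minus
#'   target), `iterations`, `converged`.
#' @examples
#' solve_delta_binary(rep(0, 10), 0.7)$delta  # qlogis(0.7)
#' @export
solve_delta_binary <- function(eta, target, tol = 1e-10, bracket = c(-30, 30)) {
  stopifnot(length(target) == 1L, is.finite(target))
  if (target <= 0 || target >= 1) stop("target must lie strictly in (0, 1)")
  f <- function(d) predicted_missing_proportion(d, eta) - target
  lo <- bracket[1]; hi <- bracket[2]
  while (f(lo) > 0 && lo > -100) lo <- max(-100, 2 * lo)
  while (f(hi) < 0 && hi < 100) hi <- min(100, 2 * hi)
  if (f(lo) > 0 || f(hi) < 0)
    stop("bisection bracket [", lo, ", ", hi, "] does not enclose the root")
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol || (hi - lo) / 2 < .Machine$double.eps * max(1, abs(mid)) ||
        it >= 200L) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  new_delta_solution(mid, fm, it, abs(fm) <= tol)
}

# per-row softmax probabilities of the K-1 non-base levels given the
# linear-predictor matrix (n x K-1) and offsets delta (length K-1)
softmax_nonbase <- function(eta, delta) {
  e <- exp(sweep(eta, 2L, delta, "+"))
  e / (1 + rowSums(e))
}

#' Solve the multinomial calibration system
#'
#' For a categorical incomplete covariate with K levels (level 1 the base),
#' finds the per-level intercept offsets \eqn{\delta_j, j = 2..K}, such
#' that the model-implied nonrespondent marginal proportions
#' \deqn{\frac{1}{n_{mis}} \sum_i
#'   \frac{\exp(\eta_{ij} + \delta_j)}{1 + \sum_{j'} \exp(\eta_{ij'} + \delta_{j'})}}
#' match the targets simultaneously. Solved by a damped Newton method with
#' the exact Jacobian
#' \eqn{J_{jl} = \mathrm{mean}_i\, p_{ij} (1[j = l] - p_{il})}; if Newton
#' fails to converge, a cyclic per-coordinate bisection fallback is used
#' (each equation is increasing in its own offset).
#'
#' @param eta numeric matrix (nonrespondents x K-1) of non-base linear
#'   predictors under the imputation model.
#' @param targets required nonrespondent proportions of levels 2..K, each
#'   in (0, 1) with sum < 1 (the base level takes the complement).
#' @param tol convergence tolerance on the proportion scale (max norm).
#' @param max_iter Newton iteration cap.
#' @return A `"delta_solution"` with a length K-1 `delta` vector and
#'   per-level residuals.
#' @export
solve_delta_categorical <- function(eta, targets, tol = 1e-10, max_iter = 100L) {
  eta <- as.matrix(eta)
  J <- ncol(eta)
  stopifnot(length(targets) == J, nrow(eta) >= 1L, all(is.finite(eta)))
  if (any(targets <= 0) || any(targets >= 1) || sum(targets) >= 1)
    stop("calibration infeasible: targets must lie in (0, 1) and sum to < 1 ",
         "(base level takes the complement)")
  delta <- rep(0, J)
  g <- function(d) colMeans(softmax_nonbase(eta, d)) - targets
  res <- g(delta)
  it <- 0L
  while (max(abs(res)) > tol && it < max_iter) {
    it <- it + 1L
    P <- softmax_nonbase(eta, delta)
    jac <- crossprod(P, -P) / nrow(P)
    diag(jac) <- diag(jac) + colMeans(P)
    step <- tryCatch(solve(jac, -res), error = function(e) NULL)
    if (is.null(step)) break
    # damping: halve until the residual norm decreases
    lambda <- 1
    repeat {
      cand <- delta + lambda * step
      rc <- g(cand)
      if (max(abs(rc)) < max(abs(res)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (max(abs(rc)) >= max(abs(res))) break
    delta <- cand; res <- rc
  }
  if (max(abs(res)) > tol) {
    # fallback: cyclic coordinate bisection; each margin is increasing in
    # its own offset, so sweeping converges like iterative proportional fitting
    for (sweep_i in seq_len(500L)) {
      for (j in seq_len(J)) {
        fj <- function(dj) {
          d <- delta; d[j] <- dj
          mean(softmax_nonbase(eta, d)[, j]) - targets[j]
        }
        lo <- -100; hi <- 100
        for (b in seq_len(120L)) {
          mid <- (lo + hi) / 2
          if (fj(mid) > 0) hi <- mid else lo <- mid
        }
        delta[j] <- (lo + hi) / 2
      }
      res <- g(delta)
      it <- it + 1L
      if (max(abs(res)) <= tol) break
    }
  }
  if (max(abs(res)) > tol * 100)
    stop("multinomial calibration failed to converge; final residuals: ",
         paste(format(res, digits = 4), collapse = ", "))
  new_delta_solution(delta, res, it, max(abs(res)) <= tol)
}
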