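#' Fit the (multinomial) logistic imputation model to the complete records
#'
#' Fits the imputation model for the incomplete covariate conditional on
#' the fully observed outcome (and any fully observed categorical
#' covariates) by maximum likelihood on the complete records only. A
#' two-level covariate gives a logistic regression; K > 2 levels a
#' multinomial logistic regression with a declared base level.
#'
#' @param data data frame; the left-hand-side variable of `formula` is the
#'   incomplete covariate (a factor, `NA` = missing), right-hand-side
#'   variables must be fully observed.
#' @param formula imputation-model formula, e.g. `x ~ y` or
#'   `x ~ y + age_group + sex`.
#' @param base_level base (reference) level of the incomplete covariate.
#'   Defaults to the first declared level for a binary covariate and to
#'   the most frequent observed level for a categorical one.
#' @return An object of class `"imputation_model"`: `theta` (ML estimates;
#'   a vector for binary, a (K-1) x p matrix for multinomial), `vcov`
#'   (asymptotic sampling variance of the flattened parameters, level-major
#'   for multinomial), level/base bookkeeping and the model terms needed to
#'   build linear predictors for new rows.
#' @examples
#' d <- apply_selection(simulate_full_data(2000, seed = 1),
#'                      selection_spec("M1", log(0.55 / 0.45)))
#' fit_imputation_model(d, x ~ y)
#' @export
fit_imputation_model <- function(data, formula, base_level = NULL) {
  x_var <- all.vars(formula[[2]])
  if (length(x_var) != 1L || !x_var %in% names(data))
    stop("the formula's left-hand side must be a single column of data")
  rhs_vars <- all.vars(formula[[3]])
  if (!all(rhs_vars %in% names(data)))
    stop("missing columns: ", paste(setdiff(rhs_vars, names(data)), collapse = ", "))
  for (v in rhs_vars) if (anyNA(data[[v]]))
    stop("imputation-model covariate ", v, " has missing values; ",
         "only the imputed covariate may be incomplete")
  x <- data[[x_var]]
  if (!is.factor(x)) stop(x_var, " must be a factor")
  lev <- levels(x)
  K <- length(lev)
  if (K < 2L) stop(x_var, " must have at least 2 levels")
  cr <- data[!is.na(x), , drop = FALSE]
  if (nrow(cr) == 0L) stop("no complete records to fit the imputation model")
  obs_tab <- table(cr[[x_var]])
  if (any(obs_tab == 0L))
    stop("imputation model not identifiable: no complete records with ",
         x_var, " = ", paste(names(obs_tab)[obs_tab == 0L], collapse = ", "))
  if (is.null(base_level))
    base_level <- if (K == 2L) lev[1L] else names(obs_tab)[which.max(obs_tab)]
  if (!base_level %in% lev) stop("base_level must be a declared level of ", x_var)
  cr[[x_var]] <- stats::relevel(cr[[x_var]], ref = base_level)
  non_base <- levels(cr[[x_var]])[-1L]

  if (K == 2L) {
    cr$.x01 <- as.integer(cr[[x_var]] == non_base)
    f2 <- stats::as.formula(paste(".x01 ~", deparse(formula[[3]])))
    fit <- stats::glm(f2, family = stats::binomial(), data = cr)
    if (!fit$converged || any(!is.finite(stats::coef(fit))))
      stop("imputation model did not converge (possible separation)")
    if (any(abs(stats::coef(fit)) > 15))
      stop("imputation model shows signs of separation (|coefficient| > 15)")
    theta <- stats::coef(fit)
    U <- stats::vcov(fit)
  } else {
    fit <- nnet::multinom(formula, data = cr, Hess = TRUE, trace = FALSE,
                          maxit = 500L)
    theta <- stats::coef(fit)  # (K-1) x p, rows in non_base order
    if (any(!is.finite(theta)) || any(abs(theta) > 15))
      stop("multinomial imputation model shows signs of separation or ",
           "non-convergence")
    U <- tryCatch(stats::vcov(fit), error = function(e)
      stop("could not invert the multinomial Hessian: ", conditionMessage(e)))
    # vcov order is level-major: all coefficients of non-base level 2, then 3, ...
  }
  tt <- stats::delete.response(stats::terms(formula, data = cr))
  xlevels <- lapply(cr[rhs_vars], function(v) if (is.factor(v)) levels(v))
  xlevels <- Filter(Negate(is.null), xlevels)
  structure(list(x_var = x_var, formula = formula, terms = tt,
                 xlevels = xlevels, levels = lev, base_level = base_level,
                 non_base = non_base, type = if (K == 2L) "binary" else "multinomial",
                 theta = theta, vcov = (U + t(U)) / 2,
                 n = nrow(data), n_obs = nrow(cr)),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("%s imputation model for %s (base level %s), %d complete records\n",
              x$type, x$x_var, x$base_level, x$n_obs))
  print(x$theta)
  invisible(x)
}

# model matrix for new rows under the fitted terms
imp_model_matrix <- function(fit, newdata) {
  mf <- stats::model.frame(fit$terms, newdata, xlev = fit$xlevels,
                           na.action = stats::na.fail)
  stats::model.matrix(fit$terms, mf)
}

flatten_theta <- function(fit) {
  if (fit$type == "binary") fit$theta else as.vector(t(fit$theta))
}

unflatten_theta <- function(fit, v) {
  if (fit$type == "binary") v
  else matrix(v, nrow = length(fit$non_base), byrow = TRUE,
              dimnames = dimnames(fit$theta))
}

#' Draw imputation-model parameters from their approximate posterior
#'
#' One draw from the large-sample normal approximation
#' \eqn{N(\hat\theta, \hat U)} of the posterior under non-informative
#' priors, as used in proper MI.
#'
#' @param fit an [fit_imputation_model()] object.
#' @return Parameters in the same shape as `fit$theta`.
#' @export
draw_parameters <- function(fit) {
  stopifnot(inherits(fit, "imputation_model"))
  v <- tryCatch(
    MASS::mvrnorm(1L, mu = flatten_theta(fit), Sigma = fit$vcov),
    error = function(e) stop("parameter covariance is not positive ",
                             "semi-definite: ", conditionMessage(e)))
  unflatten_theta(fit, v)
}

#' Draw the nuisance proportions used in the calibration equation
#'
#' Draws a response probability \eqn{\tilde p_r} from
#' \eqn{N(\hat p_r, \hat p_r (1 - \hat p_r)/n)} (sample proportion of the
#' response indicator, all n records) and observed-data level proportions
#' \eqn{\tilde p_x} from \eqn{N(\hat p_x, \hat p_x (1 - \hat p_x)/n_{obs})}
#' (complete-record proportions, complete-record denominator). Draws
#' outside (0, 1) are rejected and redrawn; for K > 2 levels the per-level
#' draws are renormalised onto the simplex, while for a binary covariate
#' only the non-base level is drawn and the base takes the complement.
#'
#' @param data data frame containing the incomplete covariate.
#' @param fit the [fit_imputation_model()] (for level bookkeeping).
#' @param max_tries rejection-sampling cap.
#' @return List with `p_r` (scalar draw) and `p_obs` (named vector over
#'   all levels, base first per the fit's ordering).
#' @export
draw_nuisance_proportions <- function(data, fit, max_tries = 1000L) {
  x <- data[[fit$x_var]]
  n <- length(x)
  n_obs <- sum(!is.na(x))
  if (n_obs == 0L || n_obs == n)
    stop("need both observed and missing values of ", fit$x_var,
         " (observed proportion is ", n_obs / n, ")")
  p_r_hat <- n_obs / n
  lev_order <- c(fit$base_level, fit$non_base)
  p_obs_hat <- prop.table(table(factor(x[!is.na(x)], levels = lev_order)))
  p_obs_hat <- stats::setNames(as.numeric(p_obs_hat), lev_order)

  draw_scalar <- function(m, s) {
    for (i in seq_len(max_tries)) {
      d <- stats::rnorm(1L, m, s)
      if (d > 0 && d < 1) return(d)
    }
    stop("could not draw a proportion inside (0, 1)")
  }
  p_r <- draw_scalar(p_r_hat, sqrt(p_r_hat * (1 - p_r_hat) / n))
  K <- length(lev_order)
  if (K == 2L) {
    p2 <- draw_scalar(p_obs_hat[2L],
                      sqrt(p_obs_hat[2L] * (1 - p_obs_hat[2L]) / n_obs))
    p_obs <- stats::setNames(c(1 - p2, p2), lev_order)
  } else {
    se <- sqrt(p_obs_hat * (1 - p_obs_hat) / n_obs)
    for (i in seq_len(max_tries)) {
      d <- p_obs_hat + stats::rnorm(K) * se
      if (all(d > 0 & d < 1)) break
      d <- NULL
    }
    if (is.null(d)) stop("could not draw observed-level proportions inside (0, 1)")
    p_obs <- d / sum(d)
  }
  list(p_r = p_r, p_obs = p_obs)
}

# reference proportions aligned to the fit's level ordering (base first)
align_reference <- function(ref, fit) {
  p <- ref$proportions
  lev_order <- c(fit$base_level, fit$non_base)
  if (!setequal(names(p), fit$levels))
    stop("reference levels {", paste(names(p), collapse = ", "),
         "} do not match the covariate levels {",
         paste(fit$levels, collapse = ", "), "}")
  p[lev_order]
}

#' Create one completed dataset
#'
#' One cycle of the proper-imputation algorithm. For `method =
#' "calibrated"`: draw imputation-model parameters \eqn{\tilde\theta} from
#' \eqn{N(\hat\theta, \hat U)}, draw the nuisance proportions
#' \eqn{\tilde p_r, \tilde p_x} and (in estimated reference mode) the
#' reference proportions \eqn{\tilde p^{pop}_x}; form the nonrespondent
#' target via [target_missing_proportion()]; solve for the calibrated
#' delta adjustment with those draws; then draw fresh parameters
#' \eqn{\dot\theta} (refitting with a fixed intercept offset leaves the
#' complete-record ML estimates unchanged, since the offset is zero on the
#' records the model is fitted to) and impute each missing value from the
#' (multinomial) logistic model with the delta offset added to the
#' intercept(s). `method = "standard"` is the same final step with the
#' offset fixed at zero.
#'
#' @param data data frame with the incomplete covariate.
#' @param fit an [fit_imputation_model()] object for `data`.
#' @param method `"standard"` or `"calibrated"`.
#' @param ref a [population_reference()] (required for `"calibrated"`).
#' @param delta optional fixed offset (scalar for binary, length K-1
#'   vector for multinomial) bypassing the calibration step; `delta = 0`
#'   in the calibrated path reproduces standard MI exactly.
#' @return The completed data frame, with attributes `delta` (offset
#'   used), `imputed` (logical row flags) and `delta_solution` (when
#'   solved).
#' @export
impute_once <- function(data, fit, method = c("standard", "calibrated"),
                        ref = NULL, delta = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "imputation_model"))
  x <- data[[fit$x_var]]
  mis <- is.na(x)
  J <- length(fit$non_base)
  if (!any(mis)) {
    attr(data, "imputed") <- mis
    attr(data, "delta") <- rep(0, J)
    return(data)
  }
  X_mis <- imp_model_matrix(fit, data[mis, , drop = FALSE])
  sol <- NULL
  if (method == "calibrated" && is.null(delta)) {
    if (is.null(ref)) stop("calibrated imputation requires a population reference")
    theta_tilde <- draw_parameters(fit)
    nu <- draw_nuisance_proportions(data, fit)
    p_pop <- align_reference(
      if (ref$mode == "fixed") ref
      else population_reference(draw_population_proportion(ref), mode = "fixed"),
      fit)
    targets <- target_missing_proportion(p_pop[-1L], nu$p_obs[-1L], nu$p_r)
    if (fit$type == "binary") {
      eta <- drop(X_mis %*% theta_tilde)
      sol <- solve_delta_binary(eta, targets)
    } else {
      if (sum(targets) >= 1)
        stop("calibration infeasible: nonrespondent level targets sum to ",
             format(sum(targets), digits = 4), " >= 1")
      eta <- X_mis %*% t(theta_tilde)
      sol <- solve_delta_categorical(eta, targets)
    }
    delta <- sol$delta
  }
  if (is.null(delta)) delta <- rep(0, J)
  if (length(delta) != J) stop("delta must have length ", J)

  theta_dot <- draw_parameters(fit)
  if (fit$type == "binary") {
    p1 <- expit(drop(X_mis %*% theta_dot) + delta)
    imp <- ifelse(stats::runif(sum(mis)) < p1, fit$non_base, fit$base_level)
  } else {
    P_nb <- softmax_nonbase(X_mis %*% t(theta_dot), delta)
    P <- cbind(pmax(1 - rowSums(P_nb), 0), P_nb)
    cum <- t(apply(P, 1L, cumsum))
    k <- rowSums(stats::runif(nrow(P)) > cum) + 1L
    imp <- c(fit$base_level, fit$non_base)[pmin(k, ncol(P))]
  }
  data[[fit$x_var]][mis] <- factor(imp, levels = fit$levels)
  attr(data, "imputed") <- mis
  attr(data, "delta") <- delta
  attr(data, "delta_solution") <- sol
  data
}

#' Multiply impute the incomplete covariate
#'
#' Creates M completed datasets, each from fresh draws of all stochastic
#' quantities (parameters, nuisance proportions, reference proportions in
#' estimated mode, the calibrated delta itself, and the imputed values).
#'
#' @inheritParams impute_once
#' @param formula imputation-model formula (see [fit_imputation_model()]).
#' @param M number of imputations (at least 2).
#' @param base_level passed to [fit_imputation_model()].
#' @return An object of class `"mi_result"`: list with `imputations` (list
#'   of M completed data frames), `deltas` (M x (K-1) matrix of offsets
#'   used), `fit`, `method`, `M`.
#' @examples
#' d <- apply_selection(simulate_full_data(500, seed = 2),
#'                      selection_spec("M1", log(0.55 / 0.45)))
#' ref <- population_reference(c("0" = 0.3, "1" = 0.7))
#' mi <- multiply_impute(d, x ~ y, method = "calibrated", M = 5, ref = ref)
#' @export
multiply_impute <- function(data, formula, method = c("standard", "calibrated"),
                            M = 50L, ref = NULL, base_level = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(M), M >= 2)
  fit <- fit_imputation_model(data, formula, base_level = base_level)
  imps <- vector("list", M)
  deltas <- matrix(NA_real_, M, length(fit$non_base),
                   dimnames = list(NULL, fit$non_base))
  for (m in seq_len(M)) {
    imps[[m]] <- impute_once(data, fit, method = method, ref = ref)
    deltas[m, ] <- attr(imps[[m]], "delta")
  }
  structure(list(imputations = imps, deltas = deltas, fit = fit,
                 method = method, M = M),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("%s MI: M = %d imputations of %s (%d missing of %d)\n",
              x$method, x$M, x$fit$x_var, x$fit$n - x$fit$n_obs, x$fit$n))
  if (x$method == "calibrated")
    cat("mean delta adjustment:",
        paste(format(colMeans(x$deltas), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Complete records (records with the covariate observed)
#'
#' @param data data frame.
#' @param x_var name of the incomplete covariate column.
#' @return The subset of rows with the covariate observed.
#' @export
complete_records <- function(data, x_var = "x") {
  stopifnot(x_var %in% names(data))
  out <- data[!is.na(data[[x_var]]), , drop = FALSE]
  if (nrow(out) == 0L) stop("no complete records")
  out
}

#' Single imputation with a reference level
#'
#' Replaces every missing value of the covariate with one declared level
#' (for example, imputing all missing ethnicity as the White group) -- a
#' common but generally biased practice, provided as a comparator.
#'
#' @param data data frame.
#' @param level level to impute.
#' @param x_var name of the incomplete covariate column.
#' @return Completed data frame.
#' @export
single_impute_reference <- function(data, level, x_var = "x") {
  stopifnot(x_var %in% names(data))
  x <- data[[x_var]]
  if (!is.factor(x)) stop(x_var, " must be a factor")
  if (!level %in% levels(x))
    stop(level, " is not a declared level of ", x_var)
  data[[x_var]][is.na(x)] <- level
  data
}
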