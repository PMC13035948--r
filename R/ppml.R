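#' Specify a PPML flow regression
#'
#' Describes the mean model for a Poisson pseudo-maximum-likelihood (PPML)
#' regression of bilateral flows: which predictor columns enter, how each is
#' transformed, which fixed-effect dimensions are absorbed, and which
#' dimensions standard errors are clustered by.
#'
#' @param predictors character vector of predictor column names present in
#'   the panel (possibly empty for a fixed-effects-only baseline).
#' @param transforms named character vector over `predictors` with values
#'   `"none"`, `"log"`, `"lag"` or `"lag_log"`. `"lag"` uses the dyad's value
#'   in the previous calendar year; records without a lag value (the first
#'   panel year) are dropped from estimation, never imputed. Unnamed
#'   predictors default to `"none"`.
#' @param fixed_effects subset of `c("origin", "destination", "year")`.
#' @param cluster subset of `c("origin", "destination", "year")` used for the
#'   multiway clustered covariance; defaults to `fixed_effects`.
#' @return A `ppml_spec` object.
#' @export
ppml_spec <- function(predictors = character(),
                      transforms = NULL,
                      fixed_effects = c("origin", "destination", "year"),
                      cluster = fixed_effects) {
  dims <- c("origin", "destination", "year")
  if (length(fixed_effects) > 0)
    fixed_effects <- match.arg(fixed_effects, dims, several.ok = TRUE)
  if (length(cluster) > 0)
    cluster <- match.arg(cluster, dims, several.ok = TRUE)
  tr <- stats::setNames(rep("none", length(predictors)), predictors)
  if (!is.null(transforms)) {
    bad <- setdiff(names(transforms), predictors)
    if (length(bad) > 0L)
      stop("transforms refer to unknown predictors: ", paste(bad, collapse = ", "))
    ok <- c("none", "log", "lag", "lag_log")
    if (!all(transforms %in% ok))
      stop("transforms must be one of: ", paste(ok, collapse = ", "))
    tr[names(transforms)] <- transforms
  }
  structure(list(predictors = predictors, transforms = tr,
                 fixed_effects = fixed_effects, cluster = cluster),
            class = "ppml_spec")
}

# Applies transforms and returns the estimation frame: keys, y, one column
# per (transformed) predictor. Lagged predictors drop first-year records.
build_frame <- function(panel, spec) {
  df <- as.data.frame(panel)
  miss <- setdiff(spec$predictors, names(df))
  if (length(miss) > 0L)
    stop("predictors not found in panel: ", paste(miss, collapse = ", "))
  out <- df[, c("origin", "destination", "year", "flow")]
  needs_lag <- FALSE
  for (p in spec$predictors) {
    x <- df[[p]]
    tr <- spec$transforms[[p]]
    if (tr %in% c("lag", "lag_log")) {
      needs_lag <- TRUE
      prev <- df[, c("origin", "destination", "year", p)]
      prev$year <- prev$year + 1L
      names(prev)[4L] <- ".lagval"
      m <- merge(out[, c("origin", "destination", "year")], prev,
                 by = c("origin", "destination", "year"),
                 all.x = TRUE, sort = FALSE)
      # merge() does not preserve row order; re-align on keys
      key_out <- paste(out$origin, out$destination, out$year)
      x <- m$.lagval[match(key_out, paste(m$origin, m$destination, m$year))]
    }
    if (tr %in% c("log", "lag_log")) {
      if (any(x <= 0, na.rm = TRUE))
        stop("log transform of '", p, "' requires strictly positive values")
      x <- log(x)
    }
    out[[p]] <- x
  }
  if (needs_lag) {
    keep <- stats::complete.cases(out[, spec$predictors, drop = FALSE])
    if (any(!keep))
      message(sum(!keep), " record(s) without lagged predictor values dropped from estimation")
    out <- out[keep, , drop = FALSE]
  }
  if (anyNA(out[, spec$predictors, drop = FALSE]))
    stop("missing predictor values after transforms")
  rownames(out) <- NULL
  out
}

# Design matrix: intercept, predictors, then fixed-effect dummies with the
# first level as reference.
build_design <- function(frame, spec) {
  terms <- c("(Intercept)" = "1")
  rhs <- c("1", spec$predictors,
           vapply(spec$fixed_effects, function(d) paste0("factor(", d, ")"), ""))
  f <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  stats::model.matrix(f, data = frame)
}

poisson_ll <- function(y, mu) {
  sum(ifelse(y > 0, y * log(mu), 0) - mu - lgamma(y + 1))
}

#' Fit a PPML flow regression
#'
#' Estimates the multiplicative mean model
#' \eqn{E[y_{ijt}] = \exp(\alpha_i + \gamma_j + \delta_t + \beta^\top x_{ijt})}
#' by Poisson pseudo-maximum likelihood (iteratively reweighted least
#' squares). Zero flows are retained; the estimator is consistent under
#' correct mean specification regardless of the distribution of the flows.
#' Perfectly collinear columns are dropped with a warning; one reference
#' level per fixed-effect dimension is dropped for identifiability.
#'
#' @param panel a [flow_panel()] carrying the predictor columns.
#' @param spec a [ppml_spec()].
#' @param tol IRLS convergence tolerance on the relative deviance change.
#' @param max_iter maximum IRLS iterations.
#' @return A `ppml_fit` with coefficients, the multiway clustered covariance
#'   (per `spec$cluster`), fitted flows, the linear predictor, Poisson
#'   log-likelihoods of the fitted, fixed-effects-only and intercept-only
#'   models on the same records, and bookkeeping needed by
#'   [fitted_intervals()], [reset_test()] and [simulate_ensemble()].
#' @export
fit_ppml <- function(panel, spec, tol = 1e-8, max_iter = 100L) {
  frame <- build_frame(panel, spec)
  y <- frame$flow
  X <- build_design(frame, spec)

  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep_cols]
    warning("dropping perfectly collinear column(s): ",
            paste(dropped, collapse = ", "))
    bad_pred <- intersect(dropped, spec$predictors)
    X <- X[, sort(keep_cols), drop = FALSE]
  }

  fit <- stats::glm.fit(X, y, family = stats::quasipoisson(link = "log"),
                        control = stats::glm.control(epsilon = tol,
                                                     maxit = max_iter))
  if (!fit$converged)
    stop(sprintf("PPML did not converge in %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance))

  mu <- fit$fitted.values
  eta <- log(mu)
  beta <- fit$coefficients

  ll <- poisson_ll(y, mu)
  ll_null <- poisson_ll(y, rep(mean(y), length(y)))  # intercept-only MLE

  fe_cols <- c("(Intercept)",
               grep("^factor\\(", colnames(X), value = TRUE))
  k_fe <- length(fe_cols)
  pred_cols <- intersect(colnames(X), spec$predictors)
  if (length(pred_cols) == 0L) {
    ll_fe <- ll
    k_fe <- length(beta)
  } else if (length(spec$fixed_effects) == 0L) {
    ll_fe <- ll_null
    k_fe <- 1L
  } else {
    Xfe <- X[, fe_cols, drop = FALSE]
    f0 <- stats::glm.fit(Xfe, y, family = stats::quasipoisson(link = "log"),
                         control = stats::glm.control(epsilon = tol,
                                                      maxit = max_iter))
    ll_fe <- poisson_ll(y, f0$fitted.values)
  }

  out <- structure(list(
    coefficients = beta,
    fitted = mu,
    eta = eta,
    y = y,
    X = X,
    keys = frame[, c("origin", "destination", "year")],
    spec = spec,
    loglik = ll,
    loglik_null = ll_null,
    loglik_fe_only = ll_fe,
    k = length(beta),
    k_fe_only = k_fe,
    n_obs = length(y),
    dropped = dropped,
    vcov = NULL,
    cluster_dims = spec$cluster
  ), class = "ppml_fit")
  out$vcov <- clustered_vcov(out, spec$cluster)
  out
}

#' @export
print.ppml_fit <- function(x, ...) {
  cat(sprintf("PPML fit: %d obs, %d parameters, loglik %.2f\n",
              x$n_obs, x$k, x$loglik))
  show <- intersect(names(x$coefficients),
                    c("(Intercept)", x$spec$predictors))
  se <- sqrt(diag(x$vcov))[show]
  b <- x$coefficients[show]
  z <- b / se
  tab <- data.frame(estimate = b, cluster_se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, 4))
  if (length(x$spec$fixed_effects) > 0)
    cat("Fixed effects: ", paste(x$spec$fixed_effects, collapse = ", "),
        " (", x$k - length(show), " absorbed coefficients)\n", sep = "")
  invisible(x)
}

#' Multiway cluster-robust covariance for a PPML fit
#'
#' Combines one-way cluster sandwich covariances over every non-empty subset
#' of the cluster dimensions by inclusion-exclusion: subsets of odd size
#' enter with a plus, even size with a minus, the deepest interaction
#' correcting for double counting. With a single dimension in which each
#' record is its own cluster, this reduces to the heteroskedasticity-robust
#' sandwich. The combined matrix can fail to be positive semi-definite, a
#' known property of the inclusion-exclusion construction; negative
#' eigenvalues are truncated at zero with a warning.
#'
#' @param fit a [fit_ppml()] result.
#' @param cluster_dims subset of `c("origin", "destination", "year")`.
#' @param df_correction apply the conventional finite-sample factor
#'   `G/(G-1) * (n-1)/(n-k)` per subset (with `G` that subset's number of
#'   clusters), reducing the downward bias of the plug-in sandwich; with no
#'   cluster dimensions the factor is `n/(n-k)` (HC1). Default `TRUE`.
#' @param psd_repair truncate negative eigenvalues at zero (with a warning)
#'   when the inclusion-exclusion combination is not PSD; set `FALSE` to
#'   obtain the raw combined matrix.
#' @return Symmetric covariance matrix over the estimated coefficients (PSD
#'   when `psd_repair = TRUE`).
#' @export
clustered_vcov <- function(fit, cluster_dims = fit$cluster_dims,
                           df_correction = TRUE, psd_repair = TRUE) {
  X <- fit$X
  n <- nrow(X)
  k <- ncol(X)
  scores <- (fit$y - fit$fitted) * X              # QMLE score contributions
  bread <- solve(crossprod(X, fit$fitted * X))    # inverse negative Hessian

  if (length(cluster_dims) == 0L) {
    adj <- if (df_correction) n / (n - k) else 1
    meat <- adj * crossprod(scores)               # robust (singleton clusters)
  } else {
    dims <- unique(cluster_dims)
    for (d in dims) {
      if (length(unique(fit$keys[[d]])) < 2L)
        stop("cluster dimension '", d, "' has a single cluster")
    }
    meat <- 0
    for (r in seq_along(dims)) {
      for (subset in utils::combn(dims, r, simplify = FALSE)) {
        g <- interaction(fit$keys[subset], drop = TRUE)
        Sg <- rowsum(scores, g)
        G <- nrow(Sg)
        adj <- if (df_correction) G / (G - 1) * (n - 1) / (n - k) else 1
        meat <- meat + (-1)^(r + 1) * adj * crossprod(Sg)
      }
    }
  }
  V <- bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  eig <- eigen(V, symmetric = TRUE)
  if (psd_repair && min(eig$values) < -1e-12 * max(abs(eig$values))) {
    warning("multiway clustered covariance not PSD; truncating negative eigenvalues at zero")
    ev <- pmax(eig$values, 0)
    V <- eig$vectors %*% (ev * t(eig$vectors))
    V <- (V + t(V)) / 2
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' RESET specification test for a PPML fit
#'
#' Augments the fitted mean model with powers of the estimated linear
#' predictor (the square by default) and tests their coefficients against
#' zero with the model's clustered covariance. A small p-value indicates
#' that the conditional mean is misspecified.
#'
#' @param fit a [fit_ppml()] result.
#' @param powers integer powers of the linear predictor used as
#'   augmentation terms; default `2`.
#' @return list with `statistic` (Wald chi-squared), `df`, `p_value`, and
#'   `degenerate` (`TRUE`, with `p_value = NA`, when the augmentation is
#'   collinear with the existing regressors).
#' @export
reset_test <- function(fit, powers = 2L) {
  aug <- sapply(powers, function(p) fit$eta^p)
  colnames(aug) <- paste0(".reset_eta", powers)
  Xa <- cbind(fit$X, aug)
  if (qr(Xa)$rank < ncol(Xa))
    return(list(statistic = NA_real_, df = length(powers),
                p_value = NA_real_, degenerate = TRUE))
  refit <- fit
  refit$X <- Xa
  g <- stats::glm.fit(Xa, fit$y,
                      family = stats::quasipoisson(link = "log"),
                      control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!g$converged)
    return(list(statistic = NA_real_, df = length(powers),
                p_value = NA_real_, degenerate = TRUE))
  refit$coefficients <- g$coefficients
  refit$fitted <- g$fitted.values
  V <- clustered_vcov(refit, fit$cluster_dims)
  idx <- colnames(aug)
  b <- g$coefficients[idx]
  Vb <- V[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(Vb) %*% b)
  list(statistic = stat, df = length(powers),
       p_value = stats::pchisq(stat, df = length(powers), lower.tail = FALSE),
       degenerate = FALSE)
}

#' Goodness-of-fit statistics for a PPML fit
#'
#' @param fit a [fit_ppml()] result.
#' @return list with `squared_correlation` (squared linear correlation of
#'   observed and fitted flows; defined as 0, with a warning, when the fitted
#'   values are constant), `adjusted_pseudo_r2` (McFadden's adjusted
#'   pseudo-R², `1 - (ll - k)/ll_null` against the intercept-only model), and
#'   `within_adjusted_pseudo_r2` (the same statistic with the
#'   fixed-effects-only model as the null and only the extra parameters
#'   penalised; `NA` when the model has no fixed effects).
#' @export
fit_statistics <- function(fit) {
  if (stats::sd(fit$fitted) == 0 || stats::sd(fit$y) == 0) {
    warning("degenerate correlation (constant observed or fitted flows); squared correlation set to 0")
    r2 <- 0
  } else {
    r2 <- stats::cor(fit$y, fit$fitted)^2
  }
  if (fit$loglik_null == 0) stop("null log-likelihood is zero; pseudo-R2 undefined")
  adj <- 1 - (fit$loglik - fit$k) / fit$loglik_null
  within <- if (length(fit$spec$fixed_effects) == 0L) NA_real_ else {
    k_extra <- fit$k - fit$k_fe_only
    1 - (fit$loglik - k_extra) / fit$loglik_fe_only
  }
  list(squared_correlation = r2,
       adjusted_pseudo_r2 = adj,
       within_adjusted_pseudo_r2 = within)
}

#' Percent change in flows implied by a coefficient
#'
#' Translates a PPML coefficient into the interpretive percentage used in
#' prose. For a binary predictor switching 0 to 1 the multiplicative mean
#' model implies an exact `100 * (exp(beta) - 1)` percent difference. For a
#' log-transformed predictor, the linear elasticity approximation gives
#' `beta * delta_pct` percent per `delta_pct` percent change in the
#' predictor.
#'
#' @param beta coefficient value.
#' @param kind `"exponential"` (binary 0/1 switch) or `"elasticity"`
#'   (log-log approximation).
#' @param delta_pct percent change in the predictor (required for
#'   `"elasticity"`).
#' @return Percent change in flows.
#' @export
effect_size <- function(beta, kind = c("exponential", "elasticity"),
                        delta_pct = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(beta)) stop("beta must be finite")
  if (kind == "exponential") return(100 * (exp(beta) - 1))
  if (is.null(delta_pct)) stop("delta_pct is required for kind = 'elasticity'")
  beta * delta_pct
}

#' Fitted flows with confidence intervals
#'
#' Interval for each dyad-year on the response scale, built on the link
#' scale and exponentiated: `exp(eta +/- z * se(eta))` with `se(eta)` from
#' the clustered coefficient covariance, so the lower bound is always
#' positive and fixed-effect estimation uncertainty is included.
#'
#' @param fit a [fit_ppml()] result.
#' @param level confidence level in (0, 1).
#' @return data.frame with `origin`, `destination`, `year`, `fitted`,
#'   `se_eta`, `lower`, `upper`; attribute `interval_scale` records the
#'   construction.
#' @export
fitted_intervals <- function(fit, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  se_eta <- sqrt(pmax(rowSums((fit$X %*% fit$vcov) * fit$X), 0))
  out <- data.frame(fit$keys,
                    fitted = fit$fitted,
                    se_eta = se_eta,
                    lower = exp(fit$eta - z * se_eta),
                    upper = exp(fit$eta + z * se_eta))
  attr(out, "interval_scale") <- "response (exponentiated link-scale interval)"
  attr(out, "level") <- level
  out
}
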