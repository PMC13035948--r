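# A small panel whose mean structure is a single binary predictor: PPML must
# reproduce the group means, so the coefficients have closed forms.
binary_panel <- function(flows0 = c(8, 12), flows1 = c(18, 22)) {
  flow_panel(data.frame(
    origin = c("A", "B", "C", "D"), destination = c("B", "A", "D", "C"),
    year = 2002L, flow = c(flows0, flows1), x = c(0, 0, 1, 1)))
}

test_that("PPML with one binary regressor reproduces group-mean ratios", {
  fit <- fit_ppml(binary_panel(),
                  ppml_spec("x", fixed_effects = character(0),
                            cluster = character(0)))
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(10), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["x"]), log(2), tolerance = 1e-7)
})

test_that("intercept-only fit on constant flows is exact", {
  p <- flow_panel(data.frame(origin = c("A", "B", "A"),
                             destination = c("B", "A", "C"),
                             year = 2002L, flow = c(7, 7, 7)))
  fit <- fit_ppml(p, ppml_spec(fixed_effects = character(0),
                               cluster = character(0)))
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(7), tolerance = 1e-8)
  expect_equal(unname(fit$fitted), rep(7, 3), tolerance = 1e-8)
})

test_that("first-order conditions hold at the solution", {
  g <- generate_panel(synthetic_truth(n_locations = 8, years = 2002:2003, seed = 5))
  fit <- suppressWarnings(fit_ppml(g$panel, ppml_spec(c("dist_log", "tie", "logratio"))))
  foc <- crossprod(fit$X, fit$y - fit$fitted)
  expect_lt(max(abs(foc)) / sum(fit$y), 1e-8)
  # with fixed effects present, fitted totals match observed totals
  expect_equal(sum(fit$fitted), sum(fit$y), tolerance = 1e-8)
})

test_that("log-likelihoods are nested: full >= FE-only >= intercept-only", {
  g <- generate_panel(synthetic_truth(n_locations = 8, years = 2002:2003, seed = 6))
  fit <- suppressWarnings(fit_ppml(g$panel, ppml_spec(c("dist_log", "tie"))))
  expect_gte(fit$loglik, fit$loglik_fe_only - 1e-6)
  expect_gte(fit$loglik_fe_only, fit$loglik_null - 1e-6)

  fit0 <- suppressWarnings(fit_ppml(g$panel, ppml_spec(c("dist_log"))))
  expect_gte(fit$loglik, fit0$loglik - 1e-6)
})

test_that("perfectly collinear predictors are dropped with a warning", {
  g <- generate_panel(synthetic_truth(n_locations = 6, years = 2002L, seed = 7))
  g$panel$dist_copy <- g$panel$dist_log
  expect_warning(
    fit <- fit_ppml(g$panel, ppml_spec(c("dist_log", "dist_copy"),
                                       fixed_effects = c("origin", "destination"),
                                       cluster = character(0))),
    "collinear")
  expect_true("dist_copy" %in% fit$dropped)
  expect_false("dist_copy" %in% names(fit$coefficients))
})

test_that("lagged predictors drop first-year records deterministically", {
  g <- generate_panel(synthetic_truth(n_locations = 6, years = 2002:2004, seed = 8))
  spec <- ppml_spec(c("dist_log", "logratio"),
                    transforms = c(logratio = "lag"))
  expect_message(fit <- suppressWarnings(fit_ppml(g$panel, spec)), "lagged")
  expect_equal(sort(unique(fit$keys$year)), c(2003L, 2004L))
  # the lagged column really is the previous year's value
  one <- fit$keys[1, ]
  frame <- flowgof:::build_frame(g$panel, spec)
  prev <- g$panel$logratio[g$panel$origin == one$origin &
                           g$panel$destination == one$destination &
                           g$panel$year == one$year - 1L]
  got <- frame$logratio[frame$origin == one$origin &
                        frame$destination == one$destination &
                        frame$year == one$year]
  expect_equal(got, prev)
})

test_that("singleton clustering equals the plain robust sandwich", {
  p <- flow_panel(data.frame(origin = c("A", "B", "C", "D", "E", "F"),
                             destination = c("B", "A", "D", "C", "F", "E"),
                             year = 2002L, flow = c(3, 9, 4, 8, 11, 2),
                             x = c(0, 0, 1, 1, 0, 1)))
  fit <- fit_ppml(p, ppml_spec("x", fixed_effects = character(0),
                               cluster = character(0)))
  v_singleton <- clustered_vcov(fit, "origin", df_correction = FALSE)
  v_robust <- clustered_vcov(fit, character(0), df_correction = FALSE)
  expect_equal(v_singleton, v_robust, tolerance = 1e-10)
})

test_that("multiway clustered covariance matches the sandwich package oracle", {
  skip_if_not_installed("sandwich")
  g <- generate_panel(synthetic_truth(n_locations = 5, years = 2002:2004, seed = 9))
  df <- as.data.frame(g$panel)
  glm_fit <- stats::glm(flow ~ dist_log + tie + factor(origin) + factor(destination),
                        family = stats::quasipoisson(), data = df)
  fit <- suppressWarnings(  # inclusion-exclusion PSD repair warning expected
    fit_ppml(g$panel, ppml_spec(c("dist_log", "tie"),
                                fixed_effects = c("origin", "destination"),
                                cluster = c("origin", "destination"))))
  # one-way oracles per subset, combined by inclusion-exclusion
  v1 <- sandwich::vcovCL(glm_fit, cluster = df$origin, type = "HC0", cadjust = FALSE)
  v2 <- sandwich::vcovCL(glm_fit, cluster = df$destination, type = "HC0", cadjust = FALSE)
  v12 <- sandwich::vcovCL(glm_fit, cluster = interaction(df$origin, df$destination),
                          type = "HC0", cadjust = FALSE)
  oracle <- v1 + v2 - v12
  mine <- clustered_vcov(fit, c("origin", "destination"),
                         df_correction = FALSE, psd_repair = FALSE)
  keep <- c("dist_log", "tie")
  expect_equal(mine[keep, keep], oracle[keep, keep], tolerance = 1e-6)
})

test_that("perfect within-cluster dependence inflates clustered variances", {
  set.seed(10)
  base <- data.frame(origin = rep(sprintf("O%d", 1:6), each = 4),
                     destination = rep(sprintf("D%d", 1:4), times = 6),
                     x = rnorm(24))
  base$flow <- rpois(24, exp(1 + 0.5 * base$x))
  # duplicate every record within its origin cluster (as extra destinations)
  dup <- base
  dup$destination <- paste0(dup$destination, "b")
  df <- rbind(cbind(base, year = 2002L), cbind(dup, year = 2002L))
  p <- flow_panel(df)
  fit <- fit_ppml(p, ppml_spec("x", fixed_effects = character(0),
                               cluster = character(0)))
  v_iid <- clustered_vcov(fit, character(0), df_correction = FALSE)
  v_cl <- clustered_vcov(fit, "origin", df_correction = FALSE)
  expect_gt(v_cl["x", "x"], v_iid["x", "x"])
})

test_that("a cluster dimension with a single cluster is rejected", {
  fit <- fit_ppml(binary_panel(),
                  ppml_spec("x", fixed_effects = character(0),
                            cluster = character(0)))
  expect_error(clustered_vcov(fit, "year"), "single cluster")
})

test_that("RESET p-values are valid and degenerate cases flagged", {
  g <- generate_panel(synthetic_truth(n_locations = 8, years = 2002L, seed = 12))
  fit <- suppressWarnings(fit_ppml(g$panel,
                                   ppml_spec(c("dist_log", "tie"),
                                             fixed_effects = c("origin", "destination"),
                                             cluster = character(0))))
  rt <- reset_test(fit)
  expect_false(rt$degenerate)
  expect_gte(rt$p_value, 0)
  expect_lte(rt$p_value, 1)

  # intercept-only model: the squared linear predictor is constant, hence
  # collinear with the intercept
  p <- flow_panel(data.frame(origin = c("A", "B"), destination = c("B", "A"),
                             year = 2002L, flow = c(4, 9)))
  fit0 <- fit_ppml(p, ppml_spec(fixed_effects = character(0),
                                cluster = character(0)))
  rt0 <- reset_test(fit0)
  expect_true(rt0$degenerate)
  expect_true(is.na(rt0$p_value))
})

test_that("RESET detects an omitted quadratic term", {
  set.seed(13)
  n <- 15
  L <- sprintf("L%02d", 1:n)
  idx <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
  rej <- vapply(1:20, function(s) {
    set.seed(100 + s)
    x <- rnorm(nrow(idx))
    al <- rnorm(n, 0, .4); ga <- rnorm(n, 0, .4)
    lam <- exp(3 + al[idx[, 1]] + ga[idx[, 2]] + 0.5 * x + 0.3 * x^2)
    p <- flow_panel(data.frame(origin = L[idx[, 1]], destination = L[idx[, 2]],
                               year = 2002L, flow = rpois(nrow(idx), lam), x = x))
    fit <- fit_ppml(p, ppml_spec("x", fixed_effects = c("origin", "destination"),
                                 cluster = character(0)))
    reset_test(fit)$p_value < 0.05
  }, NA)
  expect_gt(mean(rej), 0.5)  # measured power is ~0.98 at these settings
})

test_that("fit statistics handle perfect, baseline and degenerate fits", {
  # two groups, constant flows within group: fitted == observed
  fit <- fit_ppml(binary_panel(flows0 = c(10, 10), flows1 = c(20, 20)),
                  ppml_spec("x", fixed_effects = character(0),
                            cluster = character(0)))
  expect_equal(fit_statistics(fit)$squared_correlation, 1, tolerance = 1e-9)

  # FE-only baseline: within adjusted pseudo-R2 is zero by construction
  g <- generate_panel(synthetic_truth(n_locations = 6, years = 2002:2003, seed = 14))
  fe_only <- suppressWarnings(fit_ppml(g$panel, ppml_spec()))
  expect_equal(fit_statistics(fe_only)$within_adjusted_pseudo_r2, 0, tolerance = 1e-9)

  # constant fitted values on varying flows: defined as 0 with a warning
  p <- flow_panel(data.frame(origin = c("A", "B", "A"),
                             destination = c("B", "A", "C"),
                             year = 2002L, flow = c(2, 9, 5)))
  fit0 <- fit_ppml(p, ppml_spec(fixed_effects = character(0),
                                cluster = character(0)))
  expect_warning(st <- fit_statistics(fit0), "degenerate")
  expect_equal(st$squared_correlation, 0)
})

test_that("effect sizes translate coefficients as the mean model implies", {
  expect_equal(effect_size(0, "exponential"), 0)
  expect_equal(effect_size(0, "elasticity", delta_pct = 10), 0)
  expect_error(effect_size(1, "elasticity"), "delta_pct")
  expect_error(effect_size(Inf, "exponential"), "finite")

  # exponential kind equals the exact mean ratio of a 0 -> 1 switch
  fit <- fit_ppml(binary_panel(),
                  ppml_spec("x", fixed_effects = character(0),
                            cluster = character(0)))
  ratio <- 20 / 10  # group means
  expect_equal(effect_size(fit$coefficients[["x"]], "exponential"),
               100 * (ratio - 1), tolerance = 1e-6)
})

test_that("fitted intervals are positive, centred and nested across levels", {
  g <- generate_panel(synthetic_truth(n_locations = 6, years = 2002L, seed = 15))
  fit <- suppressWarnings(fit_ppml(g$panel,
                                   ppml_spec("dist_log",
                                             fixed_effects = c("origin", "destination"),
                                             cluster = c("origin", "destination"))))
  ci95 <- fitted_intervals(fit, 0.95)
  ci90 <- fitted_intervals(fit, 0.90)
  expect_true(all(ci95$lower > 0))
  expect_true(all(ci95$lower <= ci95$fitted & ci95$fitted <= ci95$upper))
  expect_true(all(ci90$lower >= ci95$lower & ci90$upper <= ci95$upper))
  expect_error(fitted_intervals(fit, 1.2), "level")
})
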