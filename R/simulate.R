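#' Configure an ensemble simulation
#'
#' @param S ensemble size (number of simulated systems per year).
#' @param level confidence level whose interval width is used to recover the
#'   per-dyad standard deviation, and the truncated-normal scale.
#' @param lower,upper truncation bounds `a` and `b`; the default keeps flows
#'   nonnegative and unbounded above (any finite upper bound would be an
#'   invention of the package, so it is opt-in).
#' @param calibrate rescale each simulated origin row so its total matches
#'   the observed yearly outflow of that origin.
#' @param seed root seed; per-(year, draw) substreams are derived from it
#'   deterministically, so ensembles are reproducible draw by draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(S = 100L, level = 0.95, lower = 0, upper = Inf,
                       calibrate = TRUE, seed = 1L) {
  if (S < 1L) stop("S must be >= 1")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  if (lower < 0) stop("lower truncation bound must be nonnegative")
  if (!(lower < upper)) stop("lower bound must be below upper bound")
  structure(list(S = as.integer(S), level = level, lower = lower,
                 upper = upper, calibrate = isTRUE(calibrate),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Recover a standard deviation from a confidence interval
#'
#' Under approximate normality of the sampling distribution, a symmetric
#' interval of width `upper - lower` at confidence `level` implies
#' `sigma = (upper - lower) / (2 z)` with `z` the standard-normal quantile
#' at `(1 + level) / 2`.
#'
#' @param lower,upper interval bounds (vectorised).
#' @param level confidence level in (0, 1).
#' @return Nonnegative standard deviation(s).
#' @export
sigma_from_interval <- function(lower, upper, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  if (any(upper < lower)) stop("upper must be >= lower")
  (upper - lower) / (2 * stats::qnorm((1 + level) / 2))
}

# Deterministic per-(year, draw) substream seed below 2^31.
derive_seed <- function(seed, year_index, draw) {
  (as.double(seed) * 7919 + year_index * 104729 + draw * 263) %% 2147483629
}

# Inverse-CDF truncated-normal sampler, vectorised over (mean, sd). sd = 0
# collapses to the clamped mean; a mean far outside [a, b] (interval
# probability underflowing to 0) is clamped to the nearest bound.
rtruncnorm_icdf <- function(n, mean, sd, a = 0, b = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- pmin(pmax(mean, a), b)
  pos <- sd > 0
  if (any(pos)) {
    pa <- stats::pnorm(a, mean[pos], sd[pos])
    pb <- stats::pnorm(b, mean[pos], sd[pos])
    u <- stats::runif(sum(pos))
    w <- pb - pa
    ok <- w > 0
    q <- out[pos]
    q[ok] <- stats::qnorm(pa[ok] + u[ok] * w[ok], mean[pos][ok], sd[pos][ok])
    # guard against qnorm returning +/-Inf at the extreme tails
    q <- pmin(pmax(q, a), b)
    out[pos] <- q
  }
  out
}

#' Draw simulated flows for a set of dyads
#'
#' Each dyad's flow is drawn independently from a truncated normal
#' distribution centred on its fitted flow, with the dyad's recovered
#' standard deviation and the configured truncation bounds. Sampling is by
#' inversion of the CDF, so draws are reproducible given the seed.
#'
#' @param fitted numeric vector of fitted flows (one per dyad).
#' @param sigma numeric vector of per-dyad standard deviations (recycled).
#' @param config a [sim_config()] (bounds are taken from it).
#' @param seed integer seed for this draw.
#' @return Numeric vector of simulated flows in `[lower, upper]`.
#' @export
draw_truncated_flows <- function(fitted, sigma, config = sim_config(), seed = config$seed) {
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  set.seed(seed)
  rtruncnorm_icdf(length(fitted), fitted, rep_len(sigma, length(fitted)),
                  a = config$lower, b = config$upper)
}

#' Calibrate a flow matrix to observed row totals
#'
#' Multiplicatively rescales each origin's row so its sum equals the
#' observed outflow total. Scaling preserves the relative proportions within
#' a row and the zero pattern, so no corridor absent from the simulated
#' matrix can appear through calibration, and the diagonal stays zero.
#'
#' @param m a [flow_matrix()] (or plain square matrix with zero diagonal).
#' @param observed_outflows numeric vector of per-origin totals, in row
#'   order (or named by origin label).
#' @return The calibrated matrix. A zero target sets the row to zeros; a
#'   zero simulated row with a positive target is an error naming the
#'   origin.
#' @export
calibrate_rows <- function(m, observed_outflows) {
  n <- nrow(m)
  if (!is.null(names(observed_outflows)) && !is.null(rownames(m)))
    observed_outflows <- observed_outflows[rownames(m)]
  if (length(observed_outflows) != n)
    stop("need one observed outflow total per origin")
  if (any(observed_outflows < 0)) stop("observed totals must be nonnegative")
  rs <- rowSums(m)
  bad <- rs == 0 & observed_outflows > 0
  if (any(bad))
    stop("cannot calibrate origin(s) with zero simulated outflow: ",
         paste(rownames(m)[bad], collapse = ", "))
  scale <- ifelse(observed_outflows == 0, 0,
                  observed_outflows / ifelse(rs == 0, 1, rs))
  out <- unclass(m) * scale  # scale recycles down rows: row i times scale[i]
  if (inherits(m, "flow_matrix"))
    out <- flow_matrix(out, labels = rownames(m), year = attr(m, "year"))
  out
}

#' Simulate an ensemble of synthetic flow systems
#'
#' For every year covered by the fitted model and each of `S` draws, all
#' dyads are drawn independently from their truncated-normal distributions
#' (centred on the fitted flows, scale recovered from the fitted-value
#' confidence intervals at `config$level`) and assembled into a complete
#' origin-destination matrix; with `calibrate = TRUE` each row is then
#' rescaled to the observed outflow total of that origin and year, which
#' also matches every draw's total volume to the observed system's.
#'
#' @param fit a [fit_ppml()] result.
#' @param panel the [flow_panel()] the model was fitted on (source of the
#'   observed outflow totals used by calibration).
#' @param config a [sim_config()].
#' @return A `flow_ensemble`: per-year arrays `n x n x S` of simulated
#'   matrices, plus labels, years, fitted matrices, observed matrices and
#'   the configuration.
#' @export
simulate_ensemble <- function(fit, panel, config = sim_config()) {
  ci <- fitted_intervals(fit, level = config$level)
  ci$sigma <- sigma_from_interval(ci$lower, ci$upper, config$level)
  L <- attr(panel, "locations")
  n <- length(L)
  years <- sort(unique(ci$year))
  off <- which(row(diag(n)) != col(diag(n)))  # column-major off-diagonal cells

  draws <- vector("list", length(years))
  fitted_mats <- vector("list", length(years))
  observed_mats <- vector("list", length(years))
  names(draws) <- names(fitted_mats) <- names(observed_mats) <- as.character(years)

  for (yi in seq_along(years)) {
    yr <- years[yi]
    sub <- ci[ci$year == yr, , drop = FALSE]
    if (nrow(sub) != n * (n - 1L))
      stop("fitted values do not cover all dyads for year ", yr)
    cell <- (match(sub$destination, L) - 1L) * n + match(sub$origin, L)
    fm <- matrix(0, n, n, dimnames = list(L, L))
    fm[cell] <- sub$fitted
    sg <- matrix(0, n, n, dimnames = list(L, L))
    sg[cell] <- sub$sigma
    obs <- suppressWarnings(to_matrix(panel, yr))
    target <- rowSums(obs)

    arr <- array(0, dim = c(n, n, config$S), dimnames = list(L, L, NULL))
    mu_off <- fm[off]
    sd_off <- sg[off]
    for (s in seq_len(config$S)) {
      set.seed(derive_seed(config$seed, yi, s))
      v <- rtruncnorm_icdf(length(off), mu_off, sd_off,
                           a = config$lower, b = config$upper)
      M <- matrix(0, n, n)
      M[off] <- v
      if (config$calibrate) {
        rs <- rowSums(M)
        bad <- rs == 0 & target > 0
        if (any(bad))
          stop("cannot calibrate origin(s) with zero simulated outflow: ",
               paste(L[bad], collapse = ", "))
        M <- M * ifelse(target == 0, 0, target / ifelse(rs == 0, 1, rs))
      }
      arr[, , s] <- M
    }
    draws[[yi]] <- arr
    fitted_mats[[yi]] <- flow_matrix(fm, labels = L, year = yr)
    observed_mats[[yi]] <- obs
  }

  structure(list(draws = draws, labels = L, years = years,
                 fitted = fitted_mats, observed = observed_mats,
                 config = config),
            class = "flow_ensemble")
}

#' @export
print.flow_ensemble <- function(x, ...) {
  cat(sprintf("flow_ensemble: %d draws x %d year(s), %d locations%s (seed %d)\n",
              x$config$S, length(x$years), length(x$labels),
              if (x$config$calibrate) ", row-calibrated" else "",
              x$config$seed))
  invisible(x)
}
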