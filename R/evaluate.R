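#' Mahalanobis distance of an observed vector from a simulated ensemble
#'
#' `D^2 = (x - mu)' Sigma^{-1} (x - mu)` with `mu` and `Sigma` the mean and
#' covariance of the simulated vectors. Because `Sigma` is estimated from a
#' finite ensemble and flow components can be nearly collinear, it is
#' regularised by linear shrinkage toward its diagonal before inversion,
#' `Sigma* = (1 - lambda) Sigma + lambda diag(Sigma)`; by default `lambda`
#' is the analytic shrinkage intensity of the correlation-shrinkage
#' estimator (ratio of the summed sampling variances of the off-diagonal
#' correlations to their summed squares, clamped to [0, 1]). Should the
#' regularised matrix still be numerically singular, the Moore-Penrose
#' pseudo-inverse is used with a warning.
#'
#' @param observed numeric vector of length p.
#' @param simulated S-by-p matrix of simulated vectors (S >= 2).
#' @param shrinkage shrinkage intensity in [0, 1], or `NULL` (default) for
#'   the analytic choice. `shrinkage = 0` uses the raw covariance;
#'   `shrinkage = 1` reduces `D^2` to a sum of squared componentwise
#'   z-scores.
#' @return Nonnegative scalar `D^2`; values near zero indicate close
#'   agreement between the observed vector and the ensemble.
#' @export
mahalanobis_d2 <- function(observed, simulated, shrinkage = NULL) {
  simulated <- as.matrix(simulated)
  if (nrow(simulated) < 2L) stop("need at least 2 simulated vectors")
  if (length(observed) != ncol(simulated))
    stop("observed vector and simulated vectors differ in length")
  mu <- colMeans(simulated)
  Sigma <- stats::cov(simulated)
  if (is.null(shrinkage)) shrinkage <- analytic_shrinkage(simulated)
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  Sreg <- (1 - shrinkage) * Sigma + shrinkage * diag(diag(Sigma), ncol(Sigma))
  d <- observed - mu
  qf <- tryCatch(
    drop(stats::mahalanobis(matrix(observed, 1L), mu, Sreg)),
    error = function(e) {
      warning("regularised covariance numerically singular; using pseudo-inverse")
      drop(t(d) %*% MASS::ginv(Sreg) %*% d)
    })
  max(qf, 0)
}

# Analytic shrinkage intensity toward the diagonal: sum of estimated
# sampling variances of the off-diagonal correlations over the sum of their
# squares (correlation-shrinkage rule), clamped to [0, 1]. Constant
# components are skipped; an all-constant ensemble shrinks fully.
analytic_shrinkage <- function(simulated) {
  S <- nrow(simulated)
  if (S < 3L) return(1)
  sds <- apply(simulated, 2L, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) < 2L) return(1)
  z <- scale(simulated[, keep, drop = FALSE])
  r <- crossprod(z) / (S - 1)
  w_bar <- r * (S - 1) / S
  # var-hat of r_ij from the empirical variance of the products z_i z_j
  zz2 <- crossprod(z^2) / S
  var_r <- S / (S - 1)^3 * (zz2 - w_bar^2) * S
  offd <- row(r) != col(r)
  denom <- sum(r[offd]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(var_r[offd]) / denom))
}

#' Mahalanobis distance for a location's inflow or outflow profile
#'
#' For each requested year, extracts the length `n - 1` vector of flows
#' into (or out of) the location from every other location, both from the
#' observed system and from each simulated draw, and returns the
#' Mahalanobis distance of the observed profile from the ensemble. Lower
#' values indicate a closer match; distances are reported per year and
#' never aggregated, so spatial accuracy can be tracked over time.
#'
#' @param panel observed [flow_panel()].
#' @param ensemble a [simulate_ensemble()] result on the same system.
#' @param location a location label.
#' @param years years to evaluate (default: all ensemble years).
#' @param direction `"inflow"` (column profile) or `"outflow"` (row
#'   profile).
#' @param shrinkage passed to [mahalanobis_d2()].
#' @return data.frame with `location`, `year`, `direction`, `d2`.
#' @export
location_profile_distance <- function(panel, ensemble, location,
                                      years = ensemble$years,
                                      direction = c("inflow", "outflow"),
                                      shrinkage = NULL) {
  direction <- match.arg(direction)
  L <- ensemble$labels
  if (!(location %in% L)) stop("unknown location: ", location)
  j <- match(location, L)
  rows <- lapply(years, function(yr) {
    yi <- match(yr, ensemble$years)
    if (is.na(yi)) stop("year ", yr, " not in ensemble")
    obs <- suppressWarnings(to_matrix(panel, yr))
    arr <- ensemble$draws[[yi]]
    if (direction == "inflow") {
      x <- obs[-j, j]
      sims <- t(arr[-j, j, , drop = TRUE])
    } else {
      x <- obs[j, -j]
      sims <- t(arr[j, -j, , drop = TRUE])
    }
    data.frame(location = location, year = yr, direction = direction,
               d2 = mahalanobis_d2(x, sims, shrinkage = shrinkage))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Envelope coverage of observed spatial indices
#'
#' Joins observed and simulated index series by (index, year) and flags
#' whether each observed value falls inside the ensemble envelope: the full
#' simulated range by default, or a quantile band. An observed value inside
#' the envelope means the model could reproduce that spatial feature given
#' the propagated regression uncertainty.
#'
#' @param observed long data.frame from [index_series()] on the panel.
#' @param simulated long data.frame from [index_series()] on the ensemble.
#' @param envelope `"range"` (min-max over draws) or `"quantile"`.
#' @param probs lower/upper probabilities for the quantile envelope.
#' @return data.frame per (index, year): `observed`, `sim_min`, `sim_max`,
#'   `sim_mean`, `env_lower`, `env_upper`, `inside`.
#' @export
index_envelope <- function(observed, simulated, envelope = c("range", "quantile"),
                           probs = c(0.025, 0.975)) {
  envelope <- match.arg(envelope)
  key_obs <- paste(observed$index, observed$year)
  key_sim <- paste(simulated$index, simulated$year)
  if (!all(key_obs %in% key_sim))
    stop("simulated series lacks (index, year) combinations present in observed: ",
         paste(utils::head(setdiff(key_obs, key_sim)), collapse = "; "))
  rows <- lapply(seq_len(nrow(observed)), function(i) {
    v <- simulated$value[key_sim == key_obs[i]]
    env <- if (envelope == "range") range(v)
           else stats::quantile(v, probs = probs, names = FALSE, type = 7)
    data.frame(index = observed$index[i], year = observed$year[i],
               observed = observed$value[i],
               sim_min = min(v), sim_max = max(v), sim_mean = mean(v),
               env_lower = env[1L], env_upper = env[2L],
               inside = observed$value[i] >= env[1L] &
                        observed$value[i] <= env[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Corridor-level check of observed against simulated flows
#'
#' For one directed corridor, compares the observed flow in each year with
#' the envelope of simulated flows for that cell of the matrix.
#'
#' @param panel observed [flow_panel()].
#' @param ensemble a [simulate_ensemble()] result.
#' @param origin,destination location labels of the directed corridor.
#' @param envelope,probs as in [index_envelope()].
#' @return data.frame per year: `origin`, `destination`, `observed`,
#'   `sim_min`, `sim_max`, `sim_mean`, `env_lower`, `env_upper`, `inside`.
#' @export
corridor_check <- function(panel, ensemble, origin, destination,
                           envelope = c("range", "quantile"),
                           probs = c(0.025, 0.975)) {
  envelope <- match.arg(envelope)
  L <- ensemble$labels
  if (!(origin %in% L) || !(destination %in% L) || origin == destination)
    stop("unknown corridor: ", origin, " -> ", destination)
  i <- match(origin, L); j <- match(destination, L)
  rows <- lapply(seq_along(ensemble$years), function(yi) {
    yr <- ensemble$years[yi]
    obs <- suppressWarnings(to_matrix(panel, yr))[i, j]
    v <- ensemble$draws[[yi]][i, j, ]
    env <- if (envelope == "range") range(v)
           else stats::quantile(v, probs = probs, names = FALSE, type = 7)
    data.frame(origin = origin, destination = destination, year = yr,
               observed = obs, sim_min = min(v), sim_max = max(v),
               sim_mean = mean(v), env_lower = env[1L], env_upper = env[2L],
               inside = obs >= env[1L] & obs <= env[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full spatial evaluation report
#'
#' Convenience wrapper producing the three evaluation tables at once:
#' envelope coverage of the spatial indices, per-location profile
#' Mahalanobis distances, and per-corridor checks.
#'
#' @param panel observed [flow_panel()].
#' @param ensemble a [simulate_ensemble()] result.
#' @param which indices for the coverage table, see [index_series()].
#' @param locations locations for the distance table (default: all).
#' @param corridors optional data.frame with columns `origin`,
#'   `destination`.
#' @param direction profile direction for the distance table.
#' @param envelope,probs envelope construction, see [index_envelope()].
#' @param mode reciprocity mode.
#' @param shrinkage passed to [mahalanobis_d2()].
#' @return list of class `flowgof_report` with elements `index_coverage`,
#'   `location_distances`, `corridor_checks`.
#' @export
evaluate_flows <- function(panel, ensemble,
                           which = c("acv", "gini", "inequality", "reciprocity"),
                           locations = ensemble$labels,
                           corridors = NULL,
                           direction = "inflow",
                           envelope = "range", probs = c(0.025, 0.975),
                           mode = "minimum", shrinkage = NULL) {
  obs_idx <- index_series(panel, which = which, mode = mode)
  obs_idx <- obs_idx[obs_idx$year %in% ensemble$years, , drop = FALSE]
  sim_idx <- index_series(ensemble, which = which, mode = mode)
  coverage <- index_envelope(obs_idx, sim_idx, envelope = envelope, probs = probs)

  dist_tab <- do.call(rbind, lapply(locations, function(loc)
    location_profile_distance(panel, ensemble, loc,
                              direction = direction, shrinkage = shrinkage)))

  corr_tab <- NULL
  if (!is.null(corridors)) {
    corr_tab <- do.call(rbind, lapply(seq_len(nrow(corridors)), function(i)
      corridor_check(panel, ensemble, corridors$origin[i],
                     corridors$destination[i],
                     envelope = envelope, probs = probs)))
  }
  structure(list(index_coverage = coverage,
                 location_distances = dist_tab,
                 corridor_checks = corr_tab),
            class = "flowgof_report")
}

#' @export
print.flowgof_report <- function(x, ...) {
  cat("Spatial goodness-of-fit report\n")
  cat(sprintf("  index coverage: %d/%d (index, year) cells inside envelope\n",
              sum(x$index_coverage$inside), nrow(x$index_coverage)))
  if (!is.null(x$location_distances))
    cat(sprintf("  location distances: %d rows, median D^2 = %.3f\n",
                nrow(x$location_distances),
                stats::median(x$location_distances$d2)))
  if (!is.null(x$corridor_checks))
    cat(sprintf("  corridor checks: %d rows, %d inside\n",
                nrow(x$corridor_checks), sum(x$corridor_checks$inside)))
  invisible(x)
}
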