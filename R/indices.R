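#' Spatial concentration and reciprocity indices for flow matrices
#'
#' Four system-level indices summarise how a flow system is organised across
#' space. Three measure concentration (spatial focusing) - how unevenly
#' total flow is distributed over corridors - and one measures reciprocity -
#' the share of movers matched by a counter-flow in the same corridor.
#' Diagonal cells are structural zeros and never enter any sum.
#'
#' * `acv()` - aggregate coefficient of variation: each origin's
#'   coefficient of variation of outflows (standard deviation over mean,
#'   variance divisor `n - 1` over the `n - 1` off-diagonal cells), weighted
#'   by the origin's share of total flow. Unbounded above, very sensitive to
#'   one or two dominant corridors; origins with zero outflow contribute 0
#'   (their weight is 0 in any case).
#' * `gini()` - sum of absolute differences between every ordered pair of
#'   corridor flows, normalised by `(2 n (n - 1) - 1)` times total flow
#'   (`normalisation = "printed"`, the form used in the migration
#'   literature this package follows). The textbook mean-absolute-difference
#'   normalisation `2 N` times total flow, with `N = n (n - 1)` corridors
#'   (maximum `(N - 1) / N`), is available as `normalisation = "pairs"`.
#' * `inequality()` - total absolute deviation from the uniform system in
#'   which every corridor carries `total / (n (n - 1))`, divided by twice
#'   the total flow: 0 for a uniform system, approaching 1 when a single
#'   corridor carries everything.
#' * `reciprocity()` - the two directed flows of each corridor are reduced
#'   to one value (their minimum by default; maximum or geometric mean
#'   optionally) and summed over ordered pairs, divided by total flow. With
#'   the minimum, the value is the share of movers matched by a mover in the
#'   opposite direction: 1 for a symmetric system, 0 for strictly one-way
#'   flows. A corridor with a zero flow in one direction contributes 0 under
#'   the geometric mean (its limit value).
#'
#' @param m a [flow_matrix()] (any square matrix with zero diagonal works).
#' @param normalisation Gini denominator convention, see above.
#' @param mode reciprocity reduction of the two directed flows.
#' @return A single numeric value.
#' @name flow_indices
NULL

off_diag <- function(m) m[row(m) != col(m)]

#' @rdname flow_indices
#' @export
acv <- function(m) {
  n <- nrow(m)
  total <- sum(off_diag(m))
  if (total <= 0) stop("ACV undefined for an all-zero flow matrix")
  value <- 0
  for (i in seq_len(n)) {
    v <- m[i, -i]
    mbar <- mean(v)
    if (mbar > 0) {
      cv <- sqrt(sum((v - mbar)^2) / (n - 1)) / mbar
      value <- value + cv * sum(v) / total
    }
  }
  value
}

#' @rdname flow_indices
#' @export
gini <- function(m, normalisation = c("printed", "pairs")) {
  normalisation <- match.arg(normalisation)
  n <- nrow(m)
  x <- off_diag(m)
  total <- sum(x)
  if (total <= 0) stop("Gini undefined for an all-zero flow matrix")
  N <- length(x)
  # sum over all ordered pairs of |x_p - x_q| via the sorted-vector identity
  xs <- sort(x)
  pair_sum <- 2 * sum((2 * seq_len(N) - N - 1) * xs)
  denom <- switch(normalisation,
                  printed = (2 * n * (n - 1) - 1) * total,
                  pairs = 2 * N * total)
  pair_sum / denom
}

#' @rdname flow_indices
#' @export
inequality <- function(m) {
  n <- nrow(m)
  x <- off_diag(m)
  total <- sum(x)
  if (total <= 0) stop("inequality index undefined for an all-zero flow matrix")
  uniform <- total / (n * (n - 1))
  sum(abs(x - uniform)) / (2 * total)
}

#' @rdname flow_indices
#' @export
reciprocity <- function(m, mode = c("minimum", "maximum", "geometric_mean")) {
  mode <- match.arg(mode)
  total <- sum(off_diag(m))
  if (total <= 0) stop("reciprocity undefined for an all-zero flow matrix")
  mt <- t(m)
  paired <- switch(mode,
                   minimum = pmin(m, mt),
                   maximum = pmax(m, mt),
                   geometric_mean = sqrt(m * mt))
  sum(off_diag(paired)) / total
}

index_fun <- function(name, mode, gini_normalisation) {
  switch(name,
         acv = function(m) acv(m),
         gini = function(m) gini(m, normalisation = gini_normalisation),
         inequality = function(m) inequality(m),
         reciprocity = function(m) reciprocity(m, mode = mode),
         stop("unknown index: ", name))
}

#' Index series for an observed panel or a simulated ensemble
#'
#' Computes the requested indices for every year of a [flow_panel()]
#' (source `"observed"`) or for every draw and year of a `flow_ensemble`
#' (source `"simulated"`, one row per draw).
#'
#' @param x a [flow_panel()] or a [simulate_ensemble()] result.
#' @param which character vector among `"acv"`, `"gini"`, `"inequality"`,
#'   `"reciprocity"`.
#' @param mode reciprocity mode, passed to [reciprocity()].
#' @param gini_normalisation passed to [gini()].
#' @return Long data.frame with columns `year`, `source`, `draw` (`NA` for
#'   observed), `index`, `value`.
#' @export
index_series <- function(x, which = c("acv", "gini", "inequality", "reciprocity"),
                         mode = "minimum", gini_normalisation = "printed") {
  which <- match.arg(which, several.ok = TRUE)
  funs <- lapply(stats::setNames(which, which), index_fun,
                 mode = mode, gini_normalisation = gini_normalisation)
  rows <- list()
  if (inherits(x, "flow_panel")) {
    for (yr in attr(x, "years")) {
      M <- to_matrix(x, yr)
      for (nm in which)
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, source = "observed", draw = NA_integer_,
          index = nm, value = funs[[nm]](M))
    }
  } else if (inherits(x, "flow_ensemble")) {
    for (yi in seq_along(x$years)) {
      arr <- x$draws[[yi]]
      S <- dim(arr)[3L]
      for (nm in which) {
        vals <- vapply(seq_len(S), function(s) funs[[nm]](arr[, , s]), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          year = x$years[yi], source = "simulated", draw = seq_len(S),
          index = nm, value = vals)
      }
    }
  } else {
    stop("x must be a flow_panel or flow_ensemble")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise ensemble index distributions
#'
#' @param series output of [index_series()] on an ensemble.
#' @return data.frame per (index, year) with `min`, `max`, `mean` over
#'   draws.
#' @export
summarise_index_series <- function(series) {
  sp <- split(series, list(series$index, series$year), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    index = d$index[1L], year = d$year[1L],
    min = min(d$value), max = max(d$value), mean = mean(d$value))))
  rownames(out) <- NULL
  out[order(out$index, out$year), ]
}
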