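#' Construct a bilateral flow panel
#'
#' A flow panel is a long-format table of directed dyad-year records: one row
#' per (origin, destination, year) with a nonnegative flow and, optionally,
#' further predictor columns. Diagonal records (origin equal to destination)
#' are structural zeros of the origin-destination matrix and are not allowed.
#'
#' @param data data.frame with at least columns `origin`, `destination`,
#'   `year`, `flow`; any further columns are kept as dyadic predictors.
#' @param locations optional character vector fixing the location ordering
#'   shared by all matrices derived from this panel; defaults to the
#'   lexicographic order of the labels present.
#' @return A `flow_panel`: a data.frame with attributes `locations` and
#'   `years`.
#' @details Flows are stored as nonnegative reals rather than integers:
#'   observed flows are often themselves estimates, and row calibration of
#'   simulated systems produces non-integer values.
#' @seealso [read_flow_panel()], [to_matrix()], [validate_panel()]
#' @export
flow_panel <- function(data, locations = NULL) {
  req <- c("origin", "destination", "year", "flow")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  data$origin <- as.character(data$origin)
  data$destination <- as.character(data$destination)
  data$year <- as.integer(data$year)
  data$flow <- as.numeric(data$flow)

  if (anyNA(data$flow) || any(data$flow < 0))
    stop("flows must be nonnegative and non-missing")
  diag_rows <- data$origin == data$destination
  if (any(diag_rows)) {
    key <- paste0(data$origin[diag_rows][1L], "->", data$destination[diag_rows][1L],
                  " (", data$year[diag_rows][1L], ")")
    stop("panel contains ", sum(diag_rows),
         " record(s) with origin == destination, e.g. ", key)
  }
  key <- paste(data$origin, data$destination, data$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (origin, destination, year) key: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }

  present <- sort(unique(c(data$origin, data$destination)))
  if (is.null(locations)) {
    locations <- present
  } else {
    locations <- as.character(locations)
    if (!all(present %in% locations))
      stop("labels in data not covered by `locations`: ",
           paste(setdiff(present, locations), collapse = ", "))
  }
  years <- sort(unique(data$year))

  ord <- order(match(data$origin, locations), match(data$destination, locations),
               data$year)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(data, locations = locations, years = years,
            class = c("flow_panel", "data.frame"))
}

#' @export
print.flow_panel <- function(x, ...) {
  L <- attr(x, "locations"); Ts <- attr(x, "years")
  cat(sprintf("flow_panel: %d records, %d locations, %d year(s) [%s]%s\n",
              nrow(x), length(L), length(Ts),
              paste(range(Ts), collapse = "-"),
              if (is_complete_panel(x)) ", complete" else ""))
  NextMethod()
  invisible(x)
}

is_complete_panel <- function(panel) {
  L <- length(attr(panel, "locations"))
  Ts <- length(attr(panel, "years"))
  nrow(panel) == L * (L - 1L) * Ts
}

#' Read a bilateral flow panel from CSV
#'
#' Expects a header row and at least origin, destination, year and flow
#' columns (renameable through `schema`). Rows with origin equal to
#' destination are rejected.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping the canonical names
#'   (`origin`, `destination`, `year`, `flow`) to the column names used in the
#'   file, e.g. `c(origin = "from", destination = "to")`. Unmapped names are
#'   taken as-is.
#' @inheritParams flow_panel
#' @return A [flow_panel()].
#' @export
read_flow_panel <- function(path, schema = NULL, locations = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("origin", "destination", "year", "flow")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), canonical)
    if (length(bad) > 0L)
      stop("unknown schema entries: ", paste(bad, collapse = ", "))
    map[names(schema)] <- schema
  }
  miss <- map[!(map %in% names(df))]
  if (length(miss) > 0L)
    stop("file lacks required column(s): ", paste(miss, collapse = ", "))
  for (nm in canonical) {
    if (map[[nm]] != nm) {
      df[[nm]] <- df[[map[[nm]]]]
      df[[map[[nm]]]] <- NULL
    }
  }
  flow_panel(df, locations = locations)
}

#' Write a flow panel to CSV
#'
#' Inverse of [read_flow_panel()]: columns `origin,destination,year,flow`
#' followed by any predictor columns.
#'
#' @param panel a [flow_panel()].
#' @param path output path.
#' @export
write_flow_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Attach dyadic predictors to a flow panel
#'
#' Merges a predictor table keyed by (origin, destination) and optionally
#' year. Time-invariant predictor tables (no `year` column) are broadcast to
#' every year of the panel.
#'
#' @param panel a [flow_panel()].
#' @param predictors data.frame with `origin`, `destination`, optionally
#'   `year`, and one column per predictor.
#' @return The panel with the predictor columns merged in.
#' @export
add_predictors <- function(panel, predictors) {
  if (!all(c("origin", "destination") %in% names(predictors)))
    stop("predictor table needs origin and destination columns")
  by <- c("origin", "destination")
  if ("year" %in% names(predictors)) by <- c(by, "year")
  merged <- merge(as.data.frame(panel), predictors, by = by,
                  all.x = TRUE, sort = FALSE)
  flow_panel(merged, locations = attr(panel, "locations"))
}

#' Construct a flow matrix
#'
#' A square nonnegative matrix for one year, rows indexing origins and
#' columns destinations, with a structurally zero diagonal.
#'
#' @param cells numeric n-by-n matrix; the diagonal must be zero.
#' @param labels character vector of n location labels.
#' @param year integer year the matrix refers to.
#' @return A `flow_matrix` (a matrix with `year` attribute).
#' @export
flow_matrix <- function(cells, labels = rownames(cells), year = NA_integer_) {
  cells <- as.matrix(cells)
  n <- nrow(cells)
  if (ncol(cells) != n) stop("flow matrix must be square")
  if (is.null(labels)) labels <- sprintf("L%02d", seq_len(n))
  if (length(labels) != n) stop("labels length must match matrix dimension")
  if (any(diag(cells) != 0))
    stop("diagonal cells must be structural zeros")
  if (any(cells < 0)) stop("flow matrix cells must be nonnegative")
  dimnames(cells) <- list(labels, labels)
  structure(cells, year = as.integer(year), class = c("flow_matrix", "matrix"))
}

#' Extract the origin-destination matrix for one year
#'
#' Cell (i, j) holds the flow from location i to location j in the given
#' year; the diagonal is structurally zero. Dyads absent from an incomplete
#' panel are filled with zero flow, with a warning.
#'
#' @param panel a [flow_panel()].
#' @param year a year present in the panel.
#' @return A [flow_matrix()].
#' @export
to_matrix <- function(panel, year) {
  years <- attr(panel, "years")
  if (!(year %in% years))
    stop("year ", year, " not present in panel (", paste(range(years), collapse = "-"), ")")
  L <- attr(panel, "locations")
  n <- length(L)
  sub <- panel[panel$year == year, , drop = FALSE]
  M <- matrix(0, n, n, dimnames = list(L, L))
  M[cbind(match(sub$origin, L), match(sub$destination, L))] <- sub$flow
  if (nrow(sub) < n * (n - 1L))
    warning(sprintf("panel is incomplete for year %d (%d of %d dyads); missing dyads filled with 0",
                    year, nrow(sub), n * (n - 1L)))
  flow_matrix(M, labels = L, year = year)
}

#' Flatten a flow matrix back to panel records
#'
#' @param m a [flow_matrix()].
#' @param drop_zero drop zero-flow records (default `FALSE`, keeping the
#'   panel complete).
#' @return A [flow_panel()] for the matrix's year.
#' @export
matrix_to_panel <- function(m, drop_zero = FALSE) {
  L <- rownames(m)
  n <- length(L)
  idx <- which(row(m) != col(m), arr.ind = TRUE)
  df <- data.frame(origin = L[idx[, 1L]], destination = L[idx[, 2L]],
                   year = attr(m, "year"), flow = m[idx],
                   stringsAsFactors = FALSE)
  if (drop_zero) df <- df[df$flow > 0, , drop = FALSE]
  flow_panel(df, locations = L)
}

#' Write / read a flow matrix in wide CSV form
#'
#' First column holds the origin label, remaining columns one destination
#' each.
#'
#' @param m a [flow_matrix()].
#' @param path file path.
#' @param year year to attach on read (wide CSVs carry no year).
#' @name matrix_csv
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(origin = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_csv
#' @export
read_matrix_csv <- function(path, year = NA_integer_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(df[[1L]])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  flow_matrix(cells, labels = labels, year = year)
}

#' Validate a flow panel
#'
#' A pure report: the panel is never modified and validation never throws.
#'
#' @param panel a [flow_panel()].
#' @return list with `n_records`, `n_locations`, `n_years`, `complete`
#'   (exactly n(n-1)T records), `expected_records`, `zero_flow_share` and
#'   `per_year_totals`.
#' @export
validate_panel <- function(panel) {
  L <- attr(panel, "locations")
  Ts <- attr(panel, "years")
  n <- length(L)
  expected <- n * (n - 1L) * length(Ts)
  totals <- if (nrow(panel) > 0)
    tapply(panel$flow, panel$year, sum) else numeric(0)
  list(
    n_records = nrow(panel),
    n_locations = n,
    n_years = length(Ts),
    expected_records = expected,
    complete = nrow(panel) > 0 && nrow(panel) == expected,
    zero_flow_share = if (nrow(panel) > 0) mean(panel$flow == 0) else NA_real_,
    per_year_totals = totals
  )
}
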