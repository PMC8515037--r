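# Kovats retention indices and component identification tables.

#' Construct an n-alkane reference ladder
#'
#' An alkane ladder pairs carbon numbers of n-alkane standards with their
#' retention times under the chromatographic program of interest. Retention
#' indices of sample peaks are obtained by linear interpolation between the
#' two alkanes that bracket the peak.
#'
#' @param carbon_number Integer vector of alkane carbon numbers, strictly
#'   increasing, within the C8--C40 standard range.
#' @param retention_time_min Numeric vector of retention times in minutes,
#'   strictly increasing, same length as `carbon_number`.
#' @return A data frame of class `alkane_ladder` with columns
#'   `carbon_number` and `retention_time_min`.
#' @examples
#' alkane_ladder(8:12, c(4.0, 6.1, 8.4, 10.9, 13.5))
#' @export
alkane_ladder <- function(carbon_number, retention_time_min) {
  ladder <- data.frame(
    carbon_number = as.integer(carbon_number),
    retention_time_min = as.numeric(retention_time_min)
  )
  class(ladder) <- c("alkane_ladder", "data.frame")
  validate_alkane_ladder(ladder)
}

#' @rdname alkane_ladder
#' @param ladder Object to validate.
#' @export
validate_alkane_ladder <- function(ladder) {
  if (!is.data.frame(ladder) ||
      !all(c("carbon_number", "retention_time_min") %in% names(ladder))) {
    stop("ladder must have columns 'carbon_number' and 'retention_time_min'")
  }
  cn <- ladder$carbon_number
  rt <- ladder$retention_time_min
  if (nrow(ladder) < 2L) {
    stop("alkane ladder needs at least 2 entries to interpolate")
  }
  if (anyNA(cn) || anyNA(rt) || !all(is.finite(rt))) {
    stop("alkane ladder contains missing or non-finite values")
  }
  if (any(cn < 8L) || any(cn > 40L)) {
    stop("carbon numbers must lie within the C8-C40 standard range")
  }
  if (any(diff(cn) <= 0L)) stop("carbon numbers must be strictly increasing")
  if (any(diff(rt) <= 0)) stop("retention times must be strictly increasing")
  if (!inherits(ladder, "alkane_ladder")) {
    class(ladder) <- c("alkane_ladder", class(ladder))
  }
  ladder
}

#' @export
print.alkane_ladder <- function(x, ...) {
  cat(sprintf("n-alkane ladder: C%d-C%d, %d entries, %.3f-%.3f min\n",
              min(x$carbon_number), max(x$carbon_number), nrow(x),
              min(x$retention_time_min), max(x$retention_time_min)))
  invisible(x)
}

#' Find the pair of adjacent alkanes bracketing a retention time
#'
#' Returns the unique adjacent ladder pair (Z, Z+1 by ladder order) with
#' tR(Z) <= t < tR(Z+1). A peak exactly at an alkane's retention time
#' brackets with that alkane as Z, except at the final ladder entry, which
#' brackets as Z+1. Peaks outside the ladder span are an error: the
#' interpolation is only defined between standards, and no extrapolation is
#' attempted.
#'
#' @param retention_time A single retention time in minutes.
#' @param ladder An [alkane_ladder()].
#' @return A two-row data frame: the bracketing ladder entries, low then high.
#' @export
bracket_alkanes <- function(retention_time, ladder) {
  ladder <- validate_alkane_ladder(ladder)
  if (length(retention_time) != 1L || !is.finite(retention_time)) {
    stop("retention_time must be a single finite number")
  }
  rt <- ladder$retention_time_min
  n <- length(rt)
  if (retention_time < rt[1L] || retention_time > rt[n]) {
    stop(sprintf(
      "retention time %.4f min outside ladder span [%.4f, %.4f]; no extrapolation",
      retention_time, rt[1L], rt[n]
    ))
  }
  i <- findInterval(retention_time, rt)
  if (i >= n) i <- n - 1L  # exactly at the last alkane: bracket as Z+1
  out <- ladder[c(i, i + 1L), , drop = FALSE]
  rownames(out) <- c("low", "high")
  out
}

#' Kovats retention index by linear interpolation
#'
#' Computes the retention index
#' \deqn{RI = 100 Z + 100 \frac{t_R(X) - t_R(Z)}{t_R(Z+1) - t_R(Z)}}
#' where Z and Z+1 are the carbon numbers of the n-alkanes eluting
#' immediately before and after the analyte X. When the bracketing alkanes
#' are not consecutive in carbon number the interpolation generalizes to
#' `100 * (Z + (Z1 - Z) * frac)`, which reduces to the formula above for a
#' consecutive ladder. RI is exactly `100 * carbon_number` at every ladder
#' point and monotone non-decreasing in retention time across the span.
#'
#' @param retention_time Numeric vector of peak retention times in minutes;
#'   each must lie within the ladder span.
#' @param ladder An [alkane_ladder()].
#' @return Numeric vector of dimensionless retention indices.
#' @examples
#' lad <- alkane_ladder(8:11, c(4, 6, 8.5, 11.2))
#' kovats_ri(6, lad)            # exactly at C9 -> 900
#' kovats_ri(c(5, 7.25), lad)   # midpoints -> 850, 950
#' @export
kovats_ri <- function(retention_time, ladder) {
  ladder <- validate_alkane_ladder(ladder)
  vapply(as.numeric(retention_time), function(t) {
    br <- bracket_alkanes(t, ladder)
    z0 <- br$carbon_number[1L]
    z1 <- br$carbon_number[2L]
    t0 <- br$retention_time_min[1L]
    t1 <- br$retention_time_min[2L]
    100 * (z0 + (z1 - z0) * (t - t0) / (t1 - t0))
  }, numeric(1))
}

# strip thousands-separator commas ("1,467.285" prints in identification
# tables); decimal separator is the dot
parse_numeric_column <- function(x, column, required = FALSE) {
  x <- gsub(",", "", trimws(as.character(x)), fixed = TRUE)
  x[!nzchar(x) | x %in% c("NA", "na")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("row %d, column '%s': cannot parse numeric value '%s'",
                 bad[1L], column, x[bad[1L]]))
  }
  if (required && anyNA(out)) {
    stop(sprintf("row %d, column '%s': missing required numeric value",
                 which(is.na(out))[1L], column))
  }
  out
}

#' Read a component identification table
#'
#' Reads a CSV of identified volatile-oil components with columns
#' `name,cas,content_pct,retention_index` and an optional `log_p` column.
#' Numeric cells may carry thousands-separator commas (as identification
#' tables often print retention indices, e.g. `"1,467.285"`); they are
#' stripped before parsing. Row order is preserved.
#'
#' @param source Path to a CSV file, or a character vector of CSV lines.
#' @return A data frame of class `component_table` with columns `name`,
#'   `cas`, `content_pct`, `retention_index`, `log_p` (NA when absent).
#' @seealso [table1_fixture()] for the packaged example table,
#'   [merge_logp()] to fill the `log_p` column from a lookup.
#' @export
read_component_table <- function(source) {
  raw <- if (length(source) == 1L && file.exists(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
  } else {
    utils::read.csv(text = source, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  }
  required <- c("name", "cas", "content_pct", "retention_index")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("component table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    name = trimws(as.character(raw$name)),
    cas = trimws(as.character(raw$cas)),
    content_pct = parse_numeric_column(raw$content_pct, "content_pct"),
    retention_index = parse_numeric_column(raw$retention_index,
                                           "retention_index"),
    log_p = if ("log_p" %in% names(raw)) {
      parse_numeric_column(raw$log_p, "log_p")
    } else {
      rep(NA_real_, nrow(raw))
    },
    stringsAsFactors = FALSE
  )
  validate_component_table(out)
}

#' @rdname read_component_table
#' @param components Object to validate.
#' @export
validate_component_table <- function(components) {
  required <- c("name", "content_pct")
  if (!is.data.frame(components) || !all(required %in% names(components))) {
    stop("component table must have at least 'name' and 'content_pct' columns")
  }
  if (nrow(components)) {
    if (any(!nzchar(components$name))) stop("component names must be non-empty")
    if (anyNA(components$content_pct) || any(components$content_pct < 0)) {
      stop("content_pct must be present and non-negative")
    }
    ri <- components$retention_index
    if (!is.null(ri) && any(!is.na(ri) & ri <= 0)) {
      stop("retention_index must be positive when present")
    }
  }
  if (!inherits(components, "component_table")) {
    class(components) <- c("component_table", class(components))
  }
  components
}

#' Write a component table to CSV
#'
#' Writes the canonical dialect read back by [read_component_table()]
#' (comma-separated, dot decimals, no thousands separators), so that a
#' write/read cycle round-trips every field.
#'
#' @param components A `component_table` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(components, path) {
  components <- validate_component_table(components)
  cols <- c("name", "cas", "content_pct", "retention_index", "log_p")
  for (col in setdiff(cols, names(components))) components[[col]] <- NA
  utils::write.csv(as.data.frame(components)[, cols], path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

#' Merge log P values into a component table from a lookup
#'
#' Identification tables rarely carry partition coefficients; this merges a
#' separate `name,log_p` lookup into the table. Names are matched exactly
#' after whitespace trimming.
#'
#' @param components A `component_table`.
#' @param lookup Data frame with columns `name` and `log_p`, or a path to
#'   such a CSV.
#' @return The component table with `log_p` filled where the lookup matched.
#' @export
merge_logp <- function(components, lookup) {
  components <- validate_component_table(components)
  if (is.character(lookup)) {
    lookup <- utils::read.csv(lookup, stringsAsFactors = FALSE)
  }
  if (!all(c("name", "log_p") %in% names(lookup))) {
    stop("log P lookup must have columns 'name' and 'log_p'")
  }
  idx <- match(trimws(components$name), trimws(lookup$name))
  hit <- !is.na(idx)
  components$log_p[hit] <- as.numeric(lookup$log_p[idx[hit]])
  components
}

#' Read an alkane ladder from CSV
#'
#' @param path CSV with header `carbon_number,retention_time_min`.
#' @return An [alkane_ladder()].
#' @export
read_alkane_ladder <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("carbon_number", "retention_time_min") %in% names(raw))) {
    stop("ladder file must have columns 'carbon_number' and 'retention_time_min'")
  }
  alkane_ladder(raw$carbon_number, raw$retention_time_min)
}
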