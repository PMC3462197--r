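units_required_cols <- c("unit_id", "x_m", "y_m", "surface_km2",
                         "out_commuters", "in_commuters", "role")

schema_stop <- function(...) stop(sprintf(...), call. = FALSE)

# strict numeric parse: every non-NA input must parse
parse_num <- function(x, col, rows) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    schema_stop("column '%s': unparseable number at row %d ('%s')",
                col, rows[bad[1]], x[bad[1]])
  v
}

parse_int <- function(x, col, rows, allow_na = FALSE) {
  v <- parse_num(x, col, rows)
  if (!allow_na && anyNA(v))
    schema_stop("column '%s': missing value at row %d", col, rows[which(is.na(v))[1]])
  frac <- which(!is.na(v) & v != floor(v))
  if (length(frac))
    schema_stop("column '%s': fractional value at row %d (%s)",
                col, rows[frac[1]], x[frac[1]])
  as.integer(v)
}

#' Read a units table from CSV
#'
#' Strict reader for the canonical units schema: required columns
#' `unit_id, x_m, y_m, surface_km2, out_commuters, in_commuters, role`
#' (role core/extended, case-insensitive) and optional `population`.
#' Malformed rows are never coerced silently; every error names the
#' offending row and column.
#'
#' @param path CSV file path.
#' @return a units table (see [units_table()]).
#' @export
read_units_csv <- function(path) {
  if (!file.exists(path)) schema_stop("file not found: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(units_required_cols, names(raw))
  if (length(missing))
    schema_stop("missing required column(s): %s", paste(missing, collapse = ", "))
  rows <- seq_len(nrow(raw)) + 1L  # header is line 1
  role <- tolower(trimws(raw$role))
  badrole <- which(!role %in% c("core", "extended"))
  if (length(badrole))
    schema_stop("column 'role': unknown role '%s' at row %d",
                raw$role[badrole[1]], rows[badrole[1]])
  if (anyDuplicated(raw$unit_id))
    schema_stop("column 'unit_id': duplicate id '%s'",
                raw$unit_id[duplicated(raw$unit_id)][1])
  pop <- if ("population" %in% names(raw))
    parse_int(raw$population, "population", rows, allow_na = TRUE)
  else NA_integer_
  units_table(unit_id = raw$unit_id,
              x = parse_num(raw$x_m, "x_m", rows),
              y = parse_num(raw$y_m, "y_m", rows),
              surface = parse_num(raw$surface_km2, "surface_km2", rows),
              out_commuters = parse_int(raw$out_commuters, "out_commuters", rows),
              in_commuters = parse_int(raw$in_commuters, "in_commuters", rows),
              role = role, population = pop)
}

# format doubles so that read-back recovers the value exactly
fmt_dbl <- function(x) vapply(x, function(v) formatC(v, digits = 17, format = "g"), "")

#' Write a units table to CSV
#'
#' Inverse of [read_units_csv()]: writing then reading reproduces all
#' values exactly (integers verbatim, coordinates/surfaces at full
#' double precision).
#'
#' @param units a units table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_units_csv <- function(units, path) {
  out <- data.frame(unit_id = units$unit_id,
                    x_m = fmt_dbl(units$x),
                    y_m = fmt_dbl(units$y),
                    surface_km2 = fmt_dbl(units$surface),
                    out_commuters = units$out_commuters,
                    in_commuters = units$in_commuters,
                    role = units$role,
                    population = units$population,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an OD matrix from a long-format edge-list CSV
#'
#' Schema: columns `origin_id, destination_id, flow` (nonnegative
#' integers); absent pairs mean zero flow; duplicate pairs are an
#' error, not summed.
#'
#' @param path CSV file path.
#' @param origin_ids,destination_ids index sets the ids must resolve
#'   against (e.g. the case study's core / all unit ids).
#' @return an `od_matrix` (dense, zeros for absent pairs).
#' @export
read_od_csv <- function(path, origin_ids, destination_ids) {
  if (!file.exists(path)) schema_stop("file not found: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("origin_id", "destination_id", "flow"), names(raw))
  if (length(missing))
    schema_stop("missing required column(s): %s", paste(missing, collapse = ", "))
  rows <- seq_len(nrow(raw)) + 1L
  flow <- parse_int(raw$flow, "flow", rows)
  neg <- which(flow < 0)
  if (length(neg))
    schema_stop("column 'flow': negative flow at row %d", rows[neg[1]])
  bad_o <- which(!raw$origin_id %in% origin_ids)
  if (length(bad_o))
    schema_stop("column 'origin_id': unknown id '%s' at row %d",
                raw$origin_id[bad_o[1]], rows[bad_o[1]])
  bad_d <- which(!raw$destination_id %in% destination_ids)
  if (length(bad_d))
    schema_stop("column 'destination_id': unknown id '%s' at row %d",
                raw$destination_id[bad_d[1]], rows[bad_d[1]])
  key <- paste(raw$origin_id, raw$destination_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    schema_stop("duplicate (origin_id, destination_id) pair '%s, %s' at row %d",
                raw$origin_id[d], raw$destination_id[d], rows[d])
  }
  flows <- matrix(0L, length(origin_ids), length(destination_ids),
                  dimnames = list(origin_ids, destination_ids))
  if (nrow(raw))
    flows[cbind(match(raw$origin_id, origin_ids),
                match(raw$destination_id, destination_ids))] <- flow
  od_matrix(flows, origin_ids, destination_ids)
}

#' Write an OD matrix as a long-format edge-list CSV
#'
#' Rows are sorted by (origin_id, destination_id) and zero flows are
#' omitted by default, so output is bit-stable for diffing.
#'
#' @param od an `od_matrix`.
#' @param path output CSV path.
#' @param include_zeros also write zero-flow pairs.
#' @return `path`, invisibly.
#' @export
write_od_csv <- function(od, path, include_zeros = FALSE) {
  f <- flows_of(od)
  idx <- which(include_zeros | f > 0, arr.ind = TRUE)
  out <- data.frame(origin_id = rownames(f)[idx[, 1]],
                    destination_id = colnames(f)[idx[, 2]],
                    flow = f[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$origin_id, out$destination_id), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report
#'
#' Flat tabular CSV with one row per (case, model, metric), and
#' optionally a companion distance-distribution table with one row per
#' (case, model, bin).
#'
#' @param results data.frame with columns case, model, metric, value.
#' @param path output CSV path.
#' @param distance_distributions optional data.frame with columns case,
#'   model, bin_lo_km, bin_hi_km, probability.
#' @param distance_path where to write the distance table (default:
#'   `path` with `_distances` inserted before the extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, distance_distributions = NULL,
                         distance_path = sub("(\\.[^.]+)?$", "_distances\\1",
                                             path)) {
  stopifnot(all(c("case", "model", "metric", "value") %in% names(results)))
  out <- results[, c("case", "model", "metric", "value")]
  out$value <- vapply(out$value, function(v) formatC(v, digits = 12, format = "g"), "")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(distance_distributions)) {
    dd <- distance_distributions
    stopifnot(all(c("case", "model", "bin_lo_km", "bin_hi_km", "probability")
                  %in% names(dd)))
    dd$probability <- vapply(dd$probability,
                             function(v) formatC(v, digits = 12, format = "g"), "")
    write.csv(dd, distance_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export unit centroids as GeoJSON points
#'
#' Convenience export for mapping; coordinates are written as the
#' planar meters used throughout (not longitude/latitude).
#'
#' @param units a units table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_units_geojson <- function(units, path) {
  features <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(u$x, u$y)),
         properties = list(unit_id = u$unit_id, surface_km2 = u$surface,
                           population = u$population,
                           out_commuters = u$out_commuters,
                           in_commuters = u$in_commuters, role = u$role))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
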