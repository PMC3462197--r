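#' @useDynLib commod, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm rlnorm runif setNames
#' @importFrom utils read.csv write.csv
NULL

#' Build a table of geographic units
#'
#' A unit is one geographic entity (municipality, canton, county, ...):
#' a planar centroid in meters, a surface in km2, optional population,
#' and its commuter margins -- the number of commuters leaving it
#' (out-commuters) and the number working in it (in-commuters). Core
#' units are both origins and destinations; extended units belong to the
#' surrounding job-search ring added to absorb out-of-region commuting
#' and are destinations only (out_commuters forced to be 0).
#'
#' @param unit_id character identifiers, unique.
#' @param x,y planar centroid coordinates in meters (Lambert-like / GIS
#'   projected coordinates; longitude/latitude degrees are not accepted).
#' @param surface areal extent in km2, positive.
#' @param out_commuters,in_commuters nonnegative integer margins.
#' @param role "core" or "extended".
#' @param population optional nonnegative integers (required only by the
#'   radiation comparator).
#' @return a `data.frame` with one row per unit, core units first.
#' @export
units_table <- function(unit_id, x, y, surface, out_commuters, in_commuters,
                        role = "core", population = NA_integer_) {
  n <- length(unit_id)
  role <- tolower(as.character(rep_len(role, n)))
  if (!all(role %in% c("core", "extended")))
    stop("role must be 'core' or 'extended'", call. = FALSE)
  u <- data.frame(
    unit_id = as.character(unit_id),
    x = as.numeric(x), y = as.numeric(y),
    surface = as.numeric(surface),
    population = as.integer(rep_len(population, n)),
    out_commuters = as.integer(out_commuters),
    in_commuters = as.integer(in_commuters),
    role = role,
    stringsAsFactors = FALSE
  )
  u[order(u$role != "core"), , drop = FALSE]
}

#' Euclidean distance matrix between unit centroids
#'
#' @param units a units table (see [units_table()]).
#' @return symmetric matrix of Euclidean centroid distances in meters,
#'   zero diagonal, dimnames = unit ids.
#' @export
distance_matrix <- function(units) {
  if (!all(is.finite(units$x)) || !all(is.finite(units$y)))
    stop("non-finite unit coordinates", call. = FALSE)
  xy <- cbind(units$x, units$y)
  d <- as.matrix(stats::dist(xy, method = "euclidean"))
  dimnames(d) <- list(units$unit_id, units$unit_id)
  d
}

#' Assemble a case study
#'
#' A case study bundles a validated units table (core units first) with
#' its pairwise centroid distance matrix. The n core units are commuting
#' origins; all n + m units (core plus extended ring) are destinations.
#'
#' @param units a units table.
#' @param validate if TRUE (default), stop on any invariant violation.
#' @return an object of class `case_study` with elements `units`
#'   (data.frame) and `distances` (meters matrix).
#' @export
case_study <- function(units, validate = TRUE) {
  units <- units[order(units$role != "core"), , drop = FALSE]
  rownames(units) <- NULL
  cs <- structure(list(units = units, distances = distance_matrix(units)),
                  class = "case_study")
  if (validate) {
    rep <- validate_case_study(cs)
    if (!rep$valid)
      stop("invalid case study: ", paste(rep$violations, collapse = "; "),
           call. = FALSE)
  }
  cs
}

#' @export
print.case_study <- function(x, ...) {
  n_core <- sum(x$units$role == "core")
  cat(sprintf(
    "case_study: %d core + %d extended units, %d out-commuters, %d in-capacity\n",
    n_core, nrow(x$units) - n_core,
    sum(x$units$out_commuters), sum(x$units$in_commuters)))
  invisible(x)
}

#' Validate a case study
#'
#' Pure predicate: checks every structural invariant and returns a report
#' listing all violations, without mutating the input. A feasible case
#' needs total in-capacity at least equal to the total number of
#' out-commuters (the margins need not be equal: commuters may also
#' arrive from outside the study region).
#'
#' @param case a `case_study`.
#' @return list with `valid` (logical) and `violations` (character).
#' @export
validate_case_study <- function(case) {
  u <- case$units
  v <- character(0)
  bad <- function(msg) v[[length(v) + 1L]] <<- msg

  if (anyDuplicated(u$unit_id))
    bad(sprintf("duplicate unit_id: %s",
                paste(unique(u$unit_id[duplicated(u$unit_id)]), collapse = ",")))
  if (!all(is.finite(u$x)) || !all(is.finite(u$y)))
    bad("non-finite centroid coordinates")
  if (any(!is.finite(u$surface) | u$surface <= 0))
    bad("surface must be > 0 for every unit")
  if (any(!is.na(u$population) & u$population < 0))
    bad("population must be >= 0")
  if (any(u$out_commuters < 0)) bad("out_commuters must be >= 0")
  if (any(u$in_commuters < 0)) bad("in_commuters must be >= 0")
  if (any(u$out_commuters[u$role == "extended"] > 0))
    bad("extended units must have out_commuters = 0 (destinations only)")
  if (sum(u$in_commuters) < sum(u$out_commuters))
    bad(sprintf("capacity shortfall: total in-commuters (%d) < total out-commuters (%d)",
                sum(u$in_commuters), sum(u$out_commuters)))
  d <- case$distances
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0))
    bad("distance matrix must be symmetric, nonnegative, zero diagonal")

  list(valid = length(v) == 0L, violations = v)
}

#' Average surface of the geographic units
#'
#' The scale descriptor entering the power law for the distance-decay
#' parameter. By default only core units count: the extended ring is a
#' border-correction device, not part of the studied region.
#'
#' @param case a `case_study`.
#' @param include_extended include extended units in the mean.
#' @return mean surface in km2.
#' @export
average_surface <- function(case, include_extended = FALSE) {
  u <- case$units
  s <- if (include_extended) u$surface else u$surface[u$role == "core"]
  if (length(s) == 0L) stop("no core units", call. = FALSE)
  mean(s)
}

n_core_units <- function(case) sum(case$units$role == "core")

#' Construct an origin-destination matrix object
#'
#' Integer flow matrix with rows = core origin units and columns = all
#' destination units; entry (i, j) counts commuters living in i and
#' working in j.
#'
#' @param flows integer matrix (n_core x n_dest).
#' @param origin_ids,destination_ids identifier vectors.
#' @param complete FALSE if the generator starved before placing every
#'   commuter.
#' @param unplaced number of commuters left unplaced (0 when complete).
#' @return an `od_matrix`.
#' @export
od_matrix <- function(flows, origin_ids = rownames(flows),
                      destination_ids = colnames(flows),
                      complete = TRUE, unplaced = 0) {
  flows <- as.matrix(flows)
  storage.mode(flows) <- "integer"
  if (any(flows < 0)) stop("flows must be nonnegative", call. = FALSE)
  dimnames(flows) <- list(origin_ids, destination_ids)
  structure(list(flows = flows,
                 origin_ids = as.character(origin_ids),
                 destination_ids = as.character(destination_ids),
                 complete = isTRUE(complete),
                 unplaced = as.numeric(unplaced)),
            class = "od_matrix")
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("od_matrix: %d x %d, total flow %d%s\n",
              nrow(x$flows), ncol(x$flows), sum(x$flows),
              if (x$complete) "" else sprintf(" (incomplete, %g unplaced)", x$unplaced)))
  invisible(x)
}

# coerce an od_matrix (or plain matrix) to its flow matrix
flows_of <- function(od) {
  if (inherits(od, "od_matrix")) od$flows else as.matrix(od)
}
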