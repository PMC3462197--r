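# Align two OD matrices on their shared (identical) index sets.
# Matrices must index the same origins and destinations (order may
# differ); the second is reordered to match the first.
align_flows <- function(obs, sim) {
  a <- flows_of(obs); b <- flows_of(sim)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b)) ||
        !setequal(colnames(a), colnames(b)))
      stop("origin/destination index sets do not match", call. = FALSE)
    b <- b[rownames(a), colnames(a), drop = FALSE]
  } else if (!all(dim(a) == dim(b))) {
    stop("matrix dimensions do not match", call. = FALSE)
  }
  list(obs = a, sim = b)
}

#' Common part of commuters (CPC)
#'
#' Sorensen-index similarity between two origin-destination matrices:
#'   CPC = 2 * sum_ij min(T_obs, T_sim) / (N_obs + N_sim),
#' where N is each matrix's total flow. CPC is 1 iff the matrices are
#' identical and 0 iff their supports share no common mass. When
#' N_obs = N_sim it is the fraction of commuters placed on the correct
#' origin-destination pair.
#'
#' @param obs,sim `od_matrix` objects (or plain matrices) on the same
#'   origin/destination index sets.
#' @return scalar in \[0, 1\].
#' @export
cpc <- function(obs, sim) {
  m <- align_flows(obs, sim)
  n_obs <- sum(m$obs); n_sim <- sum(m$sim)
  if (n_obs + n_sim == 0) stop("both matrices are all-zero", call. = FALSE)
  2 * sum(pmin(m$obs, m$sim)) / (n_obs + n_sim)
}

#' Mean absolute error between OD matrices
#'
#' Mean over all cells of the compared index set (zero-zero cells
#' included) of |T_sim - T_obs|.
#' @inheritParams cpc
#' @return nonnegative scalar.
#' @export
mae <- function(obs, sim) {
  m <- align_flows(obs, sim)
  mean(abs(m$sim - m$obs))
}

#' Root mean square error between OD matrices
#' @inheritParams cpc
#' @return nonnegative scalar.
#' @export
rmse <- function(obs, sim) {
  m <- align_flows(obs, sim)
  sqrt(mean((m$sim - m$obs)^2))
}

#' Normalized mean absolute error between OD matrices
#'
#' Total absolute error divided by the total observed flow,
#' sum |T_sim - T_obs| / N_obs: scale-free and, like CPC, tied to the
#' total number of observed commuters.
#' @inheritParams cpc
#' @return nonnegative scalar.
#' @export
nmae <- function(obs, sim) {
  m <- align_flows(obs, sim)
  n_obs <- sum(m$obs)
  if (n_obs == 0) stop("NMAE undefined: observed total flow is 0", call. = FALSE)
  sum(abs(m$sim - m$obs)) / n_obs
}

#' All flow-comparison statistics at once
#' @inheritParams cpc
#' @return list with cpc, mae, nmae, rmse, n_obs, n_sim.
#' @export
compare_flows <- function(obs, sim) {
  m <- align_flows(obs, sim)
  n_obs <- sum(m$obs); n_sim <- sum(m$sim)
  list(cpc = cpc(m$obs, m$sim), mae = mae(m$obs, m$sim),
       nmae = nmae(m$obs, m$sim), rmse = rmse(m$obs, m$sim),
       n_obs = n_obs, n_sim = n_sim)
}

# distances aligned to an OD matrix: rows = origins, cols = destinations
distances_for_od <- function(od, distances) {
  f <- flows_of(od)
  d <- as.matrix(distances)
  if (!is.null(rownames(f)) && !is.null(rownames(d)))
    d <- d[rownames(f), colnames(f), drop = FALSE]
  if (!all(dim(d) == dim(f)))
    stop("distance matrix does not cover the OD index sets", call. = FALSE)
  d
}

#' Flow-weighted mean commute distance
#'
#' @param od an `od_matrix` (or flow matrix); real-valued comparator
#'   matrices are accepted.
#' @param distances distance matrix in meters covering the OD index sets
#'   (e.g. `case$distances`).
#' @return mean commuting distance in km.
#' @export
mean_commute_distance <- function(od, distances) {
  f <- if (inherits(od, "od_matrix")) od$flows else as.matrix(od)
  d <- distances_for_od(f, distances)
  total <- sum(f)
  if (total <= 0) stop("mean commute distance undefined: total flow is 0",
                       call. = FALSE)
  sum(f * d) / total / 1000
}

#' Commuting distance distribution
#'
#' Histogram of commuters by trip distance: probability that a commuter
#' of the region commutes at a distance within each half-open bin
#' \[k w, (k+1) w).
#'
#' @inheritParams mean_commute_distance
#' @param bin_width_km bin width w in km, > 0 (default 2).
#' @return list with `bin_edges` (km, length nbins + 1), `probability`
#'   (per bin, sums to 1), and `mean_distance` (km).
#' @export
distance_distribution <- function(od, distances, bin_width_km = 2) {
  if (!is.finite(bin_width_km) || bin_width_km <= 0)
    stop("bin_width_km must be > 0", call. = FALSE)
  f <- if (inherits(od, "od_matrix")) od$flows else as.matrix(od)
  d_km <- distances_for_od(f, distances) / 1000
  total <- sum(f)
  if (total <= 0) stop("distance distribution undefined: total flow is 0",
                       call. = FALSE)
  bin <- floor(d_km / bin_width_km)  # half-open [k w, (k+1) w)
  nbins <- max(bin[f > 0]) + 1L
  counts <- vapply(seq_len(nbins) - 1L,
                   function(k) sum(f[bin == k]), numeric(1))
  list(bin_edges = (0:nbins) * bin_width_km,
       probability = counts / total,
       mean_distance = sum(f * d_km) / total)
}
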