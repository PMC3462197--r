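#' Destination-choice probabilities for one origin
#'
#' Probability that the next commuter leaving origin i works in unit j:
#' proportional to the remaining in-capacity of j times an exponential
#' distance-decay factor,
#'   p_j  propto  s_j^in(t) * exp(-beta * d_ij),
#' over eligible destinations (remaining capacity > 0, and j != i under
#' the default self-loop policy). beta = 0 makes the choice independent
#' of distance; large beta concentrates all mass on the nearest
#' destinations.
#'
#' @param origin_index column index of the origin among the destinations
#'   (used for self-exclusion; NA for an origin that is not a destination).
#' @param remaining_in integer vector of remaining in-capacity, one per
#'   destination.
#' @param distance_row distances from the origin to every destination, meters.
#' @param beta distance-decay parameter, 1/meters, >= 0.
#' @param self_loop_policy "exclude" (default) or "include".
#' @return probability vector summing to 1, with exact zeros on
#'   ineligible destinations; a vector of NA with attribute
#'   `starved = TRUE` when no destination is eligible.
#' @export
destination_probabilities <- function(origin_index, remaining_in, distance_row,
                                      beta,
                                      self_loop_policy = c("exclude", "include")) {
  self_loop_policy <- match.arg(self_loop_policy)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  w <- as.numeric(remaining_in) * exp(-beta * as.numeric(distance_row))
  w[remaining_in <= 0] <- 0
  if (self_loop_policy == "exclude" && !is.na(origin_index))
    w[origin_index] <- 0
  s <- sum(w)
  if (s <= 0)
    return(structure(rep(NA_real_, length(w)), starved = TRUE))
  w / s
}

# Build the decay matrix exp(-beta * d) for core origins x all
# destinations, with ineligible (self) cells zeroed.
decay_matrix <- function(case, beta, self_loop_policy = "exclude") {
  n_core <- n_core_units(case)
  decay <- exp(-beta * case$distances[seq_len(n_core), , drop = FALSE])
  if (self_loop_policy == "exclude")
    decay[cbind(seq_len(n_core), seq_len(n_core))] <- 0
  decay
}

run_allocation <- function(case, decay, seed, uniform_dest, origin_selection) {
  u <- case$units
  n_core <- n_core_units(case)
  set.seed(seed)
  res <- allocate_commuters_cpp(u$out_commuters[seq_len(n_core)],
                                u$in_commuters, decay,
                                uniform_dest,
                                origin_selection == "by_remaining")
  od_matrix(res$flows,
            origin_ids = u$unit_id[seq_len(n_core)],
            destination_ids = u$unit_id,
            complete = res$unplaced == 0,
            unplaced = res$unplaced)
}

#' Generate a commuting network
#'
#' The stochastic allocation model: starting from the per-unit margins
#' (out-commuters of each core unit, in-capacity of every unit),
#' commuters are placed one at a time. Each step picks an origin at
#' random among units with remaining out-commuters, draws its
#' destination with probability proportional to remaining in-capacity
#' times exp(-beta * distance), records the trip and decrements both
#' margins. The loop ends when every out-commuter is placed (or every
#' remaining origin is starved, in which case the partial matrix is
#' returned flagged incomplete).
#'
#' For a complete run the returned matrix reproduces the out-margins
#' exactly (row sums), never exceeds the in-margins (column sums), and
#' its total flow equals the total number of out-commuters. A fixed
#' (case, beta, seed) triple yields a bit-identical matrix.
#'
#' @param case a valid `case_study`.
#' @param beta distance-decay parameter, 1/meters, >= 0.
#' @param seed integer RNG seed.
#' @param self_loop_policy "exclude" (default; commuters do not work in
#'   their residence unit) or "include".
#' @param origin_selection "uniform" (default: uniformly among units with
#'   remaining out-commuters) or "by_remaining" (proportional to remaining
#'   out-commuters, i.e. uniform over unplaced individuals). The two
#'   differ only in allocation order; final margins are identical.
#' @return an `od_matrix`.
#' @export
generate_network <- function(case, beta, seed,
                             self_loop_policy = c("exclude", "include"),
                             origin_selection = c("uniform", "by_remaining")) {
  self_loop_policy <- match.arg(self_loop_policy)
  origin_selection <- match.arg(origin_selection)
  if (!is.finite(beta) || beta < 0) stop("beta must be finite and >= 0", call. = FALSE)
  decay <- decay_matrix(case, beta, self_loop_policy)
  run_allocation(case, decay, seed, uniform_dest = FALSE,
                 origin_selection = origin_selection)
}

#' Generate a uniform-random baseline network
#'
#' Same sequential allocation loop as [generate_network()], but the
#' destination probabilities are uniform over eligible destinations
#' (remaining in-capacity > 0, self excluded under the default policy)
#' instead of capacity- and distance-weighted. Capacity is still
#' decremented, so the baseline differs from the model only in the
#' destination-choice probabilities.
#'
#' @inheritParams generate_network
#' @return an `od_matrix`.
#' @export
generate_random_network <- function(case, seed,
                                    self_loop_policy = c("exclude", "include"),
                                    origin_selection = c("uniform", "by_remaining")) {
  self_loop_policy <- match.arg(self_loop_policy)
  origin_selection <- match.arg(origin_selection)
  decay <- decay_matrix(case, beta = 0, self_loop_policy)
  run_allocation(case, decay, seed, uniform_dest = TRUE,
                 origin_selection = origin_selection)
}
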