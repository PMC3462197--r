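#' Intervening mass inside the circle of radius d_ij
#'
#' Total mass of the units strictly inside the circle of radius d_ij
#' centred at i, excluding the source i and the destination j
#' themselves. Units exactly at the radius are outside the circle; a
#' small tolerance can absorb floating-point ties (a unit k counts iff
#' d_ik < d_ij - tol).
#'
#' @param i,j unit indices (i != j).
#' @param masses mass vector over units (population, or in-commuters for
#'   the margin-based radiation variant).
#' @param distances full distance matrix, meters.
#' @param tol nonnegative radius tolerance in meters (default 0).
#' @return scalar intervening mass.
#' @export
circle_mass <- function(i, j, masses, distances, tol = 0) {
  if (i == j) stop("circle_mass requires i != j", call. = FALSE)
  d <- distances[i, ]
  inside <- d < distances[i, j] - tol
  inside[c(i, j)] <- FALSE
  sum(masses[inside])
}

#' Radiation model OD matrix
#'
#' Parameter-free intervening-opportunities model: the expected flow
#' from i to j is
#'   T_ij = T_i * m_i n_j / ((m_i + s_ij)(m_i + n_j + s_ij)),
#' where m_i, n_j are unit populations, s_ij the population strictly
#' inside the circle of radius d_ij centred at i (source and destination
#' excluded), and T_i = m_i * N_c / N the out-flux of i given total
#' commuters N_c and total population N.
#'
#' The analytical approximation is used as published: row sums are not
#' rescaled to the origin out-flux (a finite-size property), unless
#' `normalize_rows = TRUE`.
#'
#' @param case a valid `case_study` whose units carry populations.
#' @param populations optional population vector overriding
#'   `case$units$population`.
#' @param total_commuters N_c; defaults to the case's total out-commuters.
#' @param normalize_rows rescale each row to sum to T_i (off by default).
#' @param tol radius tolerance passed to [circle_mass()].
#' @return real-valued flow matrix, core origins x all destinations,
#'   zero diagonal.
#' @export
radiation_matrix <- function(case, populations = NULL, total_commuters = NULL,
                             normalize_rows = FALSE, tol = 0) {
  u <- case$units
  m <- if (is.null(populations)) u$population else rep_len(populations, nrow(u))
  if (any(is.na(m))) stop("population missing for some units", call. = FALSE)
  if (any(m < 0)) stop("populations must be >= 0", call. = FALSE)
  N <- sum(m)
  Nc <- if (is.null(total_commuters)) sum(u$out_commuters) else total_commuters
  if (Nc <= 0) stop("total_commuters must be > 0", call. = FALSE)
  emission <- m * Nc / N
  rad_core(case, masses = m, emission = emission, normalize_rows, tol)
}

#' Margin-based (modified) radiation model OD matrix
#'
#' Radiation-model structure fed with commuter margins instead of
#' populations, so it uses the same inputs as the allocation model: the
#' origin out-flux is the observed out-commuters O_i, and every mass is
#' an in-commuter count,
#'   T_ij = O_i * I_i I_j / ((I_i + s_ij)(I_i + I_j + s_ij)),
#' with s_ij the in-commuters strictly inside the circle of radius d_ij
#' centred at i (source and destination excluded).
#'
#' @inheritParams radiation_matrix
#' @return real-valued flow matrix, core origins x all destinations,
#'   zero diagonal.
#' @export
modified_radiation_matrix <- function(case, normalize_rows = FALSE, tol = 0) {
  u <- case$units
  rad_core(case, masses = u$in_commuters,
           emission = u$out_commuters, normalize_rows, tol)
}

# shared radiation arithmetic: emission[i] * (mass_i * mass_j) /
# ((mass_i + s_ij) * (mass_i + mass_j + s_ij)); 0/0 -> 0
rad_core <- function(case, masses, emission, normalize_rows, tol) {
  u <- case$units
  n_core <- n_core_units(case)
  n_all <- nrow(u)
  masses <- as.numeric(masses)
  flows <- matrix(0, n_core, n_all,
                  dimnames = list(u$unit_id[seq_len(n_core)], u$unit_id))
  for (i in seq_len(n_core)) {
    if (emission[i] <= 0) next
    for (j in seq_len(n_all)) {
      if (j == i) next
      s <- circle_mass(i, j, masses, case$distances, tol)
      num <- masses[i] * masses[j]
      if (num == 0) next
      flows[i, j] <- emission[i] * num /
        ((masses[i] + s) * (masses[i] + masses[j] + s))
    }
    if (normalize_rows) {
      rs <- sum(flows[i, ])
      if (rs > 0) flows[i, ] <- flows[i, ] * emission[i] / rs
    }
  }
  flows
}

#' Stochastically round a real-valued flow matrix to integers
#'
#' Each cell is floored, then incremented with probability equal to its
#' fractional part; expectation equals the input.
#'
#' @param flows real-valued nonnegative matrix.
#' @param seed RNG seed.
#' @return integer matrix with the same dimnames.
#' @export
stochastic_round <- function(flows, seed) {
  set.seed(seed)
  f <- floor(flows)
  frac <- flows - f
  out <- f + (runif(length(flows)) < frac)
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(flows)
  out
}
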