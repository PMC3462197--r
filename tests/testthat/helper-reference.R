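# Pure-R reference allocator. Mirrors the compiled allocation loop
# draw-for-draw (same RNG consumption, same accumulation order), so a
# fixed seed must reproduce the installed implementation bit for bit on
# any instance. Deliberately naive: recomputes the full weight row at
# every step.
ref_allocate <- function(out0, in0, decay, uniform_dest = FALSE,
                         origin_by_mass = FALSE) {
  n_core <- nrow(decay); n_dest <- ncol(decay)
  rem_out <- as.integer(out0); rem_in <- as.integer(in0)
  flows <- matrix(0L, n_core, n_dest)
  active <- which(rem_out > 0)
  unplaced <- 0
  while (length(active) > 0) {
    n_active <- length(active)
    if (n_active == 1L) {
      pos <- 1L
    } else if (origin_by_mass) {
      tot <- 0
      for (p in seq_len(n_active)) tot <- tot + rem_out[active[p]]
      target <- runif(1) * tot
      cum <- 0; pos <- n_active
      for (p in seq_len(n_active)) {
        cum <- cum + rem_out[active[p]]
        if (cum > target) { pos <- p; break }
      }
    } else {
      pos <- as.integer(runif(1) * n_active) + 1L
      if (pos > n_active) pos <- n_active
    }
    i <- active[pos]

    S <- 0
    for (j in seq_len(n_dest)) {
      if (rem_in[j] <= 0) next
      S <- S + if (uniform_dest) as.numeric(decay[i, j] > 0)
               else decay[i, j] * rem_in[j]
    }
    if (S <= 0) {
      unplaced <- unplaced + rem_out[i]
      rem_out[i] <- 0L
      active[pos] <- active[n_active]
      active <- active[-n_active]
      next
    }
    target <- runif(1) * S
    cum <- 0; j_pick <- -1L; last_j <- -1L
    for (j in seq_len(n_dest)) {
      if (rem_in[j] <= 0) next
      w <- if (uniform_dest) as.numeric(decay[i, j] > 0) else decay[i, j] * rem_in[j]
      if (w <= 0) next
      last_j <- j
      cum <- cum + w
      if (cum > target) { j_pick <- j; break }
    }
    if (j_pick < 0) j_pick <- last_j

    flows[i, j_pick] <- flows[i, j_pick] + 1L
    rem_out[i] <- rem_out[i] - 1L
    rem_in[j_pick] <- rem_in[j_pick] - 1L
    if (rem_out[i] == 0L) {
      active[pos] <- active[n_active]
      active <- active[-n_active]
    }
  }
  list(flows = flows, unplaced = unplaced, remaining_in = rem_in)
}

# reference generate_network built on ref_allocate (same decay matrix
# construction as the package)
ref_generate <- function(case, beta, seed, uniform_dest = FALSE,
                         origin_by_mass = FALSE, self_loop = "exclude") {
  u <- case$units
  n_core <- sum(u$role == "core")
  decay <- exp(-beta * case$distances[seq_len(n_core), , drop = FALSE])
  if (self_loop == "exclude")
    decay[cbind(seq_len(n_core), seq_len(n_core))] <- 0
  set.seed(seed)
  ref_allocate(u$out_commuters[seq_len(n_core)], u$in_commuters, decay,
               uniform_dest, origin_by_mass)
}

# small hand-laid case: n core units on a line plus optional extended ring
line_case <- function(out, inn, spacing_m = 2000, roles = NULL,
                      surface = 10, population = NA) {
  n <- length(inn)
  if (is.null(roles)) roles <- rep("core", n)
  case_study(units_table(
    unit_id = sprintf("L%02d", seq_len(n)),
    x = (seq_len(n) - 1) * spacing_m, y = rep(0, n),
    surface = surface,
    out_commuters = c(out, rep(0L, n - length(out))),
    in_commuters = inn, role = roles, population = population))
}

# random small synthetic case for property sweeps; unit counts and
# capacity surplus kept away from the degenerate corner where one unit
# dominates both margins
random_small_case <- function(seed) {
  set.seed(seed)
  synth_case_study(synth_config(
    n_core = sample(6:15, 1), n_extended = sample(0:3, 1),
    extent_km = runif(1, 20, 80), pop_median = 150, pop_sigma = 0.7,
    commuter_fraction = runif(1, 0.05, 0.3),
    capacity_surplus = runif(1, 0.2, 1),
    beta_true = 10^runif(1, -4.5, -3.3), seed = seed))
}

# brute-force metric oracles (independent per-cell loops)
brute_cpc <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + min(a[i, j], b[i, j])
  2 * s / (sum(a) + sum(b))
}
brute_mae <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + abs(b[i, j] - a[i, j])
  s / length(a)
}
brute_rmse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (b[i, j] - a[i, j])^2
  sqrt(s / length(a))
}
brute_nmae <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + abs(b[i, j] - a[i, j])
  s / sum(a)
}

rand_flow_matrix <- function(nr = 10, nc = 12, max_flow = 30) {
  m <- matrix(sample(0:max_flow, nr * nc, replace = TRUE), nr, nc,
              dimnames = list(sprintf("o%02d", 1:nr), sprintf("d%02d", 1:nc)))
  m
}
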