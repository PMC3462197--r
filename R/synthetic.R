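#' Configuration for a synthetic case study
#'
#' Defines a self-contained synthetic commuting region with the
#' statistical structure the allocation model assumes: core units
#' scattered uniformly over a square region, an extended ring of
#' destination-only units around it, heavy-tailed (lognormal) unit
#' populations, commuter margins proportional to population, and
#' ground-truth flows produced by the distance-decay allocation process
#' itself at a known beta.
#'
#' @param n_core number of core units (>= 2); default 30.
#' @param n_extended number of destination-only ring units; default 8.
#' @param extent_km side of the square core region, km; default 100.
#' @param surface_mean_km2 mean unit surface; defaults to
#'   extent^2 / n_core (units tile the region on average).
#' @param pop_median median unit population (lognormal); default 2000.
#' @param pop_sigma sigma of log population; default 1.
#' @param commuter_fraction fraction of a core unit's population
#'   commuting out; default 0.1.
#' @param capacity_surplus fractional excess of provisional in-capacity
#'   over total out-commuters (default 0.2). Real regions offer more
#'   jobs than any one realization fills -- the extended ring exists to
#'   absorb exactly this -- and with no surplus a unit holding a large
#'   share of both margins cannot place its own commuters (self-loops
#'   excluded). The surplus only shapes the provisional capacity; the
#'   final margins are back-filled from the realized ground truth and
#'   balance exactly.
#' @param beta_true ground-truth distance-decay parameter, 1/meters;
#'   default 2e-4.
#' @param seed RNG seed.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_core = 30, n_extended = 8, extent_km = 100,
                         surface_mean_km2 = extent_km^2 / n_core,
                         pop_median = 2000, pop_sigma = 1,
                         commuter_fraction = 0.1, capacity_surplus = 0.2,
                         beta_true = 2e-4, seed = 1) {
  cfg <- list(n_core = as.integer(n_core), n_extended = as.integer(n_extended),
              extent_km = extent_km, surface_mean_km2 = surface_mean_km2,
              pop_median = pop_median, pop_sigma = pop_sigma,
              commuter_fraction = commuter_fraction,
              capacity_surplus = capacity_surplus, beta_true = beta_true,
              seed = as.integer(seed))
  stopifnot(cfg$n_core >= 2, cfg$n_extended >= 0, cfg$extent_km > 0,
            cfg$surface_mean_km2 > 0, cfg$pop_median > 0, cfg$pop_sigma >= 0,
            cfg$commuter_fraction > 0, cfg$commuter_fraction <= 1,
            cfg$capacity_surplus >= 0, cfg$beta_true >= 0)
  structure(cfg, class = "synth_config")
}

# largest-remainder integerization of nonnegative reals to a fixed total
integerize_to_total <- function(x, total) {
  if (sum(x) == 0) x <- rep(1, length(x))
  target <- x / sum(x) * total
  fl <- floor(target)
  short <- as.integer(round(total - sum(fl)))
  if (short > 0) {
    idx <- order(target - fl, decreasing = TRUE)[seq_len(short)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

# In-capacity proportional to weight, but capped per unit at
# total - out_i: under the self-loop exclusion a unit's own workers
# cannot fill its jobs, so feasibility requires every unit to leave at
# least out_i capacity elsewhere. Excess above a cap is redistributed
# proportionally among unsaturated units.
bounded_proportional_capacity <- function(weight, out, total) {
  n <- length(weight)
  cap <- total - out                 # sum(cap) = (n-1) * total >= total for n >= 2
  inn <- rep(0L, n)
  remaining <- total
  repeat {
    open <- which(inn < cap & weight > 0)
    if (!length(open)) open <- which(inn < cap)
    add <- integerize_to_total(weight[open], remaining)
    inn[open] <- inn[open] + add
    over <- pmax(inn - cap, 0L)
    inn <- pmin(inn, cap)
    remaining <- sum(over)
    if (remaining == 0L) break
  }
  as.integer(inn)
}

#' Draw a synthetic units table
#'
#' Core centroids uniform in the extent square; extended centroids on a
#' surrounding ring. Surfaces are the configured mean jittered +/-20%;
#' populations lognormal; out-commuters = round(fraction * population)
#' for core units (0 for extended); provisional in-commuters
#' proportional to population (capped at feasibility per unit),
#' integerized so total in-capacity carries the configured surplus over
#' total out.
#'
#' @param config a `synth_config`.
#' @return a units table (see [units_table()]).
#' @export
synth_units <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ext_m <- config$extent_km * 1000
  nc <- config$n_core; ne <- config$n_extended; n <- nc + ne

  x <- runif(nc, 0, ext_m)
  y <- runif(nc, 0, ext_m)
  if (ne > 0) {
    # ring fully outside the square: radius in [0.75, 1.0] * extent from center
    ang <- runif(ne, 0, 2 * pi)
    rad <- runif(ne, 0.75, 1.0) * ext_m
    x <- c(x, ext_m / 2 + rad * cos(ang))
    y <- c(y, ext_m / 2 + rad * sin(ang))
  }
  surface <- config$surface_mean_km2 * runif(n, 0.8, 1.2)
  population <- pmax(1L, as.integer(round(
    rlnorm(n, meanlog = log(config$pop_median), sdlog = config$pop_sigma))))
  out <- ifelse(seq_len(n) <= nc,
                as.integer(round(config$commuter_fraction * population)), 0L)
  total_in <- as.integer(ceiling((1 + config$capacity_surplus) * sum(out)))
  inn <- bounded_proportional_capacity(population, out, total_in)

  units_table(unit_id = sprintf("u%03d", seq_len(n)),
              x = x, y = y, surface = surface,
              out_commuters = out, in_commuters = inn,
              role = rep(c("core", "extended"), c(nc, ne)),
              population = population)
}

#' Build a synthetic case study with known ground truth
#'
#' Draws units, generates the ground-truth OD matrix by running the
#' allocation model at `beta_true` on the provisional margins, then
#' replaces each unit's margins with the realized row/column sums of
#' the ground truth. The case study is therefore exactly
#' self-consistent -- its margins are the marginals of its (normally
#' unobserved) true OD matrix, as census margins are -- and validation
#' passes with in-capacity equal to out-commuters.
#'
#' @param config a `synth_config`.
#' @return list with `case` (case_study), `ground_truth` (od_matrix),
#'   `beta_true`, `config`.
#' @export
synth_case_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  # a starved draw means the sampled geometry/margins were adversarial
  # (e.g. one unit holding most of both margins): redraw the whole case
  # from the next seed rather than replaying the same units
  gt <- NULL
  for (attempt in 0:4) {
    cfg_try <- config
    cfg_try$seed <- config$seed + attempt
    units <- synth_units(cfg_try)
    case0 <- case_study(units)
    g <- generate_network(case0, config$beta_true, seed = cfg_try$seed)
    if (g$complete) { gt <- g; break }
  }
  if (is.null(gt))
    stop("ground-truth generation starved in 5 attempts", call. = FALSE)

  nc <- n_core_units(case0)
  units$out_commuters <- c(as.integer(rowSums(gt$flows)),
                           rep(0L, nrow(units) - nc))
  units$in_commuters <- as.integer(colSums(gt$flows))
  case <- case_study(units)
  list(case = case, ground_truth = gt,
       beta_true = config$beta_true, config = config)
}

#' Build a suite of synthetic case studies obeying a planted surface law
#'
#' Case surfaces are log-spaced over `surface_range`; each case's
#' ground-truth beta is alpha * S^(-nu), so the calibrated betas of the
#' suite should recover the planted law. The region extent of each case
#' is set so its units tile the target surface
#' (extent = sqrt(S * n_core)).
#'
#' @param n_cases number of cases (>= 3).
#' @param alpha,nu planted law parameters (alpha in 1/meters at S = 1 km2).
#' @param surface_range range of mean unit surfaces, km2.
#' @param base_config `synth_config` whose non-geometry fields are
#'   reused for every case.
#' @param seed suite seed; case k uses seed + k.
#' @return list of elements as returned by [synth_case_study()], each
#'   with an added `observation` data.frame row (case_id, mean_surface
#'   = planted S, beta_true).
#' @export
synth_law_suite <- function(n_cases = 10, alpha = 1e-3, nu = 0.5,
                            surface_range = c(1, 400),
                            base_config = synth_config(), seed = 1) {
  stopifnot(n_cases >= 3)
  surfaces <- 10^seq(log10(surface_range[1]), log10(surface_range[2]),
                     length.out = n_cases)
  lapply(seq_len(n_cases), function(k) {
    S <- surfaces[k]
    cfg <- synth_config(
      n_core = base_config$n_core, n_extended = base_config$n_extended,
      extent_km = sqrt(S * base_config$n_core), surface_mean_km2 = S,
      pop_median = base_config$pop_median, pop_sigma = base_config$pop_sigma,
      commuter_fraction = base_config$commuter_fraction,
      beta_true = alpha * S^(-nu), seed = seed + k)
    out <- synth_case_study(cfg)
    out$case_id <- sprintf("synth%02d", k)
    out$observation <- data.frame(case_id = out$case_id, mean_surface = S,
                                  beta_true = cfg$beta_true)
    out
  })
}
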