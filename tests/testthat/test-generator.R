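test_that("destination probabilities follow capacity-weighted exponential decay", {
  # beta = 0: independent of distance
  expect_equal(
    destination_probabilities(NA, remaining_in = c(5, 5, 5, 5),
                              distance_row = c(1e3, 5e3, 2e4, 9e4), beta = 0),
    rep(0.25, 4))
  # direct evaluation of the decay law
  e <- exp(-1e-3 * c(1000, 2000))
  expect_equal(
    destination_probabilities(NA, c(1, 1), c(1000, 2000), beta = 1e-3),
    e / sum(e))
  expect_equal(
    destination_probabilities(NA, c(1, 1), c(1000, 2000), beta = 1e-3),
    c(0.73106, 0.26894), tolerance = 1e-4)
  # equal distances: capacity ratio alone, for any beta
  for (b in c(0, 1e-4, 5e-3))
    expect_equal(
      destination_probabilities(NA, c(2, 1), c(800, 800), beta = b),
      c(2, 1) / 3)
})

test_that("destination probabilities zero out ineligible destinations and flag starvation", {
  p <- destination_probabilities(2, remaining_in = c(3, 5, 0),
                                 distance_row = c(1000, 0, 700), beta = 1e-3)
  expect_equal(p[2], 0)           # self excluded
  expect_equal(p[3], 0)           # exhausted capacity
  expect_equal(sum(p), 1)
  starved <- destination_probabilities(1, remaining_in = c(4, 0),
                                       distance_row = c(0, 500), beta = 0)
  expect_true(isTRUE(attr(starved, "starved")))
})

test_that("forced and empty allocations behave exactly", {
  # one origin, one distinct destination: single flow of 5
  cs <- line_case(out = 5L, inn = c(0L, 5L), roles = c("core", "extended"))
  od <- generate_network(cs, beta = 3e-4, seed = 1)
  expect_true(od$complete)
  expect_equal(unname(od$flows), matrix(c(0L, 5L), 1))
  # random baseline coincides when there is no choice
  expect_equal(generate_random_network(cs, seed = 1)$flows, od$flows)
  # no out-commuters: zero matrix
  cs0 <- line_case(out = c(0L, 0L), inn = c(3L, 3L))
  expect_equal(sum(generate_network(cs0, 1e-4, seed = 2)$flows), 0L)
})

test_that("generated networks conserve margins and are seed-deterministic", {
  # provisional-margin case: in-capacity carries surplus, so runs complete
  case <- case_study(synth_units(synth_config(n_core = 12, n_extended = 3,
                                              pop_median = 300, seed = 7)))
  out0 <- case$units$out_commuters[case$units$role == "core"]
  in0 <- case$units$in_commuters
  for (beta in c(0, 2e-4)) {
    od <- generate_network(case, beta, seed = 5)
    expect_true(od$complete)
    expect_equal(unname(rowSums(od$flows)), as.numeric(out0))
    expect_true(all(colSums(od$flows) <= in0))
    expect_equal(sum(od$flows), sum(out0))
    expect_true(all(diag(od$flows[, seq_len(nrow(od$flows)), drop = FALSE]) == 0))
    # bit-identical under the same seed, different under another
    expect_identical(od$flows, generate_network(case, beta, seed = 5)$flows)
    expect_false(identical(od$flows, generate_network(case, beta, seed = 6)$flows))
  }
})

test_that("compiled allocator equals the naive R reference seed for seed", {
  for (seed in c(3, 11, 27)) {
    sc <- random_small_case(seed)
    for (beta in c(0, 1e-4, 8e-4)) {
      od <- generate_network(sc$case, beta, seed = seed + 100)
      ref <- ref_generate(sc$case, beta, seed = seed + 100)
      expect_identical(unname(od$flows), ref$flows)
    }
    # uniform baseline and mass-weighted origin selection too
    expect_identical(
      unname(generate_random_network(sc$case, seed = seed)$flows),
      ref_generate(sc$case, 0, seed = seed, uniform_dest = TRUE)$flows)
    expect_identical(
      unname(generate_network(sc$case, 3e-4, seed = seed,
                              origin_selection = "by_remaining")$flows),
      ref_generate(sc$case, 3e-4, seed = seed, origin_by_mass = TRUE)$flows)
  }
})

test_that("origin selection variants leave final margins identical on complete runs", {
  case <- case_study(synth_units(synth_config(n_core = 8, n_extended = 2,
                                              pop_median = 250, seed = 5)))
  a <- generate_network(case, 2e-4, seed = 9)
  b <- generate_network(case, 2e-4, seed = 9, origin_selection = "by_remaining")
  expect_true(a$complete && b$complete)
  expect_equal(rowSums(a$flows), rowSums(b$flows))
  expect_equal(sum(a$flows), sum(b$flows))
})

test_that("self-loop policy controls the diagonal", {
  cs <- line_case(out = c(10L, 10L), inn = c(15L, 15L), spacing_m = 500)
  od_ex <- generate_network(cs, beta = 0, seed = 4)
  expect_true(all(diag(od_ex$flows) == 0))
  od_in <- generate_network(cs, beta = 0, seed = 4, self_loop_policy = "include")
  expect_gt(sum(diag(od_in$flows)), 0)
})

test_that("starved origins yield a flagged partial matrix", {
  # all remaining capacity sits on the origin itself (self excluded)
  cs <- line_case(out = 5L, inn = c(10L, 2L))
  od <- generate_network(cs, beta = 1e-4, seed = 8)
  expect_false(od$complete)
  expect_equal(od$unplaced, 3)
  expect_equal(sum(od$flows), 2)
})

test_that("beta = 0 allocation follows the multivariate hypergeometric law", {
  # 1 origin (out = 4), capacities 30/10: sequential capacity-proportional
  # draws with decrement are exactly multivariate hypergeometric
  cs <- line_case(out = 4L, inn = c(0L, 30L, 10L),
                  roles = c("core", "extended", "extended"))
  n_runs <- 20000
  k1 <- integer(n_runs)
  for (s in seq_len(n_runs))
    k1[s] <- generate_network(cs, beta = 0, seed = s)$flows[1, 2]
  expect_equal(mean(k1), 3.0, tolerance = 0.01)
  obs <- tabulate(k1 + 1L, nbins = 5L)
  expected <- n_runs * dhyper(0:4, 30, 10, 4)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.99, df = 4))
})

test_that("uniform baseline splits equally between equidistant equal-capacity destinations", {
  cs <- case_study(units_table(
    c("o", "d1", "d2"), x = c(0, 2000, -2000), y = 0, surface = 1,
    out_commuters = c(10000L, 0L, 0L), in_commuters = c(0L, 20000L, 20000L),
    role = c("core", "extended", "extended")))
  f <- generate_random_network(cs, seed = 31)$flows
  # binomial(10000, 1/2) 99% CI around 5000
  half_ci <- qnorm(0.995) * sqrt(10000 * 0.25)
  expect_lt(abs(f[1, "d1"] - 5000), half_ci + 1)
})

test_that("mean commute distance decreases with beta", {
  # ample destination capacity, so stronger decay shortens trips instead
  # of merely reshuffling which commuters saturate the nearby capacity
  case <- case_study(synth_units(synth_config(n_core = 15, n_extended = 4,
                                              extent_km = 60, pop_median = 400,
                                              capacity_surplus = 1, seed = 13)))
  betas <- c(0, 1e-4, 3e-4, 1e-3)
  mean_d <- vapply(betas, function(b) {
    mean(vapply(1:20, function(s)
      mean_commute_distance(generate_network(case, b, seed = s),
                            case$distances), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_d) <= 0))
})
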