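const_model <- function(ne = 1e4, ...) {
  demography_model(epochs = cbind(0, ne), mu_per_gen = 1e-8,
                   r_per_gen = 1e-8, ...)
}

test_that("no recombination gives a single segment spanning the contig", {
  mod <- demography_model(epochs = cbind(0, 1e4), r_per_gen = 0)
  tr <- sample_pairwise_tmrca(mod, 12345, seed = 1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$length, 12345L)
})

test_that("initial TMRCA draws match the analytic pairwise coalescent", {
  # constant Ne: mean of independent draws near 2N
  mod <- const_model(1e4)
  set.seed(100)
  draws <- replicate(1e4, popcoal:::coal_time_from(mod, 0))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 2e4), 3 * se)

  # bottleneck demography: Kolmogorov distance to the analytic
  # piecewise-exponential CDF
  ep <- rbind(c(0, 1e4), c(2e4, 1e3), c(5e4, 1e4))
  mod2 <- demography_model(epochs = ep)
  set.seed(101)
  draws2 <- replicate(1e4, popcoal:::coal_time_from(mod2, 0))
  grid <- sort(draws2)
  ks <- max(abs(seq_along(grid) / length(grid) - coal_cdf(grid, ep)))
  expect_lt(ks, 0.02)
})

test_that("segment lengths are exponential with rate 2*T*r given T", {
  # pin T by flooring coalescence far above the size fluctuations
  tau <- 1e7
  mod <- demography_model(epochs = cbind(0, 1e4), split_time = tau,
                          mu_per_gen = 1e-8, r_per_gen = 1e-10)
  tr <- sample_pairwise_tmrca(mod, 5.2e6, seed = 8, min_time = tau)
  lens <- tr$length[-nrow(tr)]  # last segment is truncated by the contig end
  expect_gt(length(lens), 5e3)
  rate <- 2 * mean(tr$tmrca) * 1e-10
  qs <- stats::qexp(seq(0, 1, by = 0.05), rate)
  obs <- table(cut(lens, qs))
  expected <- rep(length(lens) / 20, 20)
  chisq <- sum((obs - expected)^2 / expected)
  # 19 df; reject only below alpha = 0.01
  expect_lt(chisq, stats::qchisq(0.99, df = 19))
})

test_that("mutation dropping matches the per-site emission probability", {
  expect_equal(heterozygosity(drop_mutations(
    structure(data.frame(length = 1000L, tmrca = 2e4),
              class = c("tmrca_track", "data.frame")),
    mu_per_gen = 0, seed = 1))$het_sites, 0)

  # constant T: binomial check of the het fraction
  track <- structure(data.frame(length = 1e6L, tmrca = 2e4),
                     class = c("tmrca_track", "data.frame"))
  x <- drop_mutations(track, 1e-8, seed = 2)
  p <- -expm1(-2 * 2e4 * 1e-8)
  h <- heterozygosity(x)
  se <- sqrt(p * (1 - p) * 1e6)
  expect_lt(abs(h$het_sites - p * 1e6), 3 * se)

  # conditional on a realized track, het count is binomial around the
  # track-implied expectation
  mod <- const_model()
  tr <- sample_pairwise_tmrca(mod, 2e6, seed = 3)
  x <- drop_mutations(tr, 1e-8, seed = 4)
  expected <- track_expected_het(tr, 1e-8) * 2e6
  expect_lt(abs(heterozygosity(x)$het_sites - expected), 3 * sqrt(expected))
})

test_that("per-site TMRCA along the sequence is unbiased for 2N", {
  mod <- const_model()
  ms <- vapply(1:6, function(s) {
    tr <- sample_pairwise_tmrca(mod, 2e6, seed = s)
    sum(as.numeric(tr$length) * tr$tmrca) / 2e6
  }, numeric(1L))
  se <- sd(ms) / sqrt(length(ms))
  expect_lt(abs(mean(ms) - 2e4), 3 * se)
})

test_that("clean-split pairs respect the divergence floor", {
  mod <- demography_model(epochs = cbind(0, 1e4), split_time = 1e5,
                          mu_per_gen = 1e-8, r_per_gen = 1e-8)
  sp <- simulate_split_pair(mod, 1e6, seed = 9)
  expect_true(all(sp$cross_track$tmrca >= 1e5))
  expect_equal(sum(sp$cross_track$length), 1e6)

  expect_error(simulate_split_pair(const_model(), 1000, seed = 1),
               "split_time")

  # degenerate limit: a vanishing floor reproduces the unconstrained
  # coalescent (KS distance on initial draws)
  set.seed(44)
  d_floor <- replicate(5e3, popcoal:::coal_time_from(mod, 1e-9))
  grid <- sort(d_floor)
  ks <- max(abs(seq_along(grid) / length(grid) -
                  coal_cdf(grid, cbind(0, 1e4))))
  expect_lt(ks, 0.02)
})

test_that("quartet site simulation is reproducible and label-antisymmetric", {
  qm <- quartet_model(admix_prop = 0.2)
  q1 <- simulate_quartet_sites(qm, n_sites = 2000, seed = 5)
  q2 <- simulate_quartet_sites(qm, n_sites = 2000, seed = 5)
  expect_identical(q1, q2)

  counts <- count_patterns(q1)
  swapped <- q1
  swapped$H1 <- q1$H2
  swapped$H2 <- q1$H1
  cs <- count_patterns(swapped)
  expect_equal(unname(cs["n_abba"]), unname(counts["n_baba"]))
  expect_equal(unname(cs["n_baba"]), unname(counts["n_abba"]))
  expect_equal(d_statistic(cs["n_abba"], cs["n_baba"]),
               -d_statistic(counts["n_abba"], counts["n_baba"]))

  expect_error(simulate_quartet_sites(qm, topology = "(H1,(H2,H3)),O",
                                      n_sites = 10, seed = 1),
               "topology")
})

test_that("simulator outputs are bit-reproducible under a fixed seed", {
  mod <- const_model()
  x1 <- simulate_consensus(mod, 5e4, seed = 123)
  x2 <- simulate_consensus(mod, 5e4, seed = 123)
  expect_identical(x1, x2)
  sp1 <- simulate_split_pair(demography_model(epochs = cbind(0, 1e4),
                                              split_time = 5e4),
                             5e4, seed = 9)
  sp2 <- simulate_split_pair(demography_model(epochs = cbind(0, 1e4),
                                              split_time = 5e4),
                             5e4, seed = 9)
  expect_identical(sp1, sp2)
})

test_that("demography model validation rejects bad inputs", {
  expect_error(demography_model(epochs = cbind(5, 1e4)), "start at time 0")
  expect_error(demography_model(epochs = rbind(c(0, 1e4), c(0, 2e4))),
               "strictly increasing")
  expect_error(demography_model(epochs = cbind(0, -5)), "positive")
  expect_error(demography_model(epochs = cbind(0, 1e4), split_time = 100,
                                admixture = list(donor = "a", recipient = "b",
                                                 time = 200, proportion = 0.1)),
               "admixture")
  expect_error(quartet_model(admix_prop = 1.5), "\\[0,1\\]")
})
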