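test_that("pattern grammar parses spans and repetitions", {
  p <- parse_pattern("4+25*2+4+6")
  expect_equal(p$n_atomic, 64L)
  expect_equal(p$n_free, 28L)
  expect_equal(parse_pattern("1")$n_atomic, 1L)
  expect_equal(parse_pattern("1")$n_free, 1L)
  p23 <- parse_pattern("2*3")
  expect_equal(p23$n_atomic, 6L)
  expect_equal(p23$n_free, 2L)
  # free-parameter tiling covers every atomic interval in order
  gi <- popcoal:::pattern_group_index(parse_pattern("2+2*3"))
  expect_equal(gi, c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))

  expect_error(parse_pattern(""), "empty")
  expect_error(parse_pattern("4++2"), "term")
  expect_error(parse_pattern("a*2"), "term")
  expect_error(parse_pattern("0"), "positive")
})

test_that("binning follows the het/missing window rules", {
  x <- cons(c1 = strrep("A", 100))
  expect_identical(unname(make_psmcfa(x)$contigs["c1"]), "T")
  x <- cons(c1 = paste0(strrep("A", 99), "R"))
  expect_identical(unname(make_psmcfa(x)$contigs["c1"]), "K")
  x <- cons(c1 = paste0(strrep("N", 95), strrep("A", 5)))
  expect_identical(unname(make_psmcfa(x)$contigs["c1"]), "N")
  # 90% missing is not above the threshold
  x <- cons(c1 = paste0(strrep("N", 90), strrep("A", 10)))
  expect_identical(unname(make_psmcfa(x)$contigs["c1"]), "T")
  # final partial window binned on its actual length
  x <- cons(c1 = paste0(strrep("A", 100), "RA"))
  expect_identical(unname(make_psmcfa(x)$contigs["c1"]), "TK")
})

test_that("time discretization is log-spaced with exact endpoints", {
  b <- discretize(64, 15)
  expect_length(b, 65L)
  expect_equal(b[1L], 0)
  expect_equal(b[65L], 15)
  expect_true(all(diff(b) > 0))
  expect_equal(discretize(1, 7), c(0, 7))
})

test_that("the HMM is a proper probability model", {
  b <- discretize(32, 15)
  lam <- exp(sin(seq_len(32) / 4))
  m <- popcoal:::psmc_matrices_cpp(b, lam, 0.04, 0.01)
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(m$Q)), rep(1, 32), tolerance = 1e-9)
  expect_true(all(diff(m$tbar) > 0))
  expect_true(all(m$emitK > 0 & m$emitK < 1))

  # forward-backward posteriors sum to one at every bin
  set.seed(6)
  obs <- sample(c(0L, 1L, 2L), 500, replace = TRUE, prob = c(0.9, 0.05, 0.05))
  fb <- popcoal:::psmc_fwdback_cpp(obs, m$pi, m$Q, m$emitK, TRUE)
  expect_equal(unname(rowSums(fb$gamma)), rep(1, 500), tolerance = 1e-9)
  expect_equal(sum(fb$gamma1), 1, tolerance = 1e-9)
})

test_that("EM increases the log-likelihood and rejects empty input", {
  mod <- demography_model(epochs = cbind(0, 1e4), mu_per_gen = 1e-8,
                          r_per_gen = 1e-8)
  x <- simulate_consensus(mod, 5e5, seed = 31)
  fit <- em_fit(make_psmcfa(x), n_iter = 6)
  expect_true(loglik_monotone(fit))
  expect_true(is.finite(fit$loglik))
  expect_true(all(fit$lambdas > 0))

  allN <- psmc_fasta(c(c1 = "NNNNN"), 100)
  expect_error(em_fit(allN), "missing")
})

test_that("scaling converts the fitted model to years and individuals", {
  fit <- structure(list(theta = 0.004, rho = 0.001,
                        lambdas = rep(1, 4), lambda_atomic = rep(1, 4),
                        boundaries = c(0, 1, 2, 4, 15),
                        pattern = parse_pattern("4"), loglik = -1,
                        loglik_trace = -1, bin_size = 100L),
                   class = "psmc_model")
  tr <- scale_trajectory(fit, mu_per_year = 2e-9, g_years = 5, s = 100)
  expect_equal(attr(tr, "N0"), 1000)
  expect_equal(tr$time_end_years[1L], 10000)   # t = 1 coalescent unit
  expect_equal(tr$ne, rep(1000, 4))            # flat at N0 when lambda = 1

  tr2 <- scale_trajectory(fit, mu_per_year = 4e-9, g_years = 5, s = 100)
  expect_equal(tr2$ne, tr$ne / 2)
  expect_equal(tr2$time_end_years, tr$time_end_years / 2)
})

test_that("divergence read-off flags self-comparisons and scans correctly", {
  mk <- function(ne) {
    tr <- data.frame(time_start_years = c(0, 1e4, 2e4, 4e4, 8e4),
                     time_end_years = c(1e4, 2e4, 4e4, 8e4, 1.6e5),
                     ne = ne)
    attr(tr, "mu_per_year") <- 2e-9
    attr(tr, "g_years") <- 5
    class(tr) <- c("demographic_trajectory", "data.frame")
    tr
  }
  single <- mk(rep(1e4, 5))
  # pseudo exploding below 40 ky: estimate is the oldest qualifying boundary
  pseudo <- mk(c(5e5, 5e5, 5e5, 1.2e4, 1e4))
  est <- divergence_readoff(pseudo, single, single, C = 10)
  expect_false(est$no_signal)
  expect_equal(est$time_years, 4e4)

  # same trajectory as the singles: no explosion anywhere
  est0 <- divergence_readoff(single, single, single, C = 10)
  expect_true(est0$no_signal)

  # stricter thresholds can only shorten the qualifying run
  pseudo2 <- mk(c(5e5, 3e5, 1.5e5, 1.2e4, 1e4))
  ests <- vapply(c(5, 20, 40), function(C) {
    e <- divergence_readoff(pseudo2, single, single, C = C)
    if (e$no_signal) 0 else e$time_years
  }, numeric(1L))
  expect_true(all(diff(ests) <= 0))

  other <- mk(rep(1e4, 5))
  attr(other, "mu_per_year") <- 1e-9
  expect_error(divergence_readoff(pseudo, other, single), "share mu")
})

test_that("masking a fifth of the bins barely moves the estimate", {
  mod <- demography_model(epochs = cbind(0, 1e4), mu_per_gen = 1e-8,
                          r_per_gen = 1e-8)
  x <- simulate_consensus(mod, 5e6, seed = 79)
  pf <- make_psmcfa(x)
  fit1 <- em_fit(pf, n_iter = 12)
  s <- strsplit(pf$contigs[[1L]], "")[[1L]]
  set.seed(78)
  s[sample(length(s), round(0.2 * length(s)))] <- "N"
  pf2 <- psmc_fasta(setNames(paste(s, collapse = ""), names(pf$contigs)),
                    pf$bin_size)
  fit2 <- em_fit(pf2, n_iter = 12)
  tr1 <- scale_trajectory(fit1, 2e-9, 5)
  tr2 <- scale_trajectory(fit2, 2e-9, 5)
  ne1 <- window_mean_ne(tr1, 0.2 * 2e4, 2 * 2e4)
  ne2 <- window_mean_ne(tr2, 0.2 * 2e4, 2 * 2e4)
  expect_lt(abs(ne2 / ne1 - 1), 0.10)
  expect_true(loglik_monotone(fit1) && loglik_monotone(fit2))
})
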