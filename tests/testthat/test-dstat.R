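test_that("quartet sampling filters missing and het-outgroup sites", {
  h1 <- cons(c1 = "AAAAA", name = "h1")
  h2 <- cons(c1 = "AAGAA", name = "h2")
  h3 <- cons(c1 = "AAGAN", name = "h3")
  og <- cons(c1 = "AARAA", name = "o")
  q <- sample_quartet(h1, h2, h3, og, block_length = 2, seed = 1)
  # site 3: informative; site 3 kept, site 5 dropped (missing h3),
  # site 3 has outgroup A; outgroup het at site 3? no: og site 3 = R -> dropped
  expect_false(3 %in% q$pos)
  expect_false(5 %in% q$pos)
  # monomorphic sites are retained
  expect_true(all(c(1, 2, 4) %in% q$pos))
  expect_equal(unname(count_patterns(q)), c(0L, 0L))

  q2 <- sample_quartet(h1, h2, h3, og, block_length = 2, seed = 1)
  expect_identical(q, q2)

  bad <- cons(c1 = "AAAA", name = "short")
  expect_error(sample_quartet(h1, h2, h3, bad), "co-aligned")
})

test_that("het sites in H1-H3 are allele-sampled, tri-allelic sites dropped", {
  h1 <- cons(c1 = "R", name = "h1")   # A/G
  h2 <- cons(c1 = "A", name = "h2")
  h3 <- cons(c1 = "G", name = "h3")
  og <- cons(c1 = "A", name = "o")
  draws <- vapply(1:200, function(s) {
    sample_quartet(h1, h2, h3, og, seed = s)$H1
  }, character(1L))
  expect_setequal(unique(draws), c("A", "G"))

  # site with three distinct alleles is excluded
  h3tri <- cons(c1 = "C", name = "h3")
  h1g <- cons(c1 = "G", name = "h1")
  q <- sample_quartet(h1g, h2, h3tri, og, seed = 1)
  expect_equal(nrow(q), 0L)
})

test_that("pattern counting implements the ABBA/BABA definitions", {
  q <- data.frame(contig = "c", pos = 1L, H1 = "A", H2 = "G", H3 = "G",
                  O = "A", block = 1L)
  expect_equal(unname(count_patterns(q)), c(1L, 0L))
  q$H1 <- "G"; q$H2 <- "A"
  expect_equal(unname(count_patterns(q)), c(0L, 1L))

  tri <- data.frame(contig = "c", pos = 1L, H1 = "A", H2 = "C", H3 = "G",
                    O = "A", block = 1L)
  expect_error(count_patterns(tri), "tri-allelic")
})

test_that("the D-statistic is the exact count quotient", {
  row <- hydrophis_dstat_row()
  expect_equal(round(d_statistic(row$n_abba, row$n_baba), 6), row$D)
  expect_equal(d_statistic(1234, 1234), 0)
  expect_equal(d_statistic(77, 0), 1)
  expect_error(d_statistic(0, 0), "undefined")
})

test_that("published D and SE give the published Z", {
  row <- hydrophis_dstat_row()
  expect_equal(round(row$D / row$SE, 2), row$Z)
})

test_that("block jackknife matches its defining formula and flags SE = 0", {
  qm <- quartet_model(admix_prop = 0.2)
  q <- simulate_quartet_sites(qm, n_sites = 2e4, block_length = 500, seed = 3)
  res <- block_jackknife(q)
  cnt <- count_patterns(q)
  expect_equal(res$n_abba, unname(cnt["n_abba"]))
  expect_equal(res$D, unname(d_statistic(cnt["n_abba"], cnt["n_baba"])))
  expect_lte(abs(res$D), 1)

  # manual recomputation of the leave-one-out SE
  ab <- tapply(q$H1 == q$O & q$H2 != q$O & q$H3 == q$H2, q$block, sum)
  ba <- tapply(q$H1 != q$O & q$H2 == q$O & q$H3 == q$H1, q$block, sum)
  keep <- ab + ba > 0
  ab <- ab[keep]; ba <- ba[keep]
  dj <- (sum(ab) - ab - (sum(ba) - ba)) / (sum(ab) - ab + sum(ba) - ba)
  m <- length(dj)
  expect_equal(res$SE, sqrt(((m - 1) / m) * sum((dj - mean(dj))^2)))
  expect_equal(res$Z, res$D / res$SE)

  # block order permutation leaves the SE unchanged
  qp <- q[sample(nrow(q)), ]
  qp$block <- max(q$block) + 1 - qp$block
  expect_equal(block_jackknife(qp)$SE, res$SE)

  # two identical blocks: zero spread, explicit infinite-Z flag
  q2 <- data.frame(contig = "c", pos = 1:4,
                   H1 = c("A", "A", "A", "A"), H2 = c("G", "G", "G", "G"),
                   H3 = c("G", "G", "G", "G"), O = c("A", "A", "A", "A"),
                   block = c(1L, 1L, 2L, 2L))
  r2 <- block_jackknife(q2)
  expect_equal(r2$SE, 0)
  expect_true(r2$infinite_z)
  expect_identical(r2$Z, Inf)

  one <- q2[q2$block == 1L, ]
  expect_error(block_jackknife(one), "at least 2")
})

test_that("no admixture leaves ABBA and BABA balanced", {
  qm <- quartet_model(admix_prop = 0)
  q <- simulate_quartet_sites(qm, n_sites = 1e5, block_length = 1000, seed = 19)
  cnt <- count_patterns(q)
  expect_lt(abs(cnt["n_abba"] - cnt["n_baba"]),
            3 * sqrt(cnt["n_abba"] + cnt["n_baba"]))
})
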