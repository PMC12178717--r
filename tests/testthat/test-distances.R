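test_that("distance corrections are exact and ordered", {
  expect_equal(correct_distance(0), 0)
  expect_equal(correct_distance(0, "poisson"), 0)
  expect_equal(round(correct_distance(0.004), 8), 0.00401070)
  expect_equal(correct_distance(0.004, "poisson"), -log(1 - 0.004))

  p <- seq(0.001, 0.7, by = 0.01)
  d <- correct_distance(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))
  expect_lt(abs(correct_distance(1e-8) / 1e-8 - 1), 1e-6)

  expect_error(correct_distance(0.75), "below 0.75")
  expect_error(correct_distance(1, "poisson"), "below 1")
  expect_error(correct_distance(-0.1), "non-negative")
})

test_that("distance matrices assemble from unordered pairwise summaries", {
  pairs <- data.frame(taxonA = "mel", taxonB = "cya", p = 0.00166)
  m <- build_matrix(pairs)
  expect_equal(m$p["mel", "cya"], 0.00166)
  expect_equal(m$p["cya", "mel"], 0.00166)
  expect_equal(diag(m$p), c(cya = 0, mel = 0))
  expect_true(all(m$d >= m$p))

  pairs3 <- data.frame(taxonA = c("a", "a"), taxonB = c("b", "c"),
                       p = c(0.1, 0.2))
  expect_error(build_matrix(pairs3), "missing pair.*b-c")

  dup <- data.frame(taxonA = c("a", "b"), taxonB = c("b", "a"), p = c(0.1, 0.2))
  expect_error(build_matrix(dup), "more than once")

  self <- data.frame(taxonA = c("a", "a", "b"), taxonB = c("b", "c", "c"),
                     p = c(0, 0.2, 0.2))
  expect_equal(build_matrix(self)$p["a", "b"], 0)
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    true <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(d[sort(rownames(d)), sort(rownames(d))])
    expect_equal(ape::dist.topo(est, true), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), rownames(d)],
                 d, tolerance = 1e-10)
  }
})

test_that("three-taxon neighbor joining uses the closed-form star lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2L])], tr$tip.label)
  expect_equal(unname(len["A"]), (3 + 5 - 6) / 2)
  expect_equal(unname(len["B"]), (3 + 6 - 5) / 2)
  expect_equal(unname(len["C"]), (5 + 6 - 3) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("taxon input order does not change the inferred tree", {
  set.seed(12)
  true <- ape::rtree(7, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(true)
  t1 <- neighbor_joining(d)
  perm <- sample(rownames(d))
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  nm <- t1$tip.label
  expect_equal(ape::cophenetic.phylo(t2)[nm, nm],
               ape::cophenetic.phylo(t1)[nm, nm], tolerance = 1e-10)
})

test_that("in-package neighbor joining agrees with ape's implementation", {
  set.seed(13)
  x <- matrix(rnorm(60), nrow = 10)
  d <- as.matrix(dist(x))  # generic non-additive distances
  dimnames(d) <- list(letters[1:10], letters[1:10])
  mine <- neighbor_joining(d)
  reference <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(mine, reference), 0, ignore_attr = TRUE)
  nm <- mine$tip.label
  expect_equal(ape::cophenetic.phylo(mine)[nm, nm],
               ape::cophenetic.phylo(reference)[nm, nm], tolerance = 1e-8)
})

test_that("correction choice does not change topology at low divergence", {
  # pseudo-diploid heterozygosities sit around 0.001-0.006, where the
  # Jukes-Cantor and pure Poisson corrections are nearly proportional
  set.seed(14)
  for (rep in 1:5) {
    true <- ape::rtree(6, rooted = FALSE, br = function(k) runif(k, 2e-4, 1.5e-3))
    p <- ape::cophenetic.phylo(true)
    taxa <- rownames(p)
    pairs <- do.call(rbind, lapply(seq_along(taxa)[-1], function(j) {
      data.frame(taxonA = taxa[seq_len(j - 1)], taxonB = taxa[j],
                 p = p[seq_len(j - 1), j])
    }))
    t_jc <- neighbor_joining(build_matrix(pairs, "jc"))
    t_po <- neighbor_joining(build_matrix(pairs, "poisson"))
    expect_equal(ape::dist.topo(t_jc, t_po), 0, ignore_attr = TRUE)
  }
})
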