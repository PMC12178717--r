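#' Sample a quartet site matrix from four consensuses
#'
#' Sites where any individual is missing, or where the outgroup is
#' heterozygous, are dropped; at heterozygous sites of H1-H3 one allele is
#' sampled uniformly (seeded). Sites with more than two distinct alleles
#' are excluded; monomorphic sites are retained (they contribute to
#' neither pattern count). Blocks are assigned by physical coordinate.
#'
#' @param h1,h2,h3,out Four [diploid_consensus()] objects on identical
#'   contigs/lengths (`out` is the outgroup).
#' @param block_length Block size in bp of physical coordinate.
#' @param seed Integer seed for allele sampling.
#' @return A `quartet_sites` data frame (columns `contig`, `pos`, `H1`,
#'   `H2`, `H3`, `O`, `block`).
#' @export
sample_quartet <- function(h1, h2, h3, out, block_length = 5e6, seed = NULL) {
  cs <- list(h1, h2, h3, out)
  for (x in cs) stopifnot(inherits(x, "diploid_consensus"))
  nms <- names(h1$contigs)
  for (x in cs[-1L]) {
    if (!identical(names(x$contigs), nms) ||
        !identical(nchar(x$contigs), nchar(h1$contigs))) {
      stop("consensuses are not co-aligned (contig names/lengths differ)")
    }
  }
  res <- list()
  block0 <- 0L
  with_seed(seed, {
    for (cn in nms) {
      raws <- lapply(cs, function(x) charToRaw(x$contigs[[cn]]))
      cls <- lapply(raws, classify_raw)
      keep <- cls[[1L]] != CLASS_MISSING & cls[[2L]] != CLASS_MISSING &
        cls[[3L]] != CLASS_MISSING & cls[[4L]] == CLASS_HOM
      pos <- which(keep)
      if (length(pos) == 0L) next
      allele <- function(k) {
        r <- raws[[k]][pos]
        i <- as.integer(r) + 1L
        a <- ALLELE_TABLES$a1[i]
        het <- which(CLASS_TABLE[i] == CLASS_HET)
        if (length(het) > 0L) {
          take2 <- het[runif(length(het)) < 0.5]
          a[take2] <- ALLELE_TABLES$a2[i[take2]]
        }
        rawToChar(a)
      }
      al <- lapply(1:4, function(k) strsplit(allele(k), "")[[1L]])
      ok <- n_distinct_alleles(al[[1L]], al[[2L]], al[[3L]], al[[4L]]) <= 2L
      res[[cn]] <- data.frame(contig = rep(cn, sum(ok)), pos = pos[ok],
                              H1 = al[[1L]][ok], H2 = al[[2L]][ok],
                              H3 = al[[3L]][ok], O = al[[4L]][ok],
                              block = block0 + ((pos[ok] - 1L) %/% block_length) + 1L,
                              stringsAsFactors = FALSE)
      block0 <- block0 + ceiling(nchar(h1$contigs[[cn]]) / block_length)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      H1 = character(0), H2 = character(0),
                      H3 = character(0), O = character(0),
                      block = integer(0))
  }
  rownames(out) <- NULL
  class(out) <- c("quartet_sites", "data.frame")
  out
}

# vectorized count of distinct alleles among four per-site base vectors
n_distinct_alleles <- function(a, b, c, d) {
  4L - ((b == a) + (c == a | c == b) + (d == a | d == b | d == c))
}

#' Count ABBA and BABA site patterns
#'
#' With `A` the outgroup allele and `B` the single alternative allele,
#' ABBA sites have `H1 = A, H2 = B, H3 = B` and BABA sites
#' `H1 = B, H2 = A, H3 = B`; all other patterns are ignored.
#'
#' @param q A `quartet_sites` data frame.
#' @return Named integer vector `c(n_abba =, n_baba =)`.
#' @export
count_patterns <- function(q) {
  stopifnot(all(c("H1", "H2", "H3", "O") %in% names(q)))
  distinct <- n_distinct_alleles(q$H1, q$H2, q$H3, q$O)
  if (any(distinct > 2L)) {
    stop("tri-allelic pattern reached the counter; filter sites upstream")
  }
  abba <- q$H1 == q$O & q$H2 != q$O & q$H3 == q$H2
  baba <- q$H1 != q$O & q$H2 == q$O & q$H3 == q$H1
  c(n_abba = sum(abba), n_baba = sum(baba))
}

#' D-statistic from pattern counts
#'
#' `D = (n_abba - n_baba) / (n_abba + n_baba)`, the exact quotient.
#'
#' @param n_abba,n_baba Site pattern counts.
#' @return The D-statistic.
#' @examples
#' d_statistic(183151, 166251)  # 0.048368
#' @export
d_statistic <- function(n_abba, n_baba) {
  if (n_abba + n_baba == 0) stop("D undefined: no ABBA or BABA sites")
  (n_abba - n_baba) / (n_abba + n_baba)
}

#' Block-jackknife D-statistic with standard error and Z-score
#'
#' Delete-one-block estimates over the `m` blocks holding at least one
#' informative (ABBA or BABA) site give
#' `SE = sqrt(((m-1)/m) * sum_j (D_(-j) - Dbar)^2)` with `Dbar` the mean
#' leave-one-out estimate, and `Z = D / SE`. When every leave-one-out
#' estimate coincides the SE is zero and `Z` is flagged infinite.
#'
#' @param q A `quartet_sites` data frame with a `block` column.
#' @return An object of class `dstat_result`: list with `n_abba`,
#'   `n_baba`, `D`, `SE`, `Z`, `n_blocks`, `infinite_z`.
#' @export
block_jackknife <- function(q) {
  abba <- q$H1 == q$O & q$H2 != q$O & q$H3 == q$H2
  baba <- q$H1 != q$O & q$H2 == q$O & q$H3 == q$H1
  ab_b <- tapply(abba, q$block, sum)
  ba_b <- tapply(baba, q$block, sum)
  informative <- (ab_b + ba_b) > 0
  ab_b <- ab_b[informative]
  ba_b <- ba_b[informative]
  m <- length(ab_b)
  if (m < 2L) stop("block jackknife needs at least 2 informative blocks")
  A <- sum(ab_b); B <- sum(ba_b)
  D <- d_statistic(A, B)
  dj <- (A - ab_b - (B - ba_b)) / (A - ab_b + B - ba_b)
  se <- sqrt(((m - 1) / m) * sum((dj - mean(dj))^2))
  inf_z <- se == 0
  z <- if (inf_z) sign(D) * Inf else D / se
  structure(list(n_abba = A, n_baba = B, D = D, SE = se, Z = z,
                 n_blocks = m, infinite_z = inf_z),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("ABBA %d  BABA %d  D = %.6f  SE = %.6f  Z = %.2f (%d blocks)\n",
              x$n_abba, x$n_baba, x$D, x$SE, x$Z, x$n_blocks))
  invisible(x)
}
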