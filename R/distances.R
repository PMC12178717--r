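#' Multiple-hit correction of a per-site difference proportion
#'
#' Default is the Jukes-Cantor correction
#' `d = -(3/4) * log(1 - (4/3) * p)`; the pure Poisson correction
#' `d = -log(1 - p)` is selectable. Both are zero at `p = 0` and strictly
#' increasing in `p`.
#'
#' @param p Observed per-site difference proportion(s).
#' @param method `"jc"` (default) or `"poisson"`.
#' @return Corrected distance(s) in substitutions per site.
#' @examples
#' correct_distance(0.004)             # 0.0040107
#' correct_distance(0.004, "poisson")
#' @export
correct_distance <- function(p, method = c("jc", "poisson")) {
  method <- match.arg(method)
  if (any(p < 0)) stop("p must be non-negative")
  ceiling_p <- if (method == "jc") 0.75 else 1
  if (any(p >= ceiling_p)) {
    stop(sprintf("p must be below %s for the %s correction", ceiling_p, method))
  }
  if (method == "jc") -0.75 * log1p(-(4 / 3) * p) else -log1p(-p)
}

#' Build a distance matrix from pairwise heterozygosities
#'
#' The genome-wide heterozygosity of each pseudo-diploid pair is the
#' uncorrected per-site distance `p` between the two individuals; the
#' corrected matrix `d` applies [correct_distance()] elementwise.
#'
#' @param pairs Data frame with columns `taxonA`, `taxonB`, `p`, one row
#'   per unordered pair over the taxa set. Self-pairs are not required.
#' @param method Correction method, passed to [correct_distance()].
#' @return An object of class `distance_matrix` with fields `taxa`, `p`
#'   and `d` (symmetric matrices with zero diagonal).
#' @export
build_matrix <- function(pairs, method = c("jc", "poisson")) {
  method <- match.arg(method)
  stopifnot(all(c("taxonA", "taxonB", "p") %in% names(pairs)))
  taxa <- sort(unique(c(pairs$taxonA, pairs$taxonB)))
  n <- length(taxa)
  if (n < 2L) stop("need at least two taxa")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  k <- key(pairs$taxonA, pairs$taxonB)
  if (anyDuplicated(k)) {
    d <- unique(k[duplicated(k)])
    stop("pair(s) given more than once: ", paste(gsub("\r", "-", d), collapse = ", "))
  }
  pm <- matrix(0, n, n, dimnames = list(taxa, taxa))
  lookup <- setNames(pairs$p, k)
  missing_pairs <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      kk <- key(taxa[i], taxa[j])
      if (is.na(lookup[kk])) {
        missing_pairs <- c(missing_pairs, paste(taxa[i], taxa[j], sep = "-"))
      } else {
        pm[i, j] <- pm[j, i] <- lookup[[kk]]
      }
    }
  }
  if (length(missing_pairs) > 0L) {
    stop("missing pair(s): ", paste(missing_pairs, collapse = ", "))
  }
  dm <- pm
  dm[] <- 0
  off <- row(pm) != col(pm)
  dm[off] <- correct_distance(pm[off], method = method)
  structure(list(taxa = taxa, p = pm, d = dm, method = method),
            class = "distance_matrix")
}

#' Neighbor-joining tree
#'
#' Canonical agglomerative neighbor joining on the corrected distance
#' matrix: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, with
#' branch lengths from the standard split formula. Ties in `Q` are broken
#' by the lowest `(i, j)` index pair; negative branch lengths are retained
#' (not clamped) so that exactly additive inputs are reproduced exactly.
#'
#' @param m A [build_matrix()] result, or a symmetric numeric matrix with
#'   dimnames (treated as the corrected distances).
#' @return An unrooted `ape` `"phylo"` tree (basal trifurcation).
#' @export
neighbor_joining <- function(m) {
  d <- if (inherits(m, "distance_matrix")) m$d else as.matrix(m)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")

  ntip <- n
  n_nodes <- 2L * ntip - 2L          # tips + internal nodes (unrooted)
  edge <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)
  # active cluster ids: tips are 1..ntip, internals ntip+2, ntip+3, ...
  # (ape reserves ntip+1 for the root, created at the final join)
  ids <- seq_len(ntip)
  next_internal <- ntip + 2L
  D <- d

  while (length(ids) > 3L) {
    nn <- length(ids)
    rs <- rowSums(D)
    Q <- (nn - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # strict < keeps the first (lowest-index) pair on ties
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(nn - 1L)) {
      for (j in (i + 1L):nn) {
        if (Q[i, j] < qmin) {
          qmin <- Q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    dij <- D[i, j]
    li <- 0.5 * dij + (rs[i] - rs[j]) / (2 * (nn - 2))
    lj <- dij - li
    new_id <- next_internal
    next_internal <- next_internal + 1L
    edge <- rbind(edge, c(new_id, ids[i]), c(new_id, ids[j]))
    edge_len <- c(edge_len, li, lj)
    dn <- 0.5 * (D[i, ] + D[j, ] - dij)
    keep <- setdiff(seq_len(nn), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    ids <- c(ids[keep], new_id)
    D <- D2
  }
  # final trifurcation at the root node ntip + 1
  root <- ntip + 1L
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  edge <- rbind(edge, c(root, ids[1L]), c(root, ids[2L]), c(root, ids[3L]))
  edge_len <- c(edge_len, l1, l2, l3)

  tree <- list(edge = edge, edge.length = edge_len, tip.label = labels,
               Nnode = ntip - 2L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}
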