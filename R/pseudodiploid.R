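#' Haploidize a diploid consensus
#'
#' At every heterozygous site one of the two IUPAC-encoded alleles is
#' chosen with probability 1/2, independently per site; homozygous sites
#' copy their base and missing sites stay missing. The draw is
#' deterministic given `seed`.
#'
#' @param x A [diploid_consensus()].
#' @param seed Integer seed for the allele draws.
#' @return An object of class `haploid_sequence` with fields `name`,
#'   `contigs` (strings over `{A,C,G,T,N}`) and `provenance`.
#' @export
haploidize <- function(x, seed) {
  stopifnot(inherits(x, "diploid_consensus"))
  with_seed(seed, {
    contigs <- vapply(x$contigs, function(s) {
      r <- charToRaw(s)
      i <- as.integer(r) + 1L
      a <- ALLELE_TABLES$a1[i]
      het <- which(CLASS_TABLE[i] == CLASS_HET)
      if (length(het) > 0L) {
        take2 <- het[runif(length(het)) < 0.5]
        a[take2] <- ALLELE_TABLES$a2[i[take2]]
      }
      rawToChar(a)
    }, character(1L))
  })
  structure(list(name = x$name, contigs = contigs,
                 provenance = list(source = x$name, seed = seed)),
            class = "haploid_sequence")
}

#' Combine two haploids into a pseudo-diploid
#'
#' A site is called iff both haploids are called there; equal bases give a
#' homozygous call, differing bases the corresponding two-base IUPAC code,
#' and any missing input gives missing. The genome-wide heterozygosity of
#' the result is the per-site mismatch fraction of the two haploids over
#' co-called sites, i.e. the uncorrected genetic distance between them.
#'
#' @param a,b [haploidize()] results with identical contig names/lengths.
#' @param name Name for the pseudo-diploid; defaults to `"a+b"`.
#' @return A [diploid_consensus()].
#' @export
combine_haploids <- function(a, b, name = NULL) {
  stopifnot(inherits(a, "haploid_sequence"), inherits(b, "haploid_sequence"))
  if (!identical(names(a$contigs), names(b$contigs)) ||
      !identical(nchar(a$contigs), nchar(b$contigs))) {
    bad <- union(setdiff(names(a$contigs), names(b$contigs)),
                 setdiff(names(b$contigs), names(a$contigs)))
    if (length(bad) == 0L) {
      shared <- names(a$contigs)
      bad <- shared[nchar(a$contigs[shared]) != nchar(b$contigs[shared])]
    }
    stop("haploids disagree on contig(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(name)) name <- paste0(a$name, "+", b$name)
  contigs <- vapply(names(a$contigs), function(cn) {
    ra <- charToRaw(a$contigs[[cn]])
    rb <- charToRaw(b$contigs[[cn]])
    rawToChar(PAIR_TABLE[as.integer(ra) * 256L + as.integer(rb) + 1L])
  }, character(1L))
  diploid_consensus(name, contigs)
}
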