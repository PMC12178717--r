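#' Genome-wide heterozygosity summary
#'
#' Heterozygosity is the exact quotient `het_sites / called_sites`, where
#' called sites are those with a homozygous or heterozygous call (missing
#' sites never count).
#'
#' @param called_sites Number of called sites (bp).
#' @param het_sites Number of heterozygous sites (bp).
#' @return An object of class `het_summary` with fields `called_sites`,
#'   `het_sites` and `heterozygosity`.
#' @examples
#' het_summary(538569068, 980917)  # heterozygosity 0.001821339
#' @export
het_summary <- function(called_sites, het_sites) {
  if (called_sites == 0) stop("heterozygosity undefined: zero called sites")
  if (het_sites < 0 || het_sites > called_sites) {
    stop("het_sites must lie in [0, called_sites]")
  }
  structure(list(called_sites = called_sites, het_sites = het_sites,
                 heterozygosity = het_sites / called_sites),
            class = "het_summary")
}

#' @export
print.het_summary <- function(x, ...) {
  cat(sprintf("called: %s  het: %s  heterozygosity: %s\n",
              format(x$called_sites, big.mark = ","),
              format(x$het_sites, big.mark = ","),
              format_het(x$heterozygosity)))
  invisible(x)
}

#' Format a heterozygosity at 9 decimals (round half to even)
#' @param h Heterozygosity value.
#' @return Character scalar.
#' @export
format_het <- function(h) sprintf("%.9f", h)

#' Apply a repeat mask to a consensus
#'
#' Calls inside mask intervals (0-based half-open) become missing; the
#' input object is not modified.
#'
#' @param x A [diploid_consensus()].
#' @param mask A [mask_intervals()] object; contigs must be a subset of the
#'   consensus contigs and intervals must not extend past contig ends.
#' @return A masked [diploid_consensus()].
#' @export
apply_mask <- function(x, mask) {
  stopifnot(inherits(x, "diploid_consensus"), inherits(mask, "mask_intervals"))
  extra <- setdiff(names(mask$intervals), names(x$contigs))
  if (length(extra) > 0L) {
    stop("mask names contig(s) absent from consensus: ",
         paste(extra, collapse = ", "))
  }
  contigs <- x$contigs
  for (cn in names(mask$intervals)) {
    m <- mask$intervals[[cn]]
    if (nrow(m) == 0L) next
    len <- nchar(contigs[[cn]])
    if (any(m[, 2L] > len)) {
      stop(sprintf("mask interval on %s extends past contig end (%d bp)", cn, len))
    }
    r <- charToRaw(contigs[[cn]])
    for (i in seq_len(nrow(m))) {
      r[(m[i, 1L] + 1L):m[i, 2L]] <- charToRaw(MISSING_CALL)
    }
    contigs[[cn]] <- rawToChar(r)
  }
  diploid_consensus(x$name, contigs)
}

#' Classify consensus calls
#'
#' @param call Character vector of single normalized calls.
#' @return Factor with levels `HOM`, `HET`, `MISSING`.
#' @export
classify_site <- function(call) {
  stopifnot(is.character(call))
  if (any(nchar(call) != 1L)) stop("calls must be single characters")
  codes <- CLASS_TABLE[as.integer(charToRaw(paste(call, collapse = ""))) + 1L]
  if (any(codes == 3L)) {
    bad <- call[codes == 3L][1L]
    stop(sprintf("'%s' is not a normalized consensus call", bad))
  }
  factor(c("HOM", "HET", "MISSING")[codes + 1L],
         levels = c("HOM", "HET", "MISSING"))
}

# Fast per-contig class counts: returns c(hom, het, missing)
count_classes <- function(x) {
  tot <- c(0, 0, 0)
  for (s in x$contigs) {
    codes <- classify_raw(charToRaw(s))
    tot <- tot + tabulate(codes + 1L, nbins = 3L)
  }
  tot
}

#' Genome-wide heterozygosity of a consensus
#'
#' @param x A [diploid_consensus()].
#' @return A [het_summary()].
#' @export
heterozygosity <- function(x) {
  stopifnot(inherits(x, "diploid_consensus"))
  n <- count_classes(x)
  het_summary(called_sites = n[1L] + n[2L], het_sites = n[2L])
}
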