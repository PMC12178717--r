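#' Diploid consensus sequence container
#'
#' Holds per-site consensus calls for one individual. Each call is one of
#' `A,C,G,T` (homozygous), one of the six two-base IUPAC ambiguity codes
#' `R,Y,S,W,K,M` (heterozygous), or `N` (missing). Contigs are stored as
#' single character strings for compact whole-genome handling.
#'
#' @param name Individual identifier.
#' @param contigs Named character vector, one string per contig; calls must
#'   already be in the 11-symbol alphabet (use [read_consensus_fasta()] to
#'   normalize arbitrary FASTA input).
#' @return An object of class `diploid_consensus`.
#' @export
diploid_consensus <- function(name, contigs) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(contigs) == 0L) stop("consensus must contain at least one contig")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("all contigs must be named")
  }
  dup <- names(contigs)[duplicated(names(contigs))]
  if (length(dup) > 0L) {
    stop("duplicate contig name(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(nchar(contigs) == 0L)) stop("zero-length contig not allowed")
  for (cn in names(contigs)) {
    r <- charToRaw(contigs[[cn]])
    bad <- which(classify_raw(r) == 3L)
    if (length(bad) > 0L) {
      stop(sprintf("contig %s: symbol '%s' at position %d is not a normalized call",
                   cn, rawToChar(r[bad[1L]]), bad[1L]))
    }
  }
  structure(list(name = name, contigs = contigs), class = "diploid_consensus")
}

#' @export
print.diploid_consensus <- function(x, ...) {
  cat(sprintf("<diploid_consensus> %s: %d contig(s), %s bp\n",
              x$name, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

contig_lengths <- function(x) nchar(x$contigs)

#' Read a diploid consensus FASTA with IUPAC ambiguity codes
#'
#' Reads FASTA and normalizes every letter into the 11-symbol call
#' alphabet: uppercase `A,C,G,T,R,Y,S,W,K,M` pass through; everything
#' else -- lowercase letters (soft-masked bases), `n`/`N`, three/four-base
#' ambiguity codes (`B,D,H,V`), gaps and stray symbols -- becomes missing
#' (`N`). Soft-masked `a/c/g/t` map to missing so repeat-derived bases drop
#' out of all downstream counts, as with a hard-masked reference.
#'
#' @param path FASTA file path.
#' @param name Individual identifier; defaults to the file base name.
#' @return A [diploid_consensus()] object.
#' @export
read_consensus_fasta <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  nms <- sub("\\s.*$", "", names(set))
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0L) {
    stop("duplicate contig name(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  contigs <- vapply(seq_along(set), function(i) {
    rawToChar(normalize_raw(charToRaw(as.character(set[[i]]))))
  }, character(1L))
  names(contigs) <- nms
  diploid_consensus(name, contigs)
}

#' Write a diploid consensus as FASTA
#'
#' @param x A [diploid_consensus()] object.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_consensus_fasta <- function(x, path, width = 60L) {
  set <- Biostrings::BStringSet(x$contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Repeat-mask intervals
#'
#' Per-contig sets of 0-based half-open intervals, sorted and merged.
#'
#' @param intervals Named list; each element a two-column matrix of
#'   `(start, end)` rows, 0-based half-open. May be empty.
#' @return An object of class `mask_intervals`.
#' @export
mask_intervals <- function(intervals = list()) {
  out <- lapply(intervals, function(m) {
    if (is.null(m) || nrow(m) == 0L) return(matrix(numeric(0), ncol = 2L))
    if (any(m[, 1L] < 0) || any(m[, 1L] >= m[, 2L])) {
      stop("invalid interval: start must satisfy 0 <= start < end")
    }
    ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L]))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  structure(list(intervals = out), class = "mask_intervals")
}

#' Read a BED3 mask file
#'
#' BED is 0-based half-open; overlapping or bookended intervals are merged
#' per contig. An empty file yields an empty mask.
#'
#' @param path BED file path.
#' @return A [mask_intervals()] object.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(mask_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) stop(sprintf("%s line %d: fewer than 3 BED columns", path, i))
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("%s line %d: non-numeric coordinates", path, i))
    }
    if (start < 0) stop(sprintf("%s line %d: negative start coordinate", path, i))
    if (start >= end) stop(sprintf("%s line %d: start >= end", path, i))
    list(chrom = f[1L], start = start, end = end)
  })
  chroms <- vapply(recs, `[[`, character(1L), "chrom")
  ivs <- lapply(split(seq_along(recs), chroms), function(ix) {
    cbind(start = vapply(recs[ix], `[[`, numeric(1L), "start"),
          end = vapply(recs[ix], `[[`, numeric(1L), "end"))
  })
  mask_intervals(ivs)
}

# ---- psmcfa: binned het/hom/missing representation ----------------------

#' Binned genome representation for the coalescent HMM
#'
#' One symbol per window of `bin_size` consensus sites: `K` if the window
#' contains at least one heterozygous call, `T` if it is called but has
#' none, `N` if too much of it is missing.
#'
#' @param contigs Named character vector over the alphabet `{K,T,N}`.
#' @param bin_size Bases per symbol.
#' @return An object of class `psmc_fasta`.
#' @export
psmc_fasta <- function(contigs, bin_size) {
  stopifnot(length(bin_size) == 1L, bin_size >= 1)
  if (length(contigs) == 0L) stop("psmc_fasta needs at least one contig")
  for (cn in names(contigs)) {
    bad <- gsub("[KTN]", "", contigs[[cn]])
    if (nzchar(bad)) {
      pos <- regexpr("[^KTN]", contigs[[cn]])
      stop(sprintf("contig %s: symbol '%s' at position %d outside {K,T,N}",
                   cn, substr(bad, 1L, 1L), pos))
    }
  }
  structure(list(contigs = contigs, bin_size = as.integer(bin_size)),
            class = "psmc_fasta")
}

#' Write / read the binned representation
#'
#' FASTA-like text, 60 symbols per line. Round-trips exactly.
#' The bin size is recorded on each header line as `>name bin_size=s`.
#'
#' @param p A [psmc_fasta()] object.
#' @param path File path.
#' @return `write_psmcfa` returns `path` invisibly; `read_psmcfa` a
#'   [psmc_fasta()].
#' @export
write_psmcfa <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(p$contigs)) {
    writeLines(sprintf(">%s bin_size=%d", cn, p$bin_size), con)
    s <- p$contigs[[cn]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_psmcfa
#' @export
read_psmcfa <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  bin_sizes <- suppressWarnings(as.integer(sub("^.*bin_size=(\\d+).*$", "\\1",
                                               lines[hdr])))
  if (any(is.na(bin_sizes))) {
    bin_sizes <- rep(100L, length(hdr))  # headers without annotation
  }
  nms <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  ends <- c(hdr[-1L] - 1L, length(lines))
  contigs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1L))
  names(contigs) <- nms
  psmc_fasta(contigs, bin_sizes[1L])
}
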