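#' Serialize an unrooted tree to Newick
#'
#' Writes an `ape` `"phylo"` tree as Newick with branch lengths at full
#' precision (15 significant digits). Labels containing whitespace,
#' parentheses, commas, colons or semicolons are single-quoted per the
#' Newick convention. Unrooted trees keep their basal trifurcation.
#'
#' @param tree A `"phylo"` object (as returned by [neighbor_joining()]).
#' @param path Output file; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 15L) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  quote_label <- function(lab) {
    if (grepl("[\\s(),:;'\\[\\]]", lab, perl = TRUE)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else {
      lab
    }
  }
  fmt_len <- function(x) sprintf("%.*g", digits, x)

  build <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- quote_label(tree$tip.label[node])
    } else {
      kids <- children[[as.character(node)]]
      s <- paste0("(", paste(vapply(kids, function(e) {
        build(tree$edge[e, 2L], e)
      }, character(1L)), collapse = ","), ")")
    }
    if (!is.null(edge_idx) && !is.null(tree$edge.length)) {
      s <- paste0(s, ":", fmt_len(tree$edge.length[edge_idx]))
    }
    s
  }
  nwk <- paste0(build(root, NULL), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
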