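#' Published sea snake genome summaries bundled with the package
#'
#' `hydrophis_het_table()` returns the published genome-wide
#' heterozygosity summary of 16 *Hydrophis* sea snake individuals
#' (called sites, heterozygous sites and the reported 9-decimal
#' heterozygosity per individual). `hydrophis_dstat_row()` returns the
#' published ABBA-BABA test of the *H. melanocephalus* species complex
#' (site counts, D, blocked-jackknife SE and Z). Both are used as worked
#' examples and arithmetic cross-checks for [het_summary()],
#' [d_statistic()] and [block_jackknife()].
#'
#' @return A data frame.
#' @export
hydrophis_het_table <- function() {
  read.table(system.file("extdata", "hydrophis_het_summary.tsv",
                         package = "popcoal"),
             header = TRUE, sep = "\t", colClasses = c("character", "character",
                                                       "numeric", "numeric",
                                                       "character"))
}

#' @rdname hydrophis_het_table
#' @export
hydrophis_dstat_row <- function() {
  read.table(system.file("extdata", "hydrophis_dstat_row.tsv",
                         package = "popcoal"),
             header = TRUE, sep = "\t",
             colClasses = c(rep("character", 3L), "numeric", "numeric",
                            "numeric", "numeric", "numeric"))
}
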