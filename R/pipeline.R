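# End-to-end orchestration: mask -> heterozygosity -> binning -> EM ->
# scaling, for single individuals, pseudo-diploid pairs, and the
# masked-vs-unmasked comparison. Output TSVs embed the config hash and
# master seed so equal configurations give byte-identical files.

drop_excluded <- function(x, cfg) {
  excl <- strsplit(cfg$exclude_contigs, ",")[[1L]]
  excl <- trimws(excl[nzchar(trimws(excl))])
  if (length(excl) == 0L) return(x)
  keep <- setdiff(names(x$contigs), excl)
  if (length(keep) == 0L) stop("exclude list removes every contig")
  diploid_consensus(x$name, x$contigs[keep])
}

#' Run the single-individual pipeline
#'
#' Applies the contig exclude list and mask, computes genome-wide
#' heterozygosity, bins the consensus, fits the coalescent HMM and scales
#' the result to years/individuals.
#'
#' @param consensus A [diploid_consensus()].
#' @param cfg A [pipeline_config][read_config] (defaults:
#'   [pipeline_defaults()]).
#' @param mask Optional [mask_intervals()].
#' @param out_dir Optional directory for TSV artifacts.
#' @return List with `het` ([het_summary()]), `model` ([em_fit()] result)
#'   and `trajectory` ([scale_trajectory()] result).
#' @export
run_individual <- function(consensus, cfg = validate_config(pipeline_defaults()),
                           mask = NULL, out_dir = NULL) {
  stage <- "exclude"
  res <- tryCatch({
    x <- drop_excluded(consensus, cfg)
    stage <- "mask"
    if (!is.null(mask)) x <- apply_mask(x, mask)
    stage <- "het"
    het <- heterozygosity(x)
    stage <- "psmcfa"
    p <- make_psmcfa(x, bin_size = as.integer(cfg$bin_size),
                     max_missing_fraction = cfg$max_missing_fraction)
    stage <- "em_fit"
    model <- em_fit(p, pattern = cfg$pattern,
                    n_iter = as.integer(cfg$em_iterations), t_max = cfg$t_max)
    stage <- "scale"
    traj <- scale_trajectory(model, mu_per_year = cfg$mu_per_year,
                             g_years = cfg$g_years, s = as.integer(cfg$bin_size))
    list(het = het, model = model, trajectory = traj)
  }, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    write_trajectory_tsv(res$trajectory, cfg,
                         file.path(out_dir, paste0(consensus$name, "_trajectory.tsv")))
  }
  res
}

#' Run the pseudo-diploid pair pipeline
#'
#' Haploidizes both individuals (one haploid per individual per run, with
#' per-individual derived seeds), combines them, and runs heterozygosity
#' (the pair's uncorrected distance), the coalescent HMM and the
#' divergence read-off against the two single-individual trajectories.
#'
#' @param a,b Two [diploid_consensus()] objects on shared coordinates.
#' @param cfg Pipeline configuration.
#' @param mask Optional mask applied to both.
#' @param singles Optional precomputed list of the two [run_individual()]
#'   results (recomputed when `NULL`).
#' @param out_dir Optional directory for TSV artifacts.
#' @return List with `het`, `model`, `trajectory`, `divergence` and
#'   `pseudo` (the combined consensus).
#' @export
run_pair <- function(a, b, cfg = validate_config(pipeline_defaults()),
                     mask = NULL, singles = NULL, out_dir = NULL) {
  ha <- haploidize(a, derive_seed(cfg$seed, "haploid_a"))
  hb <- haploidize(b, derive_seed(cfg$seed, "haploid_b"))
  pseudo <- combine_haploids(ha, hb)
  if (is.null(singles)) {
    singles <- list(run_individual(a, cfg, mask), run_individual(b, cfg, mask))
  }
  res <- run_individual(pseudo, cfg, mask, out_dir = out_dir)
  res$divergence <- divergence_readoff(res$trajectory,
                                       singles[[1L]]$trajectory,
                                       singles[[2L]]$trajectory,
                                       C = cfg$divergence_c)
  res$pseudo <- pseudo
  res
}

#' Masked-vs-unmasked comparison workflow
#'
#' Runs the single-individual pipeline once per mask configuration and
#' tabulates per-interval population-size ratios (each configuration
#' against the first) together with called/heterozygous site deltas.
#'
#' @param consensus A [diploid_consensus()].
#' @param masks Named list of [mask_intervals()] (or `NULL` entries for no
#'   mask); at least two entries.
#' @param cfg Pipeline configuration.
#' @return List with `runs` (per-mask [run_individual()] results) and
#'   `report` (data frame: mask, interval, time span, ne, ne_ratio_to_first,
#'   called_sites, het_sites).
#' @export
run_mask_sensitivity <- function(consensus, masks,
                                 cfg = validate_config(pipeline_defaults())) {
  if (length(masks) < 2L) stop("need at least 2 mask configurations")
  if (is.null(names(masks))) names(masks) <- paste0("mask", seq_along(masks))
  runs <- lapply(masks, function(m) run_individual(consensus, cfg, mask = m))
  first <- runs[[1L]]$trajectory
  report <- do.call(rbind, lapply(names(runs), function(nm) {
    tr <- runs[[nm]]$trajectory
    # compare at the first run's intervals (midpoints)
    mid <- (tr$time_start_years + tr$time_end_years) / 2
    data.frame(mask = nm, interval = seq_len(nrow(tr)),
               time_start_years = tr$time_start_years,
               time_end_years = tr$time_end_years, ne = tr$ne,
               ne_ratio_to_first = tr$ne / trajectory_ne_at(first, mid),
               called_sites = runs[[nm]]$het$called_sites,
               het_sites = runs[[nm]]$het$het_sites)
  }))
  list(runs = runs, report = report)
}

write_trajectory_tsv <- function(traj, cfg, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d mu_per_year=%g g_years=%g bin_size=%d",
                     config_hash(cfg), as.integer(cfg$seed), cfg$mu_per_year,
                     cfg$g_years, as.integer(cfg$bin_size)), con)
  write.table(format(as.data.frame(traj), digits = 10, trim = TRUE,
                     scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
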