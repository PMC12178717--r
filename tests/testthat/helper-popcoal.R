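# Shared fixtures and independent oracles, all built in code.

# quick consensus builder from call strings
cons <- function(..., name = "ind") {
  s <- c(...)
  if (is.null(names(s))) names(s) <- paste0("c", seq_along(s))
  diploid_consensus(name, s)
}

write_tmp_fasta <- function(records, ext = ".fa") {
  path <- tempfile(fileext = ext)
  con <- file(path, "w")
  for (nm in names(records)) {
    writeLines(c(paste0(">", nm), records[[nm]]), con)
  }
  close(con)
  path
}

# analytic pairwise-coalescent CDF under piecewise-constant Ne:
# P(T <= t) = 1 - exp(-integral of 1/(2 Ne(u)) du), an independent oracle
# for the simulator's time draws
coal_cdf <- function(t, epochs) {
  starts <- epochs[, 1L]
  nes <- epochs[, 2L]
  vapply(t, function(x) {
    haz <- 0
    for (i in seq_along(starts)) {
      lo <- starts[i]
      hi <- if (i < length(starts)) starts[i + 1L] else Inf
      if (x <= lo) break
      haz <- haz + (min(x, hi) - lo) / (2 * nes[i])
    }
    1 - exp(-haz)
  }, numeric(1L))
}

# mean inferred Ne over atomic intervals whose midpoint (in generations)
# falls inside [lo_gen, hi_gen]
window_mean_ne <- function(traj, lo_gen, hi_gen, g = attr(traj, "g_years")) {
  mid <- (traj$time_start_years + traj$time_end_years) / 2 / g
  sel <- mid >= lo_gen & mid <= hi_gen
  stopifnot(any(sel))
  mean(traj$ne[sel])
}

# per-site expected heterozygosity implied by a realized TMRCA track
track_expected_het <- function(track, mu) {
  sum(track$length * -expm1(-2 * track$tmrca * mu)) / sum(track$length)
}

loglik_monotone <- function(fit, tol = 1e-6) {
  tr <- fit$loglik_trace
  all(diff(tr) >= -tol * abs(tr[-1L]))
}
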