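#' Parse a time-segmentation pattern string
#'
#' The pattern groups atomic time intervals into parameter-sharing spans:
#' a term `a*b` contributes `a` groups each spanning `b` atomic intervals;
#' a bare integer contributes one group of that span. `"4+25*2+4+6"` gives
#' 64 atomic intervals and 28 free interval parameters.
#'
#' @param spec Pattern string, e.g. `"4+25*2+4+6"`.
#' @return An object of class `time_pattern` with fields `spec`, `groups`
#'   (data frame of `span`, `rep`), `n_atomic` and `n_free`.
#' @examples
#' parse_pattern("4+25*2+4+6")  # 64 atomic intervals, 28 free parameters
#' @export
parse_pattern <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  s <- gsub("\\s", "", spec)
  if (!nzchar(s)) stop("empty pattern")
  terms <- strsplit(s, "+", fixed = TRUE)[[1L]]
  if (length(terms) == 0L || any(!nzchar(terms))) {
    stop("malformed pattern at empty term: '", spec, "'")
  }
  groups <- lapply(seq_along(terms), function(i) {
    tm <- terms[i]
    if (grepl("^\\d+$", tm)) {
      c(span = as.integer(tm), rep = 1L)
    } else if (grepl("^\\d+\\*\\d+$", tm)) {
      ab <- as.integer(strsplit(tm, "*", fixed = TRUE)[[1L]])
      c(span = ab[2L], rep = ab[1L])
    } else {
      stop(sprintf("malformed pattern term %d ('%s') in '%s'", i, tm, spec))
    }
  })
  g <- do.call(rbind, groups)
  if (any(g == 0L)) stop("pattern terms must be positive: '", spec, "'")
  structure(list(spec = s, groups = as.data.frame(g),
                 n_atomic = sum(g[, "span"] * g[, "rep"]),
                 n_free = sum(g[, "rep"])),
            class = "time_pattern")
}

#' @export
print.time_pattern <- function(x, ...) {
  cat(sprintf("<time_pattern> \"%s\": %d atomic intervals, %d free parameters\n",
              x$spec, x$n_atomic, x$n_free))
  invisible(x)
}

# free-parameter index (1..n_free) for each atomic interval
pattern_group_index <- function(pattern) {
  rep(seq_len(pattern$n_free),
      times = rep(pattern$groups$span, pattern$groups$rep))
}

#' Bin a consensus into the het/hom/missing representation
#'
#' Per consecutive window of `bin_size` sites: `N` if more than
#' `max_missing_fraction` of the window is missing; otherwise `K` if the
#' window holds at least one heterozygous call, else `T`. A final partial
#' window is binned by the same rule on its actual length.
#'
#' @param x A [diploid_consensus()].
#' @param bin_size Window size in bp.
#' @param max_missing_fraction Missing-data fraction above which a window
#'   becomes `N`.
#' @return A [psmc_fasta()].
#' @export
make_psmcfa <- function(x, bin_size = 100L, max_missing_fraction = 0.9) {
  stopifnot(inherits(x, "diploid_consensus"), bin_size >= 1)
  contigs <- vapply(names(x$contigs), function(cn) {
    codes <- classify_raw(charToRaw(x$contigs[[cn]]))
    len <- length(codes)
    nbin <- ceiling(len / bin_size)
    bin <- rep(seq_len(nbin), each = bin_size, length.out = len)
    nhet <- tabulate(bin[codes == CLASS_HET], nbins = nbin)
    nmiss <- tabulate(bin[codes == CLASS_MISSING], nbins = nbin)
    width <- tabulate(bin, nbins = nbin)
    sym <- ifelse(nmiss / width > max_missing_fraction, "N",
                  ifelse(nhet > 0L, "K", "T"))
    paste(sym, collapse = "")
  }, character(1L))
  psmc_fasta(contigs, bin_size)
}

#' Log-spaced atomic time interval boundaries
#'
#' `t_j = 0.1 * (exp((j/n) * log(1 + 10 * t_max)) - 1)` for `j = 0..n`,
#' in units of `2 * N0` generations; `t_0 = 0` and `t_n = t_max` exactly.
#'
#' @param n_atomic Number of atomic intervals.
#' @param t_max Most ancient finite boundary (coalescent units).
#' @return Numeric vector of `n_atomic + 1` strictly increasing boundaries.
#' @export
discretize <- function(n_atomic, t_max = 15) {
  stopifnot(n_atomic >= 1)
  j <- 0:n_atomic
  0.1 * (exp((j / n_atomic) * log(1 + 10 * t_max)) - 1)
}

obs_codes <- function(p) {
  lapply(p$contigs, function(s) {
    code <- match(strsplit(s, "")[[1L]], c("T", "K", "N")) - 1L
    if (anyNA(code)) stop("psmcfa contig contains symbols outside {K,T,N}")
    code
  })
}

#' Fit the coalescent HMM by expectation-maximization
#'
#' The hidden state of a bin is its discretized TMRCA interval. The
#' equilibrium distribution is the coalescent prior under the current
#' piecewise relative sizes; a het bin is emitted with probability
#' `1 - exp(-theta * tbar_j)` where `tbar_j` is the interval's conditional
#' mean time; `N` bins carry no emission information but still undergo
#' transitions, preserving spatial structure across masked repeats.
#' Transitions follow the SMC recombination/re-coalescence kernel. Each
#' iteration runs scaled forward-backward, then maximizes the expected
#' complete-data log-likelihood over `(theta, rho, lambda)` (lambda tied
#' within pattern groups) by L-BFGS-B on the log scale; updates are only
#' accepted when they improve the expected objective, so the marginal
#' log-likelihood is non-decreasing.
#'
#' @param p A [psmc_fasta()].
#' @param pattern A [parse_pattern()] result or pattern string.
#' @param n_iter Number of EM iterations.
#' @param t_max Most ancient boundary in coalescent units.
#' @param theta0,rho0 Optional initial per-bin scaled mutation and
#'   recombination rates; defaults are `-log(1 - fraction_K)` and
#'   `theta0 / 5`.
#' @return An object of class `psmc_model` with fields `theta`, `rho`,
#'   `lambdas` (free), `lambda_atomic`, `boundaries`, `pattern`, `loglik`
#'   and `loglik_trace`.
#' @export
em_fit <- function(p, pattern = "4+25*2+4+6", n_iter = 25L, t_max = 15,
                   theta0 = NULL, rho0 = NULL) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  obs <- obs_codes(p)
  counts <- table(factor(unlist(lapply(obs, function(o) o)),
                         levels = 0:2))
  nT <- counts[["0"]]; nK <- counts[["1"]]
  if (nT + nK == 0L) stop("all bins are missing ('N'); nothing to fit")
  fracK <- nK / (nK + nT)
  if (is.null(theta0)) theta0 <- max(-log1p(-fracK), 1e-6)
  if (is.null(rho0)) rho0 <- theta0 / 5
  n <- pattern$n_atomic
  bounds <- discretize(n, t_max)
  gidx <- pattern_group_index(pattern)
  lambda_free <- rep(1, pattern$n_free)

  theta <- theta0
  rho <- rho0
  trace <- numeric(n_iter)

  estep <- function(theta, rho, lambda_atomic) {
    mats <- psmc_matrices_cpp(bounds, lambda_atomic, theta, rho)
    tot <- NULL
    ll <- 0
    for (o in obs) {
      fb <- psmc_fwdback_cpp(o, mats$pi, mats$Q, mats$emitK, FALSE)
      ll <- ll + fb$loglik
      if (is.null(tot)) {
        tot <- fb
      } else {
        tot$gamma1 <- tot$gamma1 + fb$gamma1
        tot$xi <- tot$xi + fb$xi
        tot$ek <- tot$ek + fb$ek
        tot$et <- tot$et + fb$et
      }
    }
    tot$loglik <- ll
    tot
  }

  for (it in seq_len(n_iter)) {
    lambda_atomic <- lambda_free[gidx]
    e <- tryCatch(estep(theta, rho, lambda_atomic), error = function(err) {
      stop(sprintf("EM iteration %d: %s", it, conditionMessage(err)))
    })
    trace[it] <- e$loglik

    par0 <- c(log(theta), log(rho), log(lambda_free))
    fn <- function(par) {
      psmc_eneg_loglik_cpp(bounds, exp(par[-(1:2)])[gidx],
                           exp(par[1L]), exp(par[2L]),
                           e$gamma1, e$xi, e$ek, e$et)
    }
    opt <- stats::optim(par0, fn, method = "L-BFGS-B",
                        lower = rep(-9, length(par0)),
                        upper = rep(9, length(par0)),
                        control = list(maxit = 60L))
    if (is.finite(opt$value) && opt$value < fn(par0)) {
      theta <- exp(opt$par[1L])
      rho <- exp(opt$par[2L])
      lambda_free <- exp(opt$par[-(1:2)])
    }
  }
  if (any(!is.finite(trace))) {
    stop("non-finite likelihood at iteration ", which(!is.finite(trace))[1L])
  }
  structure(list(theta = theta, rho = rho, lambdas = lambda_free,
                 lambda_atomic = lambda_free[gidx], boundaries = bounds,
                 pattern = pattern, loglik = trace[n_iter],
                 loglik_trace = trace, bin_size = p$bin_size),
            class = "psmc_model")
}

#' @export
print.psmc_model <- function(x, ...) {
  cat(sprintf("<psmc_model> theta=%.5g rho=%.5g, %d atomic intervals (%d free), loglik=%.2f\n",
              x$theta, x$rho, length(x$lambda_atomic), length(x$lambdas),
              x$loglik))
  invisible(x)
}

#' Scale a fitted HMM to years and individuals
#'
#' With mutation rate `mu` per base per year and generation time `g`
#' years, `mu_gen = mu * g`, `N0 = theta / (4 * mu_gen * s)` for bin size
#' `s`; step times are `2 * N0 * t_j * g` years and sizes `N0 * lambda_k`
#' individuals.
#'
#' @param m A [em_fit()] result.
#' @param mu_per_year Mutation rate per base per year.
#' @param g_years Generation time in years.
#' @param s Bin size in bp (defaults to the model's).
#' @return An object of class `demographic_trajectory`: data frame with
#'   columns `time_start_years`, `time_end_years`, `ne`, plus attributes
#'   `mu_per_year`, `g_years`, `bin_size`, `N0`.
#' @export
scale_trajectory <- function(m, mu_per_year = 2e-9, g_years = 5,
                             s = m$bin_size) {
  stopifnot(inherits(m, "psmc_model"), mu_per_year > 0, g_years > 0, s >= 1)
  mu_gen <- mu_per_year * g_years
  N0 <- m$theta / (4 * mu_gen * s)
  tb <- m$boundaries * 2 * N0 * g_years
  n <- length(m$lambda_atomic)
  out <- data.frame(time_start_years = tb[seq_len(n)],
                    time_end_years = tb[seq_len(n) + 1L],
                    ne = N0 * m$lambda_atomic)
  attr(out, "mu_per_year") <- mu_per_year
  attr(out, "g_years") <- g_years
  attr(out, "bin_size") <- s
  attr(out, "N0") <- N0
  class(out) <- c("demographic_trajectory", "data.frame")
  out
}

# step-function lookup: Ne at time t (years); beyond the last boundary the
# most ancient size continues
trajectory_ne_at <- function(traj, t) {
  idx <- findInterval(t, c(traj$time_start_years, Inf), rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), nrow(traj))
  traj$ne[idx]
}

#' Read off a divergence time from a pseudo-diploid trajectory
#'
#' A pseudo-diploid of two diverged individuals cannot coalesce more
#' recently than their split, so its inferred population size explodes for
#' times younger than the divergence. Scanning from ancient to recent,
#' the estimate is the oldest step boundary such that for that step and
#' every more recent one the pseudo-diploid size exceeds `C` times the
#' larger of the two single-individual sizes at overlapping times.
#'
#' @param pseudo Trajectory of the pseudo-diploid ([scale_trajectory()]).
#' @param single1,single2 Trajectories of the two individuals; must share
#'   `mu_per_year` and `g_years` with `pseudo`.
#' @param C Explosion threshold multiple.
#' @return An object of class `divergence_estimate`: list with
#'   `time_years` (`NA` when no step qualifies), `no_signal`, `C`.
#' @export
divergence_readoff <- function(pseudo, single1, single2, C = 10) {
  for (tr in list(single1, single2)) {
    if (!identical(as.numeric(attr(tr, "mu_per_year")),
                   as.numeric(attr(pseudo, "mu_per_year"))) ||
        !identical(as.numeric(attr(tr, "g_years")),
                   as.numeric(attr(pseudo, "g_years")))) {
      stop("trajectories must share mu and g")
    }
  }
  overlap_end <- min(max(pseudo$time_end_years),
                     max(single1$time_end_years),
                     max(single2$time_end_years))
  steps <- which(pseudo$time_start_years < overlap_end)
  if (length(steps) == 0L) stop("trajectories have no overlapping time support")
  qualifies <- vapply(steps, function(i) {
    ts <- pseudo$time_start_years[i]
    te <- min(pseudo$time_end_years[i], overlap_end)
    # maximum of each single over the step's span (step functions)
    probe <- sort(unique(c(ts, te,
                           single1$time_start_years[single1$time_start_years > ts &
                                                      single1$time_start_years < te],
                           single2$time_start_years[single2$time_start_years > ts &
                                                      single2$time_start_years < te])))
    mid <- (head(probe, -1L) + tail(probe, -1L)) / 2
    if (length(mid) == 0L) mid <- (ts + te) / 2
    ref <- max(trajectory_ne_at(single1, mid), trajectory_ne_at(single2, mid))
    pseudo$ne[i] > C * ref
  }, logical(1L))
  # maximal run of qualifying steps starting from the most recent step
  run <- cumprod(qualifies) > 0
  if (!any(run)) {
    est <- list(time_years = NA_real_, no_signal = TRUE, C = C)
  } else {
    oldest <- max(steps[run])
    est <- list(time_years = min(pseudo$time_end_years[oldest], overlap_end),
                no_signal = FALSE, C = C)
  }
  class(est) <- "divergence_estimate"
  est
}

#' @export
print.divergence_estimate <- function(x, ...) {
  if (x$no_signal) {
    cat(sprintf("<divergence_estimate> no divergence signal (C = %g)\n", x$C))
  } else {
    cat(sprintf("<divergence_estimate> %.0f years (C = %g)\n", x$time_years, x$C))
  }
  invisible(x)
}
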