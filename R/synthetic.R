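#' Piecewise-constant demographic model
#'
#' Describes the demography driving the coalescent simulator: epochs of
#' constant diploid effective size, an optional clean population split and
#' an optional admixture pulse, plus the per-generation mutation and
#' recombination rates. Time is measured in generations before present.
#'
#' @param epochs Two-column structure of `(start, ne)` rows: epoch start
#'   times (generations, strictly increasing from 0) and diploid effective
#'   sizes. A single row gives a constant-size population.
#' @param split_time Optional population split time (generations).
#' @param admixture Optional list `list(donor=, recipient=, time=,
#'   proportion=)` describing a pulse.
#' @param mu_per_gen Mutation rate per base per generation.
#' @param r_per_gen Recombination rate per base per generation.
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(epochs, split_time = NULL, admixture = NULL,
                             mu_per_gen = 1e-8, r_per_gen = 1e-8) {
  epochs <- matrix(as.numeric(unlist(epochs)), ncol = 2L,
                   dimnames = list(NULL, c("start", "ne")))
  if (epochs[1L, "start"] != 0) stop("first epoch must start at time 0")
  if (nrow(epochs) > 1L && any(diff(epochs[, "start"]) <= 0)) {
    stop("epoch start times must be strictly increasing")
  }
  if (any(epochs[, "ne"] <= 0)) stop("all Ne must be positive")
  if (!is.null(admixture)) {
    if (admixture$proportion < 0 || admixture$proportion > 1) {
      stop("admixture proportion must lie in [0,1]")
    }
    if (!is.null(split_time) && admixture$time >= split_time) {
      stop("admixture time must predate (be more recent than) the split time")
    }
  }
  if (mu_per_gen < 0 || r_per_gen < 0) stop("rates must be non-negative")
  structure(list(epochs = epochs, split_time = split_time,
                 admixture = admixture, mu_per_gen = mu_per_gen,
                 r_per_gen = r_per_gen),
            class = "demography_model")
}

# ---- pairwise coalescent draws under piecewise-constant Ne --------------

# Draw a coalescence time for two lineages both present at time `from`,
# hazard 1/(2*Ne(t)) per generation thereafter.
coal_time_from <- function(model, from = 0) {
  ep <- model$epochs
  e <- stats::rexp(1L)
  i <- findInterval(from, ep[, "start"])
  t <- from
  repeat {
    rate <- 1 / (2 * ep[i, "ne"])
    upper <- if (i < nrow(ep)) ep[i + 1L, "start"] else Inf
    need <- e / rate
    if (t + need < upper) return(t + need)
    e <- e - rate * (upper - t)
    t <- upper
    i <- i + 1L
  }
}

#' Sample a TMRCA track along a chromosome
#'
#' Realizes the sequentially Markovian coalescent for one pair of
#' haplotypes: the initial TMRCA is drawn from the pairwise coalescent
#' under the model's piecewise-constant Ne; recombination breakpoints
#' occur at per-bp rate `2 * T * r_per_gen`; at a breakpoint one lineage
#' is erased at a uniform time on `[0, T]` and re-coalesces under the same
#' demography (SMC resampling).
#'
#' @param model A [demography_model()].
#' @param length Chromosome length in bp.
#' @param seed Integer seed.
#' @param min_time Floor on coalescence times (generations); used
#'   internally for cross-population pairs, which cannot coalesce more
#'   recently than the split.
#' @return An object of class `tmrca_track`: a data frame with columns
#'   `length` (bp, summing to `length`) and `tmrca` (generations).
#' @export
sample_pairwise_tmrca <- function(model, length, seed = NULL, min_time = 0) {
  stopifnot(length >= 1)
  r <- model$r_per_gen
  with_seed(seed, {
    segs_len <- numeric(0)
    segs_t <- numeric(0)
    draw0 <- function() coal_time_from(model, min_time)
    # re-coalescence floor: erase at u, restart from max(u, min_time)
    tcur <- draw0()
    pos <- 0
    cap <- 1024L
    bps <- numeric(cap)
    tv <- numeric(cap)
    nseg <- 0L
    while (pos < length) {
      rate <- 2 * tcur * r
      seg <- if (rate > 0) stats::rexp(1L, rate) else Inf
      nxt <- min(pos + seg, length)
      nseg <- nseg + 1L
      if (nseg > cap) {
        cap <- cap * 2L
        bps <- c(bps, numeric(cap / 2L))
        tv <- c(tv, numeric(cap / 2L))
      }
      bps[nseg] <- nxt
      tv[nseg] <- tcur
      pos <- nxt
      if (pos < length) {
        u <- stats::runif(1L, 0, tcur)
        tcur <- coal_time_from(model, max(u, min_time))
      }
    }
    bps <- bps[seq_len(nseg)]
    tv <- tv[seq_len(nseg)]
    lens <- diff(floor(c(0, bps)))
    keep <- lens > 0
    segs_len <- lens[keep]
    segs_t <- tv[keep]
  })
  structure(data.frame(length = as.integer(segs_len), tmrca = segs_t),
            class = c("tmrca_track", "data.frame"))
}

#' Drop mutations on a TMRCA track to build a diploid consensus
#'
#' Each site is heterozygous with probability `1 - exp(-2 * T *
#' mu_per_gen)` given its segment's TMRCA `T`, independently across sites.
#' Heterozygous sites receive a random two-base IUPAC code, homozygous
#' sites a random base.
#'
#' @param track A [sample_pairwise_tmrca()] result.
#' @param mu_per_gen Mutation rate per base per generation.
#' @param seed Integer seed.
#' @param name Individual name for the result.
#' @param contig Contig name.
#' @return A [diploid_consensus()].
#' @export
drop_mutations <- function(track, mu_per_gen, seed = NULL,
                           name = "sim", contig = "chr1") {
  tsite <- rep(track$tmrca, track$length)
  p <- -expm1(-2 * tsite * mu_per_gen)
  with_seed(seed, {
    het <- stats::runif(length(p)) < p
    calls <- sample(charToRaw(paste(HOM_BASES, collapse = "")),
                    length(p), replace = TRUE)
    nhet <- sum(het)
    if (nhet > 0L) {
      calls[het] <- sample(charToRaw(paste(HET_CODES, collapse = "")),
                           nhet, replace = TRUE)
    }
  })
  diploid_consensus(name, setNames(rawToChar(calls), contig))
}

#' Simulate one individual's consensus genome
#'
#' Convenience wrapper: TMRCA track then mutations, with sub-seeds derived
#' from `seed`.
#'
#' @inheritParams sample_pairwise_tmrca
#' @param name Individual name.
#' @param contig Contig name.
#' @return A [diploid_consensus()].
#' @export
simulate_consensus <- function(model, length, seed, name = "sim",
                               contig = "chr1") {
  track <- sample_pairwise_tmrca(model, length, derive_seed(seed, "tmrca"))
  drop_mutations(track, model$mu_per_gen, derive_seed(seed, "mutations"),
                 name = name, contig = contig)
}

#' Simulate a clean-split pair of diploid genomes
#'
#' Two individuals from populations that split `split_time` generations
#' ago with no subsequent migration. Within-individual TMRCA tracks are
#' drawn unconstrained; the cross-population track is floored at the split
#' time. Sequences are constructed so that the haploidize-and-combine
#' pseudo-diploid has per-site mismatch probability exactly
#' `1 - exp(-2 * T_AB * mu)` in expectation: inter-population fixed
#' differences are planted at rate `mu * max(2*T_AB - T_A - T_B, 0)` and
#' each individual's private heterozygous sites contribute the remaining
#' `mu * T_A` (resp. `mu * T_B`) through the haploidization coin flip.
#'
#' @param model A [demography_model()] with `split_time` set.
#' @param length Chromosome length (bp).
#' @param seed Integer seed.
#' @param names Names for the two individuals.
#' @return List with elements `A`, `B` (consensuses), `cross_track` (the
#'   cross-population [sample_pairwise_tmrca()] track) and `split_time`.
#' @export
simulate_split_pair <- function(model, length, seed, names = c("A", "B")) {
  tau <- model$split_time
  if (is.null(tau)) stop("model has no split_time")
  mu <- model$mu_per_gen
  track_a <- sample_pairwise_tmrca(model, length, derive_seed(seed, "haploid_a"))
  track_b <- sample_pairwise_tmrca(model, length, derive_seed(seed, "haploid_b"))
  track_ab <- sample_pairwise_tmrca(model, length, derive_seed(seed, "tmrca"),
                                    min_time = tau)
  ta <- rep(track_a$tmrca, track_a$length)
  tb <- rep(track_b$tmrca, track_b$length)
  tab <- rep(track_ab$tmrca, track_ab$length)

  with_seed(derive_seed(seed, "mutations"), {
    n <- length
    bg <- sample(charToRaw(paste(HOM_BASES, collapse = "")), n, replace = TRUE)
    het_a <- stats::runif(n) < -expm1(-2 * ta * mu)
    het_b <- stats::runif(n) < -expm1(-2 * tb * mu)
    fix <- stats::runif(n) < -expm1(-mu * pmax(2 * tab - ta - tb, 0))

    other_base <- function(b, k) {
      # a uniform base different from b, vectorized
      idx <- match(as.integer(b), as.integer(charToRaw(paste(HOM_BASES, collapse = ""))))
      shift <- sample.int(3L, k, replace = TRUE)
      charToRaw(paste(HOM_BASES, collapse = ""))[((idx - 1L + shift) %% 4L) + 1L]
    }
    het_code <- function(b1, b2) {
      PAIR_TABLE[as.integer(b1) * 256L + as.integer(b2) + 1L]
    }

    a_calls <- bg
    if (any(het_a)) {
      k <- sum(het_a)
      a_calls[het_a] <- het_code(bg[het_a], other_base(bg[het_a], k))
    }
    bg_b <- bg
    if (any(fix)) {
      k <- sum(fix)
      bg_b[fix] <- other_base(bg[fix], k)
    }
    b_calls <- bg_b
    if (any(het_b)) {
      k <- sum(het_b)
      b_calls[het_b] <- het_code(bg_b[het_b], other_base(bg_b[het_b], k))
    }
  })
  list(A = diploid_consensus(names[1L], setNames(rawToChar(a_calls), "chr1")),
       B = diploid_consensus(names[2L], setNames(rawToChar(b_calls), "chr1")),
       cross_track = track_ab,
       split_time = tau)
}

#' Four-taxon quartet demography
#'
#' Constant per-population diploid size with a fixed species tree
#' `(((inner1, inner2), third), outgroup)` and an optional admixture pulse.
#'
#' @param ne Diploid effective size of every population.
#' @param split_pair Split time of the two inner taxa (generations).
#' @param split_third Join time of the third taxon.
#' @param split_outgroup Join time of the outgroup.
#' @param admix_time Pulse time (generations; must predate `split_pair`).
#' @param admix_prop Pulse proportion `f` in `[0, 1]`.
#' @return An object of class `quartet_model`.
#' @export
quartet_model <- function(ne = 1e4, split_pair = 2e4, split_third = 4e4,
                          split_outgroup = 1e5, admix_time = 1e4,
                          admix_prop = 0) {
  if (!(split_pair < split_third && split_third < split_outgroup)) {
    stop("split times must satisfy split_pair < split_third < split_outgroup")
  }
  if (admix_prop < 0 || admix_prop > 1) stop("admix_prop must lie in [0,1]")
  if (admix_prop > 0 && admix_time >= split_pair) {
    stop("admix_time must be more recent than split_pair")
  }
  structure(list(ne = ne, split_pair = split_pair, split_third = split_third,
                 split_outgroup = split_outgroup, admix_time = admix_time,
                 admix_prop = admix_prop),
            class = "quartet_model")
}

parse_quartet_topology <- function(topology) {
  s <- gsub("\\s", "", topology)
  m <- regmatches(s, regexec("^\\(\\(\\((\\w+),(\\w+)\\),(\\w+)\\),(\\w+)\\)$", s))[[1]]
  if (length(m) == 0L) {
    m <- regmatches(s, regexec("^\\(\\((\\w+),(\\w+)\\),(\\w+)\\),(\\w+)$", s))[[1]]
  }
  if (length(m) != 5L) stop("invalid topology string: ", topology)
  labs <- m[2:5]
  if (!setequal(labs, c("H1", "H2", "H3", "O"))) {
    stop("topology must place labels H1, H2, H3 and O: ", topology)
  }
  labs  # leaf order: inner1, inner2, third, outgroup
}

#' Simulate quartet site patterns under a species tree with admixture
#'
#' Per site an independent four-haplotype coalescent genealogy is drawn
#' under the quartet model, with an optional H3 -> H2 pulse of proportion
#' `f`; one mutation placed uniformly on the genealogy yields a biallelic
#' pattern. Sites carry contiguous coordinates and are grouped into blocks
#' of `block_length` sites for jackknifing.
#'
#' @param model A [quartet_model()].
#' @param topology Topology string, default `"((H1,H2),H3),O"`; the four
#'   labels may be permuted over the tree's positions.
#' @param n_sites Number of sites.
#' @param block_length Sites per jackknife block.
#' @param seed Integer seed.
#' @return A data frame of class `quartet_sites` with columns `contig`,
#'   `pos`, `H1`, `H2`, `H3`, `O` (single bases) and `block`.
#' @export
simulate_quartet_sites <- function(model, topology = "((H1,H2),H3),O",
                                   n_sites = 1e5, block_length = 1000,
                                   seed = NULL) {
  stopifnot(inherits(model, "quartet_model"), n_sites >= 1)
  labs <- parse_quartet_topology(topology)
  recipient <- which(labs == "H2") - 1L
  donor <- which(labs == "H3") - 1L
  with_seed(seed, {
    masks <- sim_quartet_masks_cpp(as.integer(n_sites), model$ne,
                                   model$split_pair, model$split_third,
                                   model$split_outgroup, model$admix_time,
                                   model$admix_prop, recipient, donor)
    anc <- sample(HOM_BASES, n_sites, replace = TRUE)
    shift <- sample.int(3L, n_sites, replace = TRUE)
  })
  der <- HOM_BASES[((match(anc, HOM_BASES) - 1L + shift) %% 4L) + 1L]
  alleles <- lapply(seq_len(4L), function(i) {
    ifelse(bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0L, der, anc)
  })
  names(alleles) <- labs
  out <- data.frame(contig = "sim", pos = seq_len(n_sites),
                    H1 = alleles[["H1"]], H2 = alleles[["H2"]],
                    H3 = alleles[["H3"]], O = alleles[["O"]],
                    block = ((seq_len(n_sites) - 1L) %/% block_length) + 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("quartet_sites", "data.frame")
  out
}

#' Plant artifact heterozygosity into a consensus
#'
#' Emulates repeat-region assembly/alignment error by overwriting a set of
#' intervals with artificially elevated heterozygosity: inside the
#' intervals each site is heterozygous with probability `het_rate`
#' regardless of the underlying genealogy. Returns the modified consensus
#' and the intervals as a mask, so the same regions can be masked out in a
#' comparison run.
#'
#' @param x A [diploid_consensus()] (single contig).
#' @param n_regions Number of artifact regions.
#' @param region_length Length of each region (bp).
#' @param het_rate Per-site heterozygosity inside the regions.
#' @param seed Integer seed.
#' @return List `consensus` (modified copy) and `mask`
#'   ([mask_intervals()] covering the planted regions).
#' @export
plant_artifact_regions <- function(x, n_regions = 40L, region_length = 5e4,
                                   het_rate = 0.01, seed = NULL) {
  stopifnot(inherits(x, "diploid_consensus"), length(x$contigs) == 1L)
  cn <- names(x$contigs)[1L]
  len <- nchar(x$contigs[[1L]])
  with_seed(seed, {
    starts <- sort(sample.int(len - region_length, n_regions))
    r <- charToRaw(x$contigs[[1L]])
    for (s in starts) {
      idx <- s:(s + region_length - 1L)
      het <- stats::runif(region_length) < het_rate
      calls <- sample(charToRaw(paste(HOM_BASES, collapse = "")),
                      region_length, replace = TRUE)
      if (any(het)) {
        calls[het] <- sample(charToRaw(paste(HET_CODES, collapse = "")),
                             sum(het), replace = TRUE)
      }
      r[idx] <- calls
    }
  })
  mask <- mask_intervals(setNames(
    list(cbind(start = starts - 1L, end = starts - 1L + region_length)), cn))
  list(consensus = diploid_consensus(x$name, setNames(rawToChar(r), cn)),
       mask = mask)
}
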