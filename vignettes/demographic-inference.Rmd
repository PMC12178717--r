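---
title: "Coalescent demographic inference from diploid consensus genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent demographic inference from diploid consensus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcoal)
```

## The problem

A single diploid genome records a surprising amount of population history.
Each locus of the genome has a time to the most recent common ancestor
(TMRCA) of its two haplotypes, and the density of heterozygous sites along
the chromosome is a noisy readout of that local TMRCA: a segment that
coalesced recently carries almost no heterozygotes, a deep-coalescing
segment carries many. Because the pairwise coalescence rate at time $t$ is
$1/(2N_e(t))$ per generation, the genome-wide distribution of local TMRCA
encodes the trajectory of historical effective population size $N_e(t)$.

`popcoal` implements this inversion for diploid consensus sequences in
IUPAC-coded FASTA — the representation produced by standard consensus
callers — together with the companion analyses that make it useful for
comparative work on groups of individuals, as in recent genome-wide
studies of marine snake speciation:

* genome-wide heterozygosity with repeat-mask handling,
* *pseudo-diploids* (one randomly chosen haploid from each of two
  individuals) whose inferred $N_e$ explodes at the divergence time of the
  two source populations,
* neighbor-joining trees from pseudo-diploid heterozygosities,
* ABBA-BABA D-statistics with block-jackknife standard errors, and
* a sequentially Markovian coalescent (SMC) simulator that generates
  consensus genomes with known demography, so every stage of the pipeline
  is testable without any sequencing data.

## The hidden Markov model

The genome is cut into bins of $s$ sites (default $s = 100$); a bin is
`K` if it contains at least one heterozygous call, `T` if it is called but
contains none, and `N` if more than 90% of it is missing. The hidden state
of a bin is its discretized TMRCA interval: boundaries

$$t_j = 0.1\,\bigl(e^{(j/n)\log(1 + 10\,t_{max})} - 1\bigr), \qquad j = 0 \dots n,$$

in units of $2N_0$ generations, with $n = 64$ atomic intervals and
$t_{max} = 15$ by default. Atomic intervals share parameters according to
a segmentation pattern (default `"4+25*2+4+6"`: 64 atomic intervals, 28
free parameters), which stabilizes the poorly constrained recent and
ancient extremes.

The model has per-bin scaled rates $\theta$ (mutation) and $\rho$
(recombination) and relative sizes $\lambda_j = N_e(t_j)/N_0$:

* **Prior** (chain equilibrium): the pairwise coalescent under piecewise
  $\lambda$, $\Pr(T > t) = \exp(-\int_0^t du/\lambda(u))$.
* **Emission**: $\Pr(K \mid j) = 1 - e^{-\theta\,\bar t_j}$ where
  $\bar t_j$ is the interval's conditional mean TMRCA under the current
  $\lambda$; `N` bins are emitted with probability one in every state, so
  masked stretches carry no mutation information but still propagate the
  chain — this is exactly the mechanism that makes repeat masking matter.
* **Transition**: the SMC kernel evaluated at $\bar t_k$: with
  probability $e^{-\rho\,\bar t_k}$ the bin keeps its state; otherwise one
  lineage is erased at a uniform time $u \in [0, \bar t_k]$ and
  re-coalesces under the piecewise-exponential hazard. The integrals over
  $u$ are closed-form per piece and accumulated in log space.

Fitting is by expectation-maximization: scaled forward–backward collects
expected initial-state, transition, and emission counts, and the M-step
maximizes the expected complete-data log-likelihood over
$(\theta, \rho, \lambda)$ with L-BFGS-B on the log scale (bounds
$e^{\pm 9}$). An update is accepted only when it improves the expected
objective, so the marginal log-likelihood is non-decreasing — a property
the test suite asserts on every fit. Using the interval-conditional mean
$\bar t_j$ rather than an integral over the interval is a deliberate
point approximation; it matches the simulator's kernel exactly and
midpoint alternatives differ negligibly at the default discretization.

Scaling to natural units uses two constants, the per-year mutation rate
$\mu$ and the generation time $g$ (defaults $\mu = 2\times10^{-9}$,
$g = 5$ years, the values used for sea snakes): $\mu_{gen} = \mu g$,
$N_0 = \theta / (4 \mu_{gen} s)$, step times $2 N_0 t_j g$ years and sizes
$N_0 \lambda_j$ individuals.

### What the estimates can and cannot resolve

With 28 free parameters and a 10 Mb genome, individual atomic intervals
are estimated with substantial scatter: refitting data simulated from the
discretized model itself leaves per-interval errors of tens of percent,
purely from estimation variance. Averages over the well-constrained
window (intervals covering roughly 0.2–2 times the mean coalescent time)
are accurate to a few percent at 10 Mb. The test suite therefore checks
window averages, and trajectory wiggles within that scatter should not be
over-interpreted on small genomes. The recent extreme (younger than a few
thousand generations) and the ancient tail are intrinsically poorly
constrained, as for any method of this family.

## Divergence from pseudo-diploids

A pseudo-diploid combines one haploid from each of two individuals; at
heterozygous sites the allele is chosen with probability $\frac12$ per
site. Its "heterozygosity" is the per-site mismatch fraction of the two
haploids — an uncorrected genetic distance — and its local mismatch
density is governed by the cross-population TMRCA, which cannot postdate
the populations' split $\tau$. The fitted trajectory therefore explodes
for times more recent than $\tau$. The read-off scans steps from ancient
to recent and reports the oldest step boundary such that that step and
every more recent one has pseudo-diploid $N_e$ exceeding $C$ times the
larger single-individual $N_e$ at overlapping times. The threshold $C$
operationalizes "nearly infinite"; it defaults to 10, is reported with
every estimate, and stricter (larger) values can only shorten the
qualifying run and hence move the estimate toward the present. On clean
10 Mb splits the estimate lands within about 20% of the truth, with a
mild systematic toward younger values because the explosion develops over
the transition interval.

## Distances and trees

Pseudo-diploid heterozygosities for all pairs give the uncorrected
distance matrix $p$; multiple substitutions are corrected by default with
Jukes–Cantor, $d = -\frac34\log(1 - \frac43 p)$, with the pure Poisson
correction $d = -\log(1-p)$ available in the configuration. At the
distance scale where this pipeline operates (pairwise $p \approx
0.001$–$0.006$) the two corrections are near-proportional and cannot
change the neighbor-joining topology, which the tests assert directly;
both are provided because either reading of "Poisson-corrected
Jukes–Cantor distance" is defensible. Neighbor joining is the canonical
Saitou–Nei algorithm; ties in the $Q$ criterion break to the lowest index
pair for determinism, and negative branch lengths are retained rather
than clamped so that exactly additive matrices are reproduced exactly
(the additivity oracle in the tests relies on this).

## D-statistics

For a quartet (H1, H2, H3, outgroup), sites where any individual is
missing or the outgroup is heterozygous are excluded; heterozygous sites
of H1–H3 are resolved by sampling one allele uniformly; sites with more
than two alleles are dropped. With A the outgroup allele and B the single
alternative, ABBA means (H1=A, H2=B, H3=B) and BABA (H1=B, H2=A, H3=B),

$$D = \frac{n_{ABBA} - n_{BABA}}{n_{ABBA} + n_{BABA}},$$

with a delete-one block jackknife over physical blocks (default 5 Mb; the
unweighted estimator, since blocks are near-equal by construction) giving
the standard error and $Z = D/SE$. $|Z| > 3$ is the conventional
significance criterion.

## The simulator and what it does (not) emulate

`sample_pairwise_tmrca()` realizes the SMC along a chromosome: an initial
TMRCA from the piecewise-exponential pairwise coalescent, breakpoints at
rate $2 T r$ per bp, and at each breakpoint an erase-and-recoalesce
resample. This is the SMC, not SMC′ — no back-coalescence to the erased
branch — which is simpler and adequate for generating data the HMM can
invert; the per-site TMRCA marginal is still the exact coalescent (the
tests verify both the marginal and the exponential segment lengths).
`drop_mutations()` places heterozygotes independently per site with
probability $1 - e^{-2T\mu_{gen}}$.

For clean-split pairs the package simulates three tracks (within A,
within B, cross-pair with TMRCA floored at $\tau$) and constructs the two
consensus sequences so that the haploidize-and-combine pseudo-diploid has
per-site mismatch probability exactly $1 - e^{-2 T_{AB} \mu}$: fixed
inter-population differences are planted at rate
$\mu \max(2T_{AB} - T_A - T_B, 0)$ and each individual's private
heterozygous sites contribute the remaining $\mu T_A$ (resp. $\mu T_B$)
through the haploidization coin flip. Without this accounting the private
variation would be double-counted and contaminate the recent end of the
pseudo-diploid trajectory with spurious coalescence signal.

Quartet sites for the D-statistic are drawn as independent four-lineage
coalescent genealogies under a fixed species tree with constant
population size and an optional admixture pulse (H3 → H2 with probability
$f$ per site at the pulse time), with one mutation placed uniformly on
the genealogy. Sites are unlinked given their block; linkage enters only
through block assignment, which is sufficient to exercise the jackknife.

Default study conditions used throughout the tests: diploid size
$N_e = 10^4$, $\mu_{gen} = 10^{-8}$ per bp per generation (i.e.
$\mu = 2\times10^{-9}$ per year with $g = 5$), $r = 10^{-8}$ per bp per
generation, split time $10^5$ generations (0.5 My) for pair scenarios,
quartet splits at $2\times10^4 / 4\times10^4 / 10^5$ generations with a
pulse at $10^4$ generations, and genome sizes of 5–10 Mb — large enough
for window-averaged recovery at a few percent, small enough that the full
suite runs on one CPU in minutes. What the simulator deliberately does
not emulate: full ancestral-recombination-graph linkage between the four
quartet lineages, migration other than a single pulse, selection,
sequencing error, and reference bias. Passing tests therefore demonstrate
correctness of the inference machinery under the model's own assumptions,
not robustness to every artifact of real resequencing data — the planted
"repeat artifact" workflow (`plant_artifact_regions()` +
`run_mask_sensitivity()`) probes exactly one such artifact class, namely
spurious heterozygosity concentrated in repeat-like regions, and
reproduces the qualitative masked-versus-unmasked divergence in the
recent era.

## Numerical choices and degenerate inputs

* Consensus normalization maps lowercase (soft-masked) bases, `n`, and
  three/four-base ambiguity codes to missing; a diploid consensus can
  carry at most two alleles per site, so `B/D/H/V` indicate low
  confidence rather than genotypes. This treats soft-masked input like a
  hard-masked reference, which the mask-sensitivity analysis requires.
* BED masks are 0-based half-open and merged on input; intervals past the
  contig end are hard errors, as are mask contigs absent from the
  consensus.
* Heterozygosity is reported as the exact integer quotient, displayed at
  9 decimals.
* `em_fit()` refuses all-`N` input and reports the iteration on any
  non-finite likelihood; zero called sites is an explicit error for
  heterozygosity; a D-statistic with no informative sites is an explicit
  error, and identical jackknife blocks yield SE 0 with an explicit
  infinite-Z flag rather than NaN.
* All randomness flows through R's Mersenne–Twister; each stochastic
  operation seeds a local RNG scope (the caller's stream is untouched)
  and pipeline stages derive sub-seeds from the master seed by fixed
  labeled offsets, so any stage can be replayed in isolation. Outputs
  embed the configuration hash and master seed; equal configurations give
  byte-identical files.

## A small worked example

```{r example, eval = FALSE}
mod <- demography_model(epochs = cbind(0, 1e4), split_time = 1e5,
                        mu_per_gen = 1e-8, r_per_gen = 1e-8)
pair <- simulate_split_pair(mod, 2e6, seed = 1)
pseudo <- combine_haploids(haploidize(pair$A, 1), haploidize(pair$B, 2))
heterozygosity(pseudo)          # ~ 2 * mu * (tau + 2N)
fit <- em_fit(make_psmcfa(pseudo), n_iter = 15)
scale_trajectory(fit, mu_per_year = 2e-9, g_years = 5)
```

## Known limitations

* The point-mass transition approximation and the SMC (rather than SMC′)
  kernel are shared simplifications of simulator and fitter; they favor
  internal consistency over fidelity to the full coalescent with
  recombination.
* Per-interval size estimates on sub-genome-scale input carry large
  variance; compare window averages, not single intervals.
* The divergence read-off assumes no post-split gene flow; admixed pairs
  do not explode cleanly and should be screened with the D-statistic
  workflow instead.
* Bootstrap resampling of segments, multi-haplotype extensions, CpG
  filtering and per-chromosome mutation-rate heterogeneity are out of
  scope.
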