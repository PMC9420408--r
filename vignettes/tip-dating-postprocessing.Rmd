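---
title: "Ancestral states, geocoordinates and lineage counts on tip-dated trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral states, geocoordinates and lineage counts on tip-dated trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoASR)
```

# Scope

`paleoASR` covers the computational stages that sit *around* a Bayesian
tip-dating run for a clade with a rich fossil record — the kind of study in
which fossil occurrences enter the tree as dated tips and the time-scaled
consensus tree is then mined for trait evolution, historical biogeography and
diversity dynamics. The MCMC engines themselves (tree inference,
stepping-stone marginal likelihoods, variable-rates continuous-trait
samplers) are out of scope: the package consumes their outputs (time-trees,
posterior tree samples, marginal log-likelihoods) and prepares their inputs
(supermatrices, tip-age priors, clock-rate priors).

Everything operates on two containers: the `time_tree` (an `ape::phylo`
carrying absolute node ages in Ma, the primary representation from which
branch lengths are derived) and the `char_matrix` (taxa-by-characters
discrete states with per-character ordered flags and partition ids).

# Matrix preparation

Morphological source matrices of very different sizes are concatenated with
*duplication balancing*: each block is repeated an integer number of times so
partition sizes come out nearly equal (83, 28, 17 characters at factors 1, 3,
5 give partitions of 83/84/85). The duplication exists purely to upweight the
likelihood signal of small matrices during topology proposals; duplicated
columns therefore carry a `dup_of` flag so that downstream character
statistics (ancestral reconstruction, rate estimates) can use each character
once. Columns whose observed states collapse to a single value are removed,
because variable coding for ascertainment bias presupposes variability.

Biogeography is coded as one **ordered** multistate character from five
contiguous longitudinal zones that tile the circle (codes 0–4, west to east,
one zone crossing the dateline). Intervals are half-open `[lon_min,
lon_max)` so every longitude in `(-180, 180]` maps to exactly one zone; a
boundary longitude belongs to the zone whose lower bound it equals (the
source description leaves boundary points unspecified; a deterministic
convention is required for reproducibility). Wide-ranging taxa whose
distributions straddle several zones are coded `?` so they cannot corrupt
the contiguity of the ordered series.

Taxa known from localities with *different* age ranges are split into one
OTU per distinct range. The OTU with the oldest range — ranked by `age_max`
descending, then `age_min` descending, then locality id (a tie-break the
source leaves open) — keeps the original character scores; the others are
recoded all-missing, which forces morphological distances to be computed
between earliest occurrences. Each split taxon yields one clade constraint
and per-OTU uniform tip-age priors, rendered on request as a reference
MrBayes block.

# Discrete ancestral states

Characters evolve under the symmetric Mk model. We parameterise the rate as
the *per-allowed-move* rate: `Q = r (A - diag(rowSums(A)))` with `A` the
adjacency of allowed transitions (all pairs when unordered; neighbours only
when ordered). This keeps `r` comparable across ordered and unordered
characters. The root prior is uniform over the `k` states, which is also the
stationary distribution of the symmetric model. Missing tips contribute
all-ones partial likelihoods.

Likelihoods use Felsenstein pruning with per-message rescaling; marginal
node probabilities use the outside–inside recursion, which is algebraically
identical to re-rooting at every node but costs one extra pass. In `"ML"`
mode the per-character rate is first maximised (bounded search on the log
scale); in `"mcmc"` mode the rate is sampled by a log-scale random-walk
Metropolis under a uniform prior (with the log-rate Jacobian in the
acceptance ratio), the step size adapted toward 0.3 acceptance over a
500-iteration burn-in, and node marginals averaged over 3,500 retained
samples by default — matching the sample count of the discrete-ASR toolkit
this emulates, whose internal sampler is not documented; the emulation is
flagged as such.

A branch is an *unambiguous synapomorphy* for a character when the modal
states of its two endpoint reconstructions differ and each reaches the
confidence threshold `p*`. The source never defines "unambiguous"
numerically; we default to `p* = 0.9`, configurable.

# Continuous geocoordinates: the two-pass reconstruction

Ancestral positions are modelled as bivariate Brownian motion of (lon, lat)
on the plane. Longitudes are first unwrapped about a chart centre (default:
the spherical centroid of the tips) so point sets straddling the dateline
become contiguous; latitudes are used as-is. This planar treatment matches
the "two continuous traits" convention of the continuous-character engines
it replaces and is a documented approximation that degrades toward the
poles. The 2×2 rate matrix is estimated by REML from phylogenetically
independent contrasts (computed by a sequential peeling recursion that
tolerates polytomies and zero-length branches); ancestral means are the GLS
estimates, obtained by a two-pass message recursion; each node's covariance
is its Brownian conditional-variance scalar times the rate matrix, and
confidence ellipses take semi-axes `sqrt(eigenvalue × qchisq(c, 2))`, by
default at c = 0.68. The homogeneous-rate model replaces the variable-rates
MCMC of the original engine deliberately: it has closed-form structure that
can be verified against cherry-tree algebra and calibrated by simulation,
whereas the variable-rates machinery is an engine internal that the source
does not specify.

**First pass.** Tips bundling several same-age localities enter as their
spherical geocentroids (unit-vector means — arithmetic longitude means fail
across the dateline), extant species as the centroid of their range sample
points; the BM fit supplies every internal node's mean position.

**Second pass.** Each multi-locality tip is expanded so every locality gets
its own tip, then the BM fit is rerun on the expanded tree:

1. a per-tip scaling factor `s = Δt / d` (Ma/km) converts geographic
   distance to time, where `Δt` is the tip's branch duration and `d` the
   distance from its centroid to its parent's first-pass mean (if `d = 0`
   the global median `s` is used and the event logged);
2. *two* localities: the terminal bifurcates; both new tips keep the
   original tip age and the new node sits at `tip age + d·s` (the full
   scaled inter-locality distance — the source wording is ambiguous between
   `d·s` and `d·s/2`, so the alternative is one argument away), clamped 1%
   of the branch duration below the parent;
3. *three or more* localities: geodesic distance matrix (haversine,
   R = 6371 km) → neighbor joining (negative branch lengths clamped with the
   deficit moved to the sibling, preserving path lengths) → rooted at the
   midpoint of the terminal branch of the locality closest to the parent's
   first-pass position (ties to the lowest label) → nonparametric rate
   smoothing to a flush-tipped tree → scaled to km depth equal to twice the
   mean root-to-tip path (so the n = 2 case reproduces rule 2 exactly) → ×s
   into Ma → grafted so all new tips sit exactly at the original tip age.

NPRS minimises Sanderson's squared rate-difference objective over
logit-parameterised age fractions, the root term taken as deviations of the
root children's rates from their mean; clock-like input is recovered with
objective ≈ 0 because the initialisation (mean node-to-tip depths) is then
already optimal. Tips with zero-duration terminal branches cannot be split
(there is no branch to shorten) and stay bundled at their centroid, logged.

# Lineage counts through time

Diversity is quantified at fixed slices (default 0.5 Ma). An edge is alive
at slice `t` iff `age(parent) > t ≥ age(child)`: a node exactly at the slice
counts as already split and a fossil tip counts at its own age but not at
younger slices (conventions the source leaves open; both are documented and
tested). Before counting, species represented by several OTUs are reduced to
their latest occurrence, so the count at `t = 0` equals the number of extant
species. Branches are assigned to zones only when both endpoint
reconstructions agree confidently; transition branches are excluded from
every zone subset, so per-zone counts plus the ambiguous count always
partition the total. `percent_decline()` optionally floors the percentage to
match "declined by a minimum of x%" phrasing.

# Posterior summaries and priors

`hdi()` is the exact shortest-window interval over the sorted sample
(leftmost window on ties), checked against exhaustive search.
`parse_tip_ages()` reads each posterior sample's tip ages off its root-to-tip
path lengths, anchoring each sample by treating its youngest tip as extant.
`implied_rates()` divides non-clock root-to-tip path lengths (substitutions
per site) by tip time spans; `fit_clockrate_prior()` fits lognormal, gamma,
exponential and normal families by maximum likelihood and ranks them by
`BIC = k ln n − 2 lnL`, reporting lognormal parameters on the log scale used
by tip-dating software. One rate observation per tip is used; the published
script this emulates does not document its internals, so the emulation is
flagged in the output metadata. `ln_bayes_factor()` is the difference of
marginal log-likelihoods with the conventional ln-odds evidence bands.

# The synthetic-data generator

Because the real inputs live in an external archive, every stage is
exercised on synthetic data with the same statistical structure: a forward
birth–death simulation from two crown lineages with Poisson fossil
recovery (each fossil a terminal tip; unsampled extinct lineages pruned),
discrete characters evolved with the *same* Mk kernel the reconstruction
uses, coordinates evolved by planar bivariate BM wrapped only at output, and
occurrence tables with jittered multi-locality fossils, uniform age ranges
containing the true age, and per-extant-species range samples.

Defaults are fixed once to emulate the study conditions: crown age 56 Ma
(the outgroup-based root minimum); λ = 0.15, μ = 0.12, ψ = 0.05 per Ma,
giving a handful of extant survivors and tens of fossil tips, as in a clade
with 4 living species and ~56 sampled fossil species; 83 characters; BM rate
diag(25, 9) deg²/Ma, whose implied longitudinal spread (sd ≈ 37° over the
crown span) reproduces the multi-zone, trans-oceanic dispersal structure of
the empirical dataset; 30% multi-locality fossils (~106 localities for 56
taxa); 1.3 Ma age-range half-widths (the scale of the empirical ranges);
500 km locality jitter; 30 range points per extant species. All randomness
is R's Mersenne-Twister under an explicit seed; identical configurations
give byte-identical outputs.

What the generator does *not* emulate: DNA sequences (out of scope),
posterior tree distributions (only point trees are simulated; the posterior
parser is tested on hand-perturbed samples), spherical diffusion (the
simulator is planar by design so parameter recovery is a clean test of the
matching reconstruction model), and biased fossil recovery in space or
time. Passing tests therefore demonstrate internal correctness and
calibration under the model's own assumptions, not robustness to
model violation on real data.

# Numerical choices and problem sizes

Age arithmetic tolerates 1e-6 Ma of tip-date/branch-length inconsistency
(configurable). Rate optimisation brackets `r` in [1e-6, 1e3] on the log
scale. The Metropolis sampler adapts its step every 50 burn-in iterations.
NPRS uses BFGS refined by Nelder–Mead (Brent for a single free node) from
depth-based initial ages. Matrix exponentials use the symmetric
eigendecomposition of `Q`, cached per model. Degenerate inputs — zero-length
branches, identical localities, all-missing columns, antipodal centroid
sets — either take documented fallback paths or fail loudly.

The test-suite problem sizes are chosen so the whole suite runs in about a
minute: exhaustive-enumeration oracles on 1,000 random 5-tip trees, BM
calibration on 300 replicates of 200-tip trees, NJ recovery on 5–8-tip
additive matrices, HDI oracles to n = 500. The calibration experiment
(`bm_root_coverage_68pct`) is the one place a nominal probability is
verified empirically: the true root falls inside the 68% ellipse in a
binomially consistent fraction of replicates.

# Known limitations

* Planar BM on lon/lat is a chart approximation; reconstructions near the
  poles or for clades spanning > 180° of longitude after unwrapping are
  unreliable.
* The homogeneous-rate BM replaces a variable-rates model; rate
  heterogeneity along branches is absorbed into the single REML matrix.
* Ordered Mk assumes symmetric adjacent-state rates; directional dispersal
  is not modelled.
* The expanded second-pass tree treats locality subtrees as real phylogeny;
  their internal node ages are distance-scaled constructions, not estimates
  with credible intervals.
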