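---
title: "Multi-scale chromatin domain inference: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale chromatin domain inference: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the method: the model and its
assumptions, the tunable parameters and their defaults, the numerical
conventions, and the places where the design was genuinely open and a choice
had to be made.  For a worked example see the README; for the formal
contracts see the function documentation.

## 1. From Hi-C counts to a correlation matrix

The preprocessing chain `preprocess_hic()` interprets an intra-chromosomal
Hi-C matrix as a noisy census of pairwise contact events of a Gaussian
polymer network.  Its stages, with the decisions behind them:

* **Masking** (`mask_low_coverage()`): bins with empty rows (unmappable or
  filtered regions) are excluded from every downstream statistic rather than
  imputed.  The mask travels with every object; masked bins reappear as
  `NA`/`.` entries in outputs.
* **Balancing** (`kr_normalize()`): Knight–Ruiz diagonal balancing on the
  valid submatrix, target row sum exactly 1 (tolerance `1e-6`, at most 100
  outer Newton iterations with an inner conjugate-gradient solve).  Balancing
  requires an irreducible contact graph; a disconnected graph raises an error
  suggesting stronger masking, rather than silently balancing components.
* **Contact probabilities** (`contacts_to_probability()`): the balanced
  signal is proportional to a contact probability, with the unknown constant
  fixed by anchoring the mean nearest-neighbour probability at
  `p1bar = 0.9` — close to, but below, certain contact.  Entries pushed above
  1 are clipped; the off-diagonal fraction clipped is recorded and a warning
  is issued above 10%, at which point a smaller `p1bar` is advisable.  The
  self-contact diagonal is ignored (the self-correlation is 1 by
  definition).
* **Stiffness inversion** (`invert_contact_probability()`): the closed-form
  contact probability
  `p(gamma) = erf(sqrt(gamma) r_c) - 2 r_c sqrt(gamma/pi) exp(-gamma r_c^2)`
  is strictly increasing, so each probability determines one stiffness.  The
  inverse is computed by a 4096-knot monotone lookup followed by Newton
  polishing (the derivative has the simple form
  `2 r_c^3 sqrt(gamma) exp(-gamma r_c^2) / sqrt(pi)`), iterated to relative
  machine precision in `gamma`.  Conditioning deteriorates as `p -> 1`:
  beyond `gamma ~ 20` (at `r_c = 1`) a double-precision probability no
  longer determines the stiffness to better than `1e-8` relative, and beyond
  `gamma ~ 37` the forward map rounds to exactly 1.  Clipped probabilities
  are therefore assigned the finite cap `invert(1 - 1e-6)` and flagged,
  keeping the correlation map finite.
* **Correlation** (`gamma_to_correlation()`): with a uniform variance scale
  `sigma_c`, correlations are `1 - 1/(4 sigma_c gamma)`.  `sigma_c` is set
  to the median of `1/(4 gamma)` over valid, unsaturated off-diagonal
  entries — this balances the fractions of positive and negative
  correlations and cancels the arbitrary capture radius `r_c`, so the final
  matrix is `r_c`-invariant (asserted in the tests by running the chain at
  `r_c = 1` and `r_c = 2`).  Off-diagonal values are clamped into
  `[-1, 1 - 1e-6]`: the upper margin keeps the likelihood finite (the energy
  diverges as an intra-domain correlation sum approaches its maximum), and
  values below −1 can only arise from the algebra at tiny stiffness.

## 2. The group model and the penalized objective

Each bin's hidden state mixes a domain-shared standard normal with per-bin
noise; a domain's strength `g >= 0` sets the mixture, giving intra-domain
correlation `g/(1+g)` and zero between domains.  Conventions adopted for the
likelihood algebra, all tested:

* The intra-domain correlation sum `c_k` **includes the diagonal** (each
  member contributes 1), exactly as the double sum is written.  When a
  diagonal band is excluded (compartment inference), banded pairs contribute
  0 to `c_k` — band removal masks evidence, not self-correlation.
* The per-domain likelihood is maximized in closed form at
  `g_hat = (c_k - n_k)/(n_k^2 - c_k)`, **clamped at 0**: negative values
  would mean the model "rewards" anti-correlated groupings, which the
  generative premise (`g >= 0`) forbids.  A domain at the boundary, and any
  singleton, contributes zero energy — the same value as leaving its bins
  ungrouped, so anti-correlated merges are never favoured.
* Natural logarithms throughout; forced for the generalized domain count
  (where `exp` must invert the entropy) and adopted uniformly.
* The energy satisfies `E(s|C) = -log p(C|s, g_hat) - N/2`; the constant is
  pinned by the all-singleton state and the identity is asserted to `1e-9`.

Parsimony is imposed through `H = E + lambda * K(s)` with
`K(s) = exp(entropy of domain-size fractions)` — the *generalized* domain
count, equal to the plain count for equal sizes.  Two consequences matter in
practice.  First, `lambda` is a resolution index, not a biological quantity;
solutions should be read as a family.  Second, because merging two *large*
domains lowers the size entropy the most, large-`lambda` solutions tend to
become heterogeneous — a dominant merged domain absorbing weakly-structured
regions while strongly-correlated small domains persist (visible as the
index of dispersion of domain sizes crossing 1).  This is intrinsic to the
entropy-based penalty, not an annealing artifact: on two-level synthetic
data with a strong fine scale, the coarse level is *never* the optimum at
any `lambda`, while with balanced strengths both scales appear as clean
family members (the two-scale test uses `g = 0.9`, `h = 1` for this
reason).

## 3. Simulated annealing

The partition space is explored by single-site moves: each sweep visits
every valid bin in random order and proposes relabeling it to one of the
other existing domains or to a fresh singleton, uniformly.  Because the
number of available proposals changes when the domain count changes, the
plain Metropolis rule does not leave the target `exp(-H/T)` invariant; the
acceptance probability therefore carries the Metropolis–Hastings factor
`K/K'` (current over proposed domain count).  A four-site test compares
long-run visit frequencies against the exactly enumerated distribution over
all 15 partitions.

Bookkeeping is incremental — a move touches two domains' `(n_k, c_k)` in
`O(n_k)` and the size-entropy sum in `O(1)` — and is asserted to agree with
full recomputation to `1e-9`.  Emptied domains are deleted immediately;
labels are canonicalized (first occurrence order) on return, which is also
the tie-breaking rule: among equal-`H` states the first visited is kept.

The default schedule (`anneal_schedule()`): `T0 = 1`, geometric cooling
`alpha = 0.9` to `T_min = 1e-3`, 20 sweeps per temperature, 5 independent
restarts, each starting from all singletons (unbiased with respect to the
domain count; the penalty then shrinks it).  These defaults were chosen so
that the annealer reproduces exhaustive enumeration on 8-site instances
(all 4140 partitions) at better than 95% over seeds, and they are exposed —
harder energy landscapes may need slower cooling.  `sweep_lambda()` runs
ascending penalties and can warm-start each anneal from the previous
solution as one restart; a test checks warm and cold starts agree on the
final objective within 1%, guarding against warm-start lock-in.  All
randomness (R's RNG, also driving the compiled sampler) is controlled by
explicit seeds; fixed seed and schedule give bit-identical output.

## 4. Secondary (compartment) inference

Compartments coexist with the primary TAD-scale solution as a weaker,
non-local second grouping.  Two routes are implemented
(`infer_compartments()`):

* **Band mode**: anneal on the correlation matrix with pairs closer than
  `band_width` (default 2 Mb — the meta-TAD scale) excluded, leaving only
  the long-range checkerboard evidence.
* **Residual mode**: subtract the fitted primary structure,
  `C_res = (1 + g~) C - g~ [same domain]`, symmetrized by averaging (the raw
  expression is asymmetric when the two sites' strengths differ — an open
  point resolved here by averaging, which preserves the exact cases) and
  clamped; then anneal the residual as an ordinary single-level problem.

The strengths `g~` entering the residual deserve care.  The single-level
maximum-likelihood strength of a primary domain absorbs any correlation
shared through the secondary level: fitted on two-level data it converges
to the *sum* of both contributions, and plugging it into the residual
over-subtracts, leaving clamped near-1 artifacts between same-compartment
domains.  The default is therefore `estimate_primary_strengths()`:
`g~ = (a - b)/(1 - a + b)` with `a` the domain's mean intra-correlation and
`b` its largest mean cross-domain correlation — this equals the ML fit when
no secondary structure exists (`b = 0`) and the primary-only strength under
the two-level model.  Any explicit `g_tilde` can still be supplied,
including 0 (residual mode then reduces to a plain anneal, which is
tested).

The secondary anneal uses a small positive penalty (`lambda = 2` in the
benchmarks): enough to suppress noise-driven fragmentation of the weak
long-range evidence, while staying well below the energy cost of merging
the two compartments (which grows with compartment size).  A/B identities
are assigned by local compactness (`assign_AB()`): of the two largest
domains, the one with the higher mean contact at short range (distances
1–10 bins) is B, ties broken deterministically by label order with a
warning.

## 5. Evaluation statistics: conventions

* **Similarity** `binary_similarity()`: Pearson correlation of co-membership
  matrices over distinct valid pairs; label-permutation invariant; undefined
  (with warning) against a single-domain solution.
* **nMI** `nmi()`: the data matrix is discretized into exactly 100
  equal-width bins over its observed range (the top edge closed); the
  co-membership indicator is binary; the result is base-invariant by
  normalization.
* **Nestedness** `nestedness()`: per-domain best overlap, chance-corrected
  by 100 seeded draws without replacement from the coarse solution.
  Singleton domains (and any domain whose chance level is 1) are perfectly
  nested by chance alone and carry no information; they are dropped and the
  size-weighted score is renormalized over the scored mass, so perfect
  nesting scores exactly 1 and the score's own null is centered at 0 (both
  tested).
* **Domain sizes** `size_stats()`: the index of dispersion
  `D = var(size)/mean(size)` is computed on sizes in Mb by default so that
  the `D ~ 1` crossover refers to the genomic scale; the unit is a switch
  (`units = "bins"`), since the variance-to-mean ratio is not
  unit-invariant.
* **Boundary correlation** `boundary_correlation()`: the boundary indicator
  marks the *first* bin of each maximal run of a label (non-local domains
  contribute one boundary per run; the leftmost valid bin counts).  Whether
  the last bin should also count is genuinely ambiguous; first-bin was
  chosen and the displacement function is computed over both signs of `d`,
  which absorbs the half-bin convention.  The correlation length comes from
  unweighted least squares of `log|chi|` on the positive values at
  `d >= 0`; the mean-subtraction baseline biases this fit when boundaries
  are dense relative to the decay, so the planted-kernel test uses sparse
  boundaries.
* **Compartment–track correlation** `compartment_track_correlation()`:
  signed ±1 indicator vectors projected on the track, normalized by both
  norms; exactly two domains covering all bins give `c_B = -c_A`.

## 6. The synthetic generators, and what passing tests show

`sample_signals()` draws the hidden states of the (optionally two-level)
group model exactly as the model is written — one shared normal per domain
per sample, unit marginal variance — and returns the empirical correlation
of `n` samples, which converges to the model correlation at the Monte-Carlo
rate.  For heterogeneous strengths the exact process correlation uses the
geometric mean of the two sites' normalizations; within any shared group the
strengths coincide and the familiar additive form is recovered.
`synth_hic()` runs the polymer map forward (stiffness from the inverted
correlation relation at a configured `sigma_c`, default 0.25 so that zero
correlation maps to unit stiffness, recorded in the map) and samples
binomial — optionally Poisson — read counts per pair.

The generators realize the *statistical* structure the inference assumes:
block-structured correlations, polymer-consistent count noise, nested
two-level hierarchies.  They do not emulate distance-decay exponents,
loops, translocations, or cell-type mixtures; a passing benchmark therefore
demonstrates correctness of the inference under its own model, not
performance on any particular genome.  Benchmark problem sizes were chosen
as the smallest that leave the regimes of interest well separated: 8 bins
where exhaustive enumeration is the oracle, 100–120 bins for planted
primary/secondary recovery (domains of 10–20 bins, strengths `g = 2`,
`h = 1`, 400 samples), and a 500-bin nested benchmark (5 super-domains,
sub-domains of mean 12 bins with strengths drawn from U(1, 4) so the
coarsening transitions spread across the penalty grid 0–100) for the
monotonicity of mean domain size in `lambda`.

## 7. Degenerate inputs and numerical guards

* Correlation matrices are validated on construction (symmetry `1e-8`, unit
  diagonal, off-diagonal within `[-1, 1]`); the likelihood additionally
  refuses `c_k` within `1e-12` of `n_k^2`, which the clamp prevents.
* `expected_profile()` carries the last finite value forward across
  distances with no valid pair; `oe_pearson()` masks zero-variance rows
  (uniform maps thus come back fully masked with a warning rather than
  producing NaNs).
* An all-masked map, a band covering the whole matrix, a probability of
  exactly 1 handed to the inverter, a single-domain solution handed to the
  boundary statistic — each raises a specific error rather than propagating
  non-finite values.

## 8. Known limitations

* Single-site proposals make the chain ergodic but slow to reorganize large
  blocks; merge/split moves are a natural extension hook.
* The entropy-based penalty's preference for heterogeneous coarse solutions
  (Section 2) means "the" TAD/meta-TAD scale should be read off the family's
  diagnostics, not from a single `lambda`.
* The residual-strength estimator assumes at most one dominant shared
  component per domain pair; deeper hierarchies would need the recursion
  applied level by level.
* Preprocessing assumes the balanced signal is proportional to a contact
  probability; copy-number variation and unbalanced translocations violate
  this and should be masked out beforehand.
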