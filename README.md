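# multicd

Multi-scale chromatin domain inference from Hi-C contact maps.

Chromosomes fold into nested layers of *chromatin domains* (CDs): sub-TADs,
topologically associating domains (TADs), meta-TADs and, at the largest
scale, the non-local A/B compartments that produce the familiar checkerboard
Hi-C pattern.  Most callers target one of these layers with scale-specific
heuristics.  `multicd` instead treats domain calling at every scale as one
statistical problem: a physically motivated transform turns the Hi-C matrix
into a pairwise correlation matrix, and a single penalized likelihood —
with one resolution parameter — is minimized to obtain the domain partition
at each scale.  It is aimed at computational genomicists who want
scale-consistent, model-based domain calls and quantitative comparisons
between them.

## The model

**From contacts to correlations.**  The chromosome is modeled as a Gaussian
polymer network: the distance between segments *i* and *j* follows the
radial density *P*(*r*; γ<sub>ij</sub>) ∝ γ<sub>ij</sub><sup>3/2</sup>
*r*² exp(−γ<sub>ij</sub> *r*²), where γ<sub>ij</sub> is the effective
harmonic stiffness coupling the pair.  After Knight–Ruiz balancing of the
raw counts (rows sum to 1) and anchoring the mean nearest-neighbour contact
probability at p̄₁ = 0.9, each contact probability is inverted through the
closed form

> p<sub>ij</sub> = erf(√γ<sub>ij</sub> r<sub>c</sub>) − 2 r<sub>c</sub>
> √(γ<sub>ij</sub>/π) · exp(−γ<sub>ij</sub> r<sub>c</sub>²)

to a stiffness, and stiffnesses map to correlations via
C<sub>ij</sub> = 1 − 1/(4 σ<sub>c</sub> γ<sub>ij</sub>), with σ<sub>c</sub>
the median of 1/(4γ<sub>ij</sub>).  The capture radius r<sub>c</sub> cancels
exactly: `preprocess_hic()` is invariant to it.

**The group model.**  Each bin *i* carries a hidden genomic state
*x*<sub>i</sub> mixing a domain-shared Gaussian variable (weight set by the
domain strength g<sub>k</sub> ≥ 0) with per-bin noise, so the model
correlation is g<sub>k</sub>/(1+g<sub>k</sub>) inside domain *k* and 0
between domains.  The profiled log-likelihood of a partition **s** gives the
energy

> E(**s**|**C**) = ½ Σ<sub>k</sub> [ log(c<sub>k</sub>/n<sub>k</sub>) +
> (n<sub>k</sub>−1) log((n<sub>k</sub>² − c<sub>k</sub>)/(n<sub>k</sub>² −
> n<sub>k</sub>)) ],

with n<sub>k</sub> the domain size and c<sub>k</sub> the intra-domain
correlation sum.  Parsimony enters through the generalized domain count
K(**s**) = exp(entropy of the domain-size fractions), and the objective

> H<sub>λ</sub>(**s**|**C**) = E(**s**|**C**) + λ·K(**s**)

is minimized by simulated annealing (Metropolis–Hastings over partitions,
geometric cooling, multiple restarts).  Sweeping λ yields the multi-scale
solution family; note that λ indexes resolution only — its numeric value
carries no intrinsic biological meaning.  Compartments are recovered as a
*secondary* partition, by re-running the same inference on the correlation
matrix with a near-diagonal band removed, or on the residual correlation
left after subtracting the fitted primary structure.

## Worked example

Everything below is generated by the package itself — no downloads.

```r
library(multicd)

## plant 4 domains of 10 bins, strength g = 2, and estimate the
## correlation matrix from 300 samples of the group model
truth <- domain_solution(rep(1:4, each = 10))
C <- sample_signals(truth, g = 2, n_samples = 300, seed = 1)$C_hat

fit <- multicd(C, lambda = 0, seed = 1)
fit
#> Multi-scale chromatin domain fit
#>   40 bins (40 valid), 1 lambda value(s)
#>  lambda         H K genK mean_size dispersion nmi
#>       0 -15.84279 4    4        10          0  NA

binary_similarity(domains(fit), truth)
#> [1] 1
round(coef(fit), 2)
#> domain1 domain2 domain3 domain4
#>    2.08    1.99    1.76    2.16
```

The fit recovered the planted partition exactly (similarity ρ = 1: the
Pearson correlation of the two co-membership matrices), with 4 domains of 10
bins and fitted strengths scattered around the true g = 2.  `H` is the
minimized objective; `genK` the generalized domain count.  A raw Hi-C
matrix (sparse triplet or dense text) can be passed straight in:
`multicd(read_contact_map("chr10_50kb.txt", bin_size = 50000), lambda = c(0, 10, 20))`
runs the polymer preprocessing and returns the solution family; coarse
compartment-like structure comes from
`infer_compartments(C, mode = "band", band_width = 2e6)`.

A thin command-line wrapper over these functions is installed at
`system.file("cli", "multicd.R", package = "multicd")` with subcommands
`preprocess`, `infer`, `sweep`, `compartments`, `eval` and `simulate`.

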