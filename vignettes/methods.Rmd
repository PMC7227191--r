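---
title: "Methods: models, estimators and design choices in mitopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in mitopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitopop analyses a single maternally inherited, non-recombining locus —
a mitochondrial amplicon such as *cox1* — sampled across a hierarchy of
trapping sites (subpopulations), localities (populations) and regions or
ecozones (groups).  This note records the models behind each stage, the
tunable parameters and their defaults, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## Input model and site filtering

All statistics operate on an equal-length alignment over `{A,C,G,T}`.
Alignment itself is out of scope: sequences of unequal length are
rejected, not aligned.  `complete_deletion()` removes every column that
contains a gap, `N`, or any IUPAC ambiguity code in *any* sequence.
Ambiguity codes are treated exactly like missing data because a
statistic defined on nucleotide mismatch counts has no principled
partial-match value for them; deleting the site globally keeps every
pairwise comparison over the same site set.  Retained columns are
reported 1-based through the `retained_sites` attribute (internally,
indexing is R's native 1-based).

## Diversity indices

For `n` sequences over `L` post-filter sites with pairwise difference
counts `d_ij`:

* mean pairwise differences `K = 2/(n(n-1)) * sum_{i<j} d_ij`;
* nucleotide diversity `pi = K / L`;
* haplotype diversity `Hd = n/(n-1) * (1 - sum p_i^2)` over haplotype
  relative frequencies `p_i`;
* segregating sites `S` = number of columns with more than one state.

No multiple-hit (Jukes–Cantor) correction is applied: the raw-count
versions are what the comparable desktop tools report for closely
related intraspecific sequences, where multiple hits are rare.  Reports
round to 4 decimals (R's default round-half-even); full-precision
values are always written alongside (`full_precision/`).

## Neutrality tests

Tajima's `D = (K - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
constants from `tajima_constants()`.  `S = 0` yields an `NA` sentinel,
not an error, so per-unit report loops survive monomorphic units.

Fu's `Fs` uses the Ewens sampling formula.  With `theta` estimated by
`K` (the mean pairwise difference — the estimator Arlequin uses, so that
published tables are reproducible),

```
S' = sum_{k = k_obs}^{n} |S(n,k)| theta^k / (theta)_(n),   Fs = ln(S'/(1-S'))
```

`|S(n,k)|` are unsigned Stirling numbers of the first kind, computed by
the row recurrence entirely in log space with `log(exp(a)+exp(b))`
stabilisation; rows are cached and grown on demand.  Log-space doubles
are exact to ~1e-12 relative error for `n` in the hundreds (checked
against exact integers for `n <= 12` and by the normalisation
`sum_k P(K=k) = 1` to 1e-10 for `n <= 100`), so no arbitrary-precision
arithmetic is needed at this locus scale.  The tail is `>= k_obs` (many
haplotypes = small `S'` = negative `Fs`), which is Fu's original
direction; the frequently misquoted "equal or smaller" direction would
flip the sign of every published expansion signal.

Significance comes from a fixed-`S` coalescent null: constant-size
Kingman genealogies with exactly `S` mutations placed on branches with
probability proportional to branch length.  For `D` the default p-value
is the lower-tail `Pr(D_sim <= D_obs)` — the convention of the
simulation-based tools whose published tables these functions reproduce
(a `two.sided` option doubles the smaller tail).  For `Fs` the p-value
is `Pr(Fs_sim <= Fs_obs)`, each replicate's `Fs` computed from its own
haplotype count and `K`.  Default 10,000 replicates, seeded; all
p-values are plain tail proportions (no +1 correction), so `p = 0` can
be printed, matching the desktop tools.

## AMOVA, pairwise Phi-ST and gene flow

AMOVA is distance-based: the pairwise nucleotide difference `d_ij` is
used as a squared Euclidean distance.  Sums of squares come from the
standard identity `SS(group) = sum_{i<j in group} d_ij / n_group`;
variance components use the unequal-size coefficients of the classical
three-level decomposition, and fixation indices are
`F_CT = Va/V`, `F_SC = Vb/(Vb+Vc)`, `F_ST = (Va+Vb)/V`.  Negative
variance components are reported as computed (`pct_raw`) and floored at
zero for the report-style `pct` column, matching how published tables
print them.  The three permutation schemes are the classical ones:
individuals across demes regardless of grouping (`F_ST`), individuals
across demes within their group (`F_SC`), whole demes across groups
(`F_CT`).  Permutation ties count into the tail at tolerance 1e-12.

Pairwise "F_ST" is the two-population Phi-ST from the same machinery
(`method = "haplotype"` switches the distance to the 0/1
different-haplotype indicator for a purely frequency-based variant).
Gene flow converts by the haploid island-model formula
`Nm = (1 - F_ST) / (2 F_ST)`, reported as `NA` when `F_ST <= 0`
(unbounded gene flow).  `apparent_density()` implements the trap-survey
index `FTD = total flies / (traps x days)`.

## Mismatch distributions and the sudden-expansion model

The stationary mismatch law is geometric,
`F_j(theta) = theta^j/(theta+1)^(j+1)`.  Under an instantaneous
expansion from `theta0` to `theta1` at `tau` mutational time units
before present, the expected spectrum is the Poisson-smoothed mixture

```
F_j(tau, theta0, theta1) = F_j(theta1) +
    exp(-tau/theta1) * sum_i Pois(i; tau) [F_{j-i}(theta0) - F_{j-i}(theta1)]
```

which reduces to the `theta0` equilibrium at `tau = 0` and the `theta1`
equilibrium as `tau -> Inf`.  The fit minimises the sum of squared
deviations (SSD) between observed and model spectra, both renormalised
over a common support `0..max(d_obs, ceil(tau)+5)`: a coarse grid
(`tau` up to twice the cap, `theta0 <= theta1`) followed by Nelder–Mead
on a transformed scale that enforces `tau >= 0` and
`0 <= theta0 <= theta1 <= cap`.  `theta1` is capped at 10x the largest
observed difference class because the likelihood surface is flat as
`theta1 -> Inf`; the cap is recorded in the fit.  If the local
optimiser fails to improve on the grid, the best grid point is returned
and flagged.

Harpending's raggedness is `r = sum (x_i - x_{i-1})^2` with a trailing
zero class.  Bootstrap p-values re-simulate coalescent samples under
the fitted `(tau, theta0, theta1)` (present-day `theta = theta1`, size
ratio `theta0/theta1` before `tau/theta1` coalescent time units), refit
each replicate with the same grid and optimiser settings, and report
`Pr(stat_sim >= stat_obs)` separately for SSD and `r` — the two
statistics are deliberately given independent p-values rather than a
joint test, since published tables print them separately.

## Median-joining networks

`build_mjn()` follows the median-joining scheme: compute the minimum
spanning network (all edges that belong to some minimum spanning tree,
with relaxation `epsilon`); enumerate connected triples and their
position-wise majority-consensus medians (three-way ties resolved
toward the first sequence of each rotation, so every pair of a triple
sees a median on its geodesic); admit candidate medians in increasing
connection-cost order, each only if the spanning cost of the grown node
set does not increase; prune median vectors left with fewer than three
links; repeat to stability.  Because admission is sequential and
Hamming distance is a metric, the final network always contains every
minimum spanning tree of the observed haplotypes, possibly with median
vectors subdividing edges at equal total weight — asserted directly in
the tests.  `epsilon` defaults to 0, the common software default; all
sites are weighted equally.  Median labels `mv1..mvk` follow creation
order and carry no meaning; tests compare topology, never labels.
Frequencies and per-population compositions are node attributes in the
GraphML/TSV exports; drawing is left to downstream tools.

## The synthetic-data generator

`simulate_dataset()` implements a haploid structured coalescent: demes
of equal size exchange lineages at per-lineage rate `M/2` (or an
arbitrary deme-by-deme rate matrix), coalescence within a deme at rate
`k(k-1)/2` per `N`-generation time unit, mutations Poisson with mean
`theta/2` per lineage per unit time.  Each mutation takes its own site
(collisions re-drawn), so pairwise differences equal mutation-path
lengths — the infinite-sites behaviour the neutrality tests assume —
while still emitting valid fixed-length FASTA from an all-`A` ancestral
sequence with random alternative alleles.  An optional instantaneous
expansion makes selected demes `factor`-times smaller before
`tau/theta` coalescent units; `merge_time` pools all demes into one
ancestral population (required finite when demes are fully isolated,
since isolated lineages would otherwise never coalesce).  A single seed
makes datasets byte-identical.

`make_study_fixture()` emulates a 3-population x 3-subpopulation
riverine survey with 88/88/87 sequences and a 570 bp locus:
`theta = 0.8` per deme (within-population K of a few differences),
within-population migration `M = 10` (effectively panmictic
subpopulations), between-population migration `M = 2` (expected
pairwise Phi-ST near `1/(1 + 2 Nm d/(d-1)) = 0.1`, spanning roughly
0.05–0.15 across realisations), and a 10-fold expansion in one
population at `tau = 0.4` mutational units.  The expansion age is
deliberately *recent* — 0.5 coalescent units, inside the bulk of the
within-deme coalescent history — because an older instantaneous
expansion (age beyond the typical TMRCA) leaves almost no signature in
`D` or the mismatch spectrum.

What the generator does **not** emulate: recombination (none, as
appropriate for mtDNA), selection, sequencing error, base-composition
or rate heterogeneity, and back-mutation.  Passing tests on this
generator therefore validate the estimators under the neutral
infinite-sites island model — the same model the statistics themselves
assume — not robustness to artefacts of real chromatograms.

## Test problem sizes

The suite exercises: exact brute-force oracle equivalence on 100 random
alignments (`n <= 20`, `L <= 50`); simulator calibration with 2000
single-deme replicates (`n = 20`, `theta = 5`) against the Watterson
and pairwise-difference expectations; null-uniformity of the `D`
p-value via 500 fixed-`S` datasets probability-integral-transformed
against a 1000-replicate null (randomised tie-breaking, since the
fixed-`S` `D` distribution has atoms); expansion-parameter recovery on
exact spectra and rank recovery across simulated expansion ages (15
replicates per age, `n = 40`); and 20-seed comparisons of expanded
versus constant demes.  These sizes give stable Monte-Carlo margins
(3+ standard errors) for every stochastic assertion.

## Known limitations

* Fu's `Fs` p-values are simulation-based only; the beta approximation
  sometimes used for `D` is available as an option but no closed form
  is offered for `Fs`.
* The AMOVA is distance-based (Phi-statistics); a full
  allele-frequency F-statistics variant exists only for the pairwise
  case (`method = "haplotype"`).
* The sudden-expansion model is purely demographic; the spatial
  expansion variant of the mismatch model is not implemented.
* Median-joining networks are exact for the locus sizes used here but
  the triple enumeration is cubic in node count; very large haplotype
  sets (hundreds) would need the reduced-median preprocessing step,
  which is not implemented.
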