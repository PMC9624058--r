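---
title: "Simulating recurrent selection with overlapping or discrete generations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recurrent selection with overlapping or discrete generations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recselsim)
```

## The question

Recurrent selection improves a quantitative trait by cyclically selecting
the best candidates and intermating them. Conventionally generations are
*discrete*: a candidate is evaluated once and is eligible as a parent in
that cycle only. They can instead be allowed to *overlap*, with every
past candidate remaining eligible. Whether overlap helps or hurts depends
on how candidates are evaluated. A phenotype is measured once and frozen,
so a candidate whose phenotype was inflated by error keeps that inflated
score forever; a genomic estimated breeding value (GEBV) is re-computed
from the current prediction model every cycle, so old errors can be
corrected. `recselsim` simulates both policies under phenotypic
selection, genomic truncation selection and genomic optimum contribution
selection (OCS), and measures the mechanism through *selection error
bias*: the ratio of mean absolute criterion error (criterion minus true
breeding value, TBV) in the selected parents to that in all candidates.
Truncation selects from the upper tail, where errors are
disproportionately positive and large, so this ratio exceeds 1 under a
noisy criterion; with frozen phenotypes and overlapping generations the
same erroneously-favoured individuals are selected again and again, and
genetic gain suffers.

## Founder genomes and identity by descent

Founders are outbred diploids with 10 chromosomes of 1000 segregating
biallelic sites (1 Morgan each, uniform site spacing). Haplotypes are
built as Markov mosaics of a 20-haplotype ancestral panel: site
frequencies are drawn from Beta(0.5, 0.5), ancestral alleles are
Bernoulli draws at those frequencies, and each founder haplotype switches
ancestral source at rate 1 per Morgan. This induces realistic linkage
disequilibrium while staying cheap and fully reproducible; any site left
monomorphic is resampled so that every site segregates at generation 0.
The generator emulates the qualitative features a coalescent founder
simulation would give (allele-frequency spectrum skewed toward extreme
frequencies, local LD, exchangeable founders); it does not reproduce a
specific demographic history, mutation model, or the long-range LD decay
profile of any particular species. All of the study's comparisons are
relative contrasts between scenarios sharing the founder process, which
is why a pluggable emulator is adequate.

Meiosis draws a Poisson number of crossovers per chromosome (mean = map
length) with breakpoints uniform on the map and no interference —
standard simulation defaults. Every founder haplotype carries a unique
label per chromosome, and labels are copied through every meiosis, so
coancestry is *computed exactly* from label matching, not estimated:
`ibd_kinship()` returns the probability that random alleles from two
individuals at a random site descend from the same founder haplotype,
and `ibd_inbreeding()` averages it over all pairs of distinct
individuals. Doubled haploids (DH) duplicate a single gamete and are
homozygous at every site by construction.

## Trait architecture

Additive effects for 100 QTL per chromosome are drawn N(0, 1) and scaled
by a single scalar so the *sample variance of TBV across the founders
equals 1 exactly*; the intercept centers the founder mean at 0. A
further 50 sites per chromosome, disjoint from the QTL, form the SNP
chip genotyped every cycle.

The multi-stage pipeline adds year and genotype-by-year (G×Y) effects
under compound symmetry (uniform genetic variances and covariances
across years): one year effect per calendar year, N(0, 0.2), shared by
every trial in that year; and per-QTL year-specific deviations drawn
N(0, σ²ₐ σ²ₐᵧ / σ²_G), with σ²ₐ the variance of the scaled additive
effects, σ²ₐᵧ = 0.2 the target G×Y variance and σ²_G = 1 the base
genetic variance. Because a genotype's G×Y deviations are independent
across years, the genetic covariance of its phenotypes in two years is
σ²_G, as compound symmetry requires. The scaling formula is exact under
linkage equilibrium; with LD the realized founder G×Y variance for a
given effect draw disperses around 0.2 (roughly ±0.03 at these sizes),
which is why calibration checks average over replicate trait draws.

Phenotypes always store their components (TBV, year, G×Y, plot error)
so selection error decomposes exactly. Plot-error variances are
calibrated at the base population and frozen: narrow-sense phenotypes
use σ²_G (1 − h²)/h² divided by the replicate count; stage-level trials
use σ²_G (1 − H²)/H² anchored at the base genetic variance, *excluding*
the year variance (common to all entries of a trial) and the G×Y
variance from the denominator. Whether stage H² should include the G×Y
variance is genuinely open; the alternative
(`h2_denominator = "with_gxy"`) is provided, and the default was chosen
because initial heritabilities are most naturally anchored to the base
genetic variance alone.

## Genomic prediction

RR-BLUP fits y = 1μ + Zm + e with iid marker effects on centered 0/1/2
chip dosages. The variance ratio λ = σ²ₑ/σ²ₘ is estimated by REML: one
eigendecomposition of the marker cross-product turns the restricted
likelihood into a cheap function of λ, maximized by a bounded scalar
search in log λ (tolerance 1e-6). Monomorphic chip columns are dropped
from the solve and given zero effect; a fixed ratio derived from the
known heritability is available as a cheaper mode. The fit equals the
GBLUP solution with the matching relationship matrix, which the test
suite checks against a direct mixed-model-equation oracle to 1e-8.

Training sets are either every phenotyped record to date (`allGen`) or
a rolling window (`fiveGen`) holding the five most recent previous
cycles *plus the current cycle's own records* — the window semantics the
package adopts for the ambiguous boundary case, chosen so candidates are
never predicted from a model that has seen no contemporary data. In the
multi-stage program the training set is all yield-trial records (stages
4–7) from all cycles.

## Selection

Truncation keeps the top n by criterion, ties broken by smallest id.
OCS maximizes c′g over contribution vectors on the simplex subject to
c′Kc ≤ θ, with K the exact IBD coancestry of the candidates,
θ = k̄ + (1 − k̄)ΔF, k̄ the current mean kinship and ΔF = 1/(2Nₑ). The
convex program is solved by an active-set simplex QP nested in a
bisection on the Lagrange multiplier of the kinship constraint
(constraint tolerance 1e-8); among merit-equivalent optima the
minimum-kinship solution is returned, making degenerate ties
deterministic. When even the minimum achievable c′Kc exceeds θ — which
eventually happens in long programs with tight Nₑ as kinship
accumulates — a typed `ocs_infeasible` condition carrying the minimum
achievable value is raised, and the running scenario is truncated and
logged rather than aborted. The number of OCS parents is emergent
(candidates with contribution > 1e-6), not fixed. Contributions are
turned into crosses by sampling distinct parent pairs with probability
proportional to contribution; the mapping from contributions to a fixed
number of crosses is not uniquely determined by the design, and this
sampler is the package's documented choice (expected usage proportional
to c).

Nₑ levels are configured as {10, 45, 90} and exposed as free
configuration rather than hard-coded.

## The two pipelines

**Single-cohort mass selection** (`run_rsa_scenario()`): 100 founders;
first parents selected phenotypically; each cycle makes 100 random
crosses of the 20 parents (one progeny each), phenotypes the cohort,
refreshes GEBVs for the whole eligible pool under genomic selection, and
selects parents under the generation policy. Phenotypic criteria are
frozen at first evaluation; GEBVs are re-predicted every cycle. Genomic
scenarios phenotype every cohort regardless, because the records feed
the training set.

**Multi-stage DH program** (`run_rsay_scenario()`): 30 parents are
crossed into 100 biparental crosses of 97 progeny; DHs are produced the
next year and flow through headrows (H² = 0.1, keep 500), a preliminary
yield trial (H² = 0.2, keep 50), an advanced yield trial (H² = 0.5,
keep 10) and two elite-trial years (H² = 0.8), with a variety picked
from the elite means (recorded, no feedback into selection). Each stage
takes one year. Parents are the top 20 from the current preliminary
yield trial plus the 10 lines advanced out of *last* year's advanced
trial (the current first-year elite entries); overlapping scenarios rank
both groups over all cycles ever evaluated instead of the current one.

Two conventions here deserve justification. First, ages count the
creation year as age 1, and a DH line is created at DH production; under
this convention the discrete steady-state mean parental age is exactly
(20×3 + 10×5)/30 = 3.67, the value the design prints, whereas counting
from the crossing year (3.33) or selecting the same-year advanced-trial
cohort (ages 3 and 4) cannot produce it. Second, selection error bias
is computed over *discretionary* decisions only — groups where fewer are
selected than are eligible. In discrete scenarios that is the stage-4
decision alone, whose candidates all share one trial year, so the
year-component bias is exactly 1, reproducing the design's structural
constant; the stage-5-derived group (all 10 of 10 taken) involves no
choice and would otherwise contaminate the ratio with a second year
effect.

Pipeline fill: years 1–5 bootstrap from a single founder draw. Founders
are phenotyped in year 1 at preliminary-yield-trial precision
(H² = 0.2) and the top 30 become the first parents; parent groups
switch to the pipeline rule as their source stages come online (year 4
for the stage-4 group, year 6 for the stage-5 group), with remaining
slots filled by top founders. Fill years are flagged in the output
(`fill` column) and excluded from steady-state checks and contrasts.
Under genomic selection no yield-trial records exist before year 4, so
parent selection falls back to founder phenotypes during fill.

## Experiments, seeds and statistics

`expand_scenarios()` builds the factor grid with inapplicable
combinations pruned (replication only under phenotypic selection, Nₑ
only under OCS); the multi-stage design has exactly four scenarios.
Every replicate's seed is a deterministic 31-bit hash of (base seed,
scenario id, replicate), so any run is attributable and reruns are
byte-identical. Timepoint contrasts of discrete versus overlapping arms
use Welch's two-sample test on replicate-level values: with one
observation per replicate per scenario, a heteroscedastic two-group
mixed-model contrast reduces to exactly this, which is why the package
uses it in place of a weighted mixed model with post-hoc contrasts.
Structural constants (parental age 1 or 3.67, year bias 1) are tested
with one-sample t tests under explicit Bonferroni family sizes; the
family size is configuration, not inference, because it depends on
which responses a user chooses to interrogate.

## Problem sizes and numerical choices

The package defaults are the full study design (50 cycles × 10
replicates; 40 years with 9700 DH per cohort). The test suite and the
reproduction script run the documented reduced sizes: 20 cycles for the
single-cohort program, and 15 years with 20 crosses × 10 progeny and
60/20/10 advancement for the multi-stage program — the same stage
structure at roughly one-fiftieth the cohort size, which preserves every
structural constant and the direction of the headline contrasts while
keeping a full factorial replicate set affordable on one CPU.
Calibration checks of the G×Y variance average over about eight
replicate founder/trait draws because the single-draw realized value
disperses (see above). Degenerate inputs are handled explicitly:
constant phenotypes give a zero-effect marker model; zero-variance
criteria give NaN accuracy; all-zero errors (TBV selection) give NaN
bias rather than an invented ratio, because the quantity is genuinely
undefined there.

What the simulations do *not* show about real data: there is no
dominance or epistasis, no mutation, no Finlay–Wilkinson-style
regression G×E (compound symmetry was chosen precisely to keep year and
G×Y error components separable), no genotyping error, and the founder
emulator is not a demographic model. Conclusions about the *relative*
behaviour of overlapping versus discrete policies are the intended
scope.

## A worked example

```{r example, eval = FALSE}
library(recselsim)

cfg_disc <- rsa_config(h2 = 0.1, policy = "discrete",
                       criterion = "phenotype", n_cycles = 20)
cfg_over <- rsa_config(h2 = 0.1, policy = "overlapping",
                       criterion = "phenotype", n_cycles = 20)
r_disc <- run_rsa_scenario(cfg_disc, seed = 1)
r_over <- run_rsa_scenario(cfg_over, seed = 1)
tail(r_disc$mean_genetic_value, 1)
tail(r_over$mean_genetic_value, 1)
tail(r_over$selection_error_bias, 1)
```

See the README for a complete worked example with the numbers it
prints, and `scripts/acceptance.R` for the full reproduction of the
calibration and structural constants.
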