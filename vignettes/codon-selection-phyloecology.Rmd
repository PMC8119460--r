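---
title: "Codon-model selection tests and ancestral-diet inference with phylotroph"
author: "phylotroph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model selection tests and ancestral-diet inference with phylotroph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotroph)
```

## What the package does

`phylotroph` implements a molecular-phyloecology workflow: it scans a panel
of digestive system-related genes for positive selection along designated
ancestral branches of a species tree, aggregates the positively selected
genes (PSGs) into per-pathway profiles over the KEGG carbohydrate (CDA,
map04973), protein (PDA, map04974) and fat (FDA, map04975)
digestion-and-absorption pathways, and converts the resulting nutrient
profile into a rule-based call on the ancestor's diet (carnivore vs
herbivore, with fruit and seed/nut refinements from marker genes). A codon
sequence simulator with exactly the model structure assumed by the tests
makes every stage testable without any external data.

## The codon substitution model

The engine works on the 61 sense codons of the standard nuclear code. The
instantaneous rate from codon $i$ to codon $j$ follows the Goldman-Yang
parameterization:

$$q_{ij} = \begin{cases}
0 & \text{more than one position differs} \\
\pi_j \,\kappa^{[\text{transition}]}\, \omega^{[\text{non-synonymous}]} & \text{otherwise,}
\end{cases}$$

with $\kappa$ the transition/transversion rate ratio, $\omega = dN/dS$, and
$\pi_j$ the stationary codon frequencies (F3x4 by default, estimated from
position-specific nucleotide frequencies and renormalized over sense
codons; `equal`, `F1x4` and `empirical` are selectable). The model is
reversible; transition probabilities are computed by eigendecomposition of
the symmetrized generator, which is deterministic for fixed inputs.

**Rate scaling.** All site classes of a mixture share one scale: every
generator is divided by the expected substitution rate of the *neutral*
($\omega = 1$) process at stationarity. Branch lengths are therefore
expected substitutions per codon for a neutral site, conserved classes
evolve proportionally slower and positively selected classes
proportionally faster. This shared scale is what gives the selection tests
their rate-elevation signal; normalizing each class separately would leave
only the composition (non-synonymous vs synonymous) signal and cripples
power. The standalone `codonRateMatrix()` keeps the conventional
one-substitution-per-unit-time scaling for single-process uses.

Likelihoods are computed by Felsenstein pruning over the codon state space
(compiled code, with per-node rescaling against underflow), site patterns
are aggregated, and gap or ambiguous codons are treated as missing data and
marginalized. For the branch-site family with a single foreground branch
the four site classes share two background pruning passes; the tree is
rerooted at the foreground branch's parent and each class only applies its
own transition matrix on that branch.

## The selection tests

* **Branch models.** `fitOneRatio()` shares one $\omega$ across branches;
  `fitTwoRatio()` frees a foreground $\omega$ (optionally pinned to 1).
  Their likelihood ratio, referred to $\chi^2_1$, tests for a shift in
  $\omega$ on the foreground branch.
* **Branch-site model (`fitBranchSite()`, `branchSiteTest()`).** Four site
  classes: conserved ($0 < \omega_0 < 1$) and neutral ($\omega_1 = 1$)
  everywhere, plus classes 2a/2b that take a shared $\omega_2 \ge 1$ on the
  foreground branches only. The alternative frees $\omega_2$; the null pins
  $\omega_2 = 1$; $2\Delta\ell$ is referred to plain $\chi^2_1$. We use the
  plain $\chi^2_1$ reference (not the 50:50 boundary mixture) because the
  published table this package mirrors is reproduced exactly by it; the
  choice is conservative-leaning in the regimes we calibrate.
* **Selection intensity (`fitRelax()`, `relaxTest()`).** The $\omega$
  distribution is a small set of categories (3 by default) shared by all
  branches; on *test* branches each category $\omega$ is raised to the
  exponent $k$. $k > 1$ pushes categories away from neutrality
  (intensified selection), $k < 1$ pulls them toward 1 (relaxed). The
  null pins $k = 1$ (df = 1). Unlabeled branches keep the reference
  distribution untransformed.

**Branch lengths.** The tree's branch lengths are inputs (they typically
come from a baseline fit upstream) and the default fits trust them: our
200-replicate null calibration under the shared neutral scale gives a
type-I error of about 0.03 at $\alpha = 0.05$ with lengths fixed, with
full power retained. Two escape hatches exist for distrusted lengths:
`control = list(freeFgLength = TRUE)` refits the foreground (or test)
branch length as a free multiplier in *both* models of a labeled
comparison (slightly conservative and slower — part of the selection
signal is absorbed into the longer branch), and
`fitOneRatio(..., branchLengths = "optimize")` estimates all lengths
jointly under the one-ratio model for reuse downstream.

**Optimization.** Outer parameters ($\log\kappa$, $\omega_0$,
$\log\omega_2$, optionally the log length multiplier; for intensity fits
the category $\omega$s and $\log k$) are maximized by bounded quasi-Newton
(L-BFGS-B)
with cached forward-difference gradients (step $10^{-6}$) and a relative
log-likelihood tolerance of $10^{-8}$. The mixture *proportions* enter the
likelihood only through the cheap per-site mixing step, so they are
profiled out at every outer evaluation by an EM warmup with a closed-form
M-step followed by damped Newton iterations; the inner solve always starts
from the same fixed point, which keeps the profiled objective a smooth,
deterministic function of the outer parameters (a data-dependent inner
start measurably corrupts the outer finite differences). The alternative
branch-site fit uses three $\omega_2$ starts (1.5, 5, 50) warm-started
from the null fit; the first start gets the full iteration budget and
later starts a capped budget with full polishing only when they beat the
incumbent. Intensity fits start $k$ at 3 and 0.3 ($k = 1$ is not a start:
warm-started from the null it sits exactly at a stationary point).
Negative $2\Delta\ell$ within $10^{-6}$ is clamped to zero. $\omega$
estimates are capped at 999 and $\kappa$ at [0.01, 100]; estimates at a
bound are flagged (`capped` slot), matching the reporting convention of
the published table (entries like 998.99 are cap artifacts, not point
estimates).

**Sites.** `sitePosteriors()` computes naive empirical-Bayes posteriors
(plug-in maximum-likelihood estimates, not full Bayes-empirical-Bayes
integration) for the selected classes 2a + 2b; sites at or above 0.90
posterior are flagged high-support, following the published threshold.
Residue letters come from a configurable reference taxon (default: the
alphabetically first leaf below the foreground branch; the source table
does not state which sequence's residues it reports).

## Multiple testing and PSG inclusion

P-values are Bonferroni-adjusted with a default multiplier of 2,
interpreting the published parenthesized values as correction for the two
foreground branches tested per gene (every row except one is exactly twice
the raw p; the CELA3B row equals its raw p and is annotated, not
"corrected" away). A gene is included as a PSG when its *uncorrected* p
falls below $\alpha = 0.05$ and the foreground $\omega_2$ exceeds 1 — the
published table contains rows whose corrected value exceeds 0.05, so the
uncorrected rule is the one its inclusion actually used.

## From PSGs to a diet call

`aggregateProfile()` counts PSGs per pathway, counting multi-membership
genes (e.g. ATP1B3 in CDA and PDA) in every pathway they belong to, and
ranks pathways by count with ties broken by the smallest per-pathway
p-value. `callDiet()` freezes the narrative mapping from nutrient profiles
to diets into an explicit rule table:

1. all counts zero → **indeterminate**;
2. PDA strictly top-ranked → **carnivore** (protein-dominated intake);
3. CDA and FDA jointly dominant with PDA last → **herbivore**, refined to
   *fruit* if a fructose-transporter marker PSG (SLC2A5) is present and
   *seed/nut* if a plant-sterol marker PSG (ABCG5) is present;
4. anything else → **omnivore-ambiguous**.

Every rule fired is recorded in the call's evidence trail, so the decision
is reproducible and auditable. The rules formalize prose reasoning; they
are deliberately configurable (the marker table is a plain data frame) and
the defaults ship with exactly the two markers above.

The bundled pathway catalog assigns ATP1B3 to CDA and PDA but ATP1B4 to
CDA only. The source material describes both as CDA-and-PDA genes, yet its
printed per-branch counts (bird: 7 CDA / 8 FDA; archosaur: 8 PDA / 6 FDA /
3 CDA) are only mutually consistent if ATP1B4 is not counted in PDA; the
catalog follows the printed counts.

## The simulator and what the tests show

`simulateAlignment()` draws each site's class i.i.d. from the class
proportions (no autocorrelation along the sequence — the simplest
structure consistent with the fitted models), draws the root codon from
the stationary distribution, and evolves it along each branch with the
class- and partition-specific transition matrices. `simulatePanel()` wraps
this into gene panels whose pathway membership and selection placement
mimic an ancestral-diet signature: a carnivore-ancestor scenario places
selected genes predominantly in PDA/FDA, an herbivore-ancestor scenario in
CDA/FDA. Membership counts and per-pathway selected fractions are
allocated exactly (stratified, up to rounding) rather than drawn
binomially — a scenario's defining property is its selection profile, and
multinomial draws would produce panels whose true profile contradicts the
scenario tag in a substantial fraction of runs; only *which* genes carry
the selection is random.

Desk-scale defaults, chosen once and used throughout the test suite: 8
taxa on a balanced unrooted tree with every branch 0.2 neutral
substitutions per codon and one internal foreground branch; 300 codons per
gene; $\kappa = 2$, $\omega_0 = 0.2$, null proportions $p_0 = 0.49$,
$p_1 = 0.21$; panels of 30 genes with equal pathway membership; selected
genes carry $\omega_2 = 8$ at 30% of sites (the published foreground
$\omega$ estimates of 10-999 motivate a strong effect) with per-pathway
selection probabilities of 0.5 in the two favoured pathways and 0.08 in
the disfavoured one. Calibration and power studies use these conditions:
200 null replicates bound the branch-site type-I error in [0.01, 0.09] at
$\alpha = 0.05$; 50 replicates at $\omega_2 = 5$, 20% selected sites and
500 codons establish ≥80% power; 30 replicates at intensity exponent
$k = 3$ establish ≥80% recovery of "intensified"; and 10 seeded
herbivore-ancestor panels must yield ≥8 herbivore calls end to end.

What passing these tests does *not* show about real data: the simulator
matches the fitted model exactly, so the studies certify internal
consistency, calibration and power under the assumed structure — not
robustness to alignment error, indels (not simulated), recombination,
among-site rate autocorrelation, codon-usage mismatch, or tree error. The
published analysis this package mirrors also depends on upstream choices
(orthology, alignment pruning) that are out of scope here.

## Numerical choices and degenerate inputs

* Frequencies are floored at $10^{-9}$ and renormalized so the chain stays
  irreducible under sparse data.
* Alignments with no variable sites give flagged non-informative fits
  rather than arbitrary estimates; a zero-length foreground branch flags
  $\omega$ on that branch as unidentifiable.
* Per-gene failures inside panel scans are recorded in the record's
  `status` and never abort the scan.
* Identical inputs give bit-identical results: optimizer start grids are
  deterministic and all simulation entry points take seeds.

## Known limitations

* Standard nuclear genetic code only; no amino-acid or nucleotide models.
* No among-site rate variation beyond the site-class mixtures; no clade
  models or M-series site models beyond what the branch-site test needs.
* Naive empirical Bayes for site identification (no uncertainty in the
  plug-in estimates).
* The intensity model fixes the category count (default 3) rather than
  selecting it; its last category is constrained to $\omega \ge 1$ so both
  directions of the $k$ transform are identifiable.
* The diet rules are a deliberate formalization of narrative reasoning;
  they are transparent and configurable but not themselves statistically
  calibrated.

## A minimal end-to-end example

```{r example, eval = FALSE}
tr <- simulationTree(8, 0.2, kind = "selection")
panel <- simulatePanel(scenarioSpec("herbivore-ancestor", nGenes = 12),
                       seed = 1)
records <- runGenePanel(panel$alignments, panel$tree,
                        branchName = "ancestral_branch")
profile <- aggregateProfile(records, panel$catalog, "ancestral_branch")
callDiet(profile)
```

The bundled fixtures reproduce the published scan without any fitting:

```{r fixtures}
chk <- checkTable1()
sum(chk$p_match)                      # 34 of 34 rows
fx <- readTable1Fixture()
fx$is_psg <- fx$p < 0.05 & fx$omega2a > 1
bird <- aggregateProfile(fx[fx$branch == "ancestral_bird", ],
                         defaultPathwayCatalog(), "ancestral_bird")
pathwayCounts(bird)
callDiet(bird)
```
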