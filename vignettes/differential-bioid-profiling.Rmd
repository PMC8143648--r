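---
title: "Differential profiling of BioID interactomes from spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential profiling of BioID interactomes from spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bioidr)
library(dplyr)
```

## The problem

A BioID (proximity-dependent biotin identification) screen fuses a
promiscuous biotin ligase to a bait protein, biotinylates the bait's
near-neighbours in living cells, purifies the biotinylated proteins on
streptavidin, and identifies them by mass spectrometry. The primary
quantitative readout per identified protein ("prey") is its spectral
count (SpC) — the number of MS/MS spectra assigned to it — which is a
semi-quantitative abundance proxy. Two statistical problems follow:

1. **Interaction scoring.** Streptavidin purifications are dominated by a
   contaminant background shared with negative-control purifications
   (here, the model is an unrelated transmembrane control bait). Which
   preys are enriched over that background?
2. **Differential profiling.** When the same bait is screened in two
   forms — canonically a wild-type and a disease mutant — which
   interactions are preferentially associated with one form?

`bioidr` implements both stages for the canonical design of triplicate
purifications per condition, plus a generative model of such screens so
that every stage can be validated against planted ground truth.

## Interaction scoring and hit selection

For each prey and each bait condition, scored against the shared control
runs:

* **Mean SpC** over the condition's runs (raw counts by default; the
  bait-normalized variant is available via
  `bioid_config(use_normalized_spc = TRUE)` but raw counts are the
  default because hit selection precedes the differential normalization
  in the standard workflow).
* **FC-A**, the primary fold change in the CRAPome style:
  `mean(bait SpC) / max(mean(control SpC), 0.1)`. The floor (default
  0.1, configurable) keeps the score finite for preys never observed in
  controls; with triplicate controls it equals the score a prey would
  get against a single stray control spectrum, so "absent from controls"
  and "one control spectrum in one run" are not separated by orders of
  magnitude.
* **An interaction probability** from a two-component Poisson mixture,
  in the spirit of SAINT. The background rate is `lambda0 =
  max(mean(control), 0.1)` and the interaction rate `lambda1 =
  mean(bait)`. Each bait replicate `x_j` contributes the posterior
  probability of the interaction component under a 0.5 prior, and the
  reported score is the replicate average — so a prey only approaches 1
  when *every* replicate supports enrichment. When `mean(bait) <=
  lambda0` the score is truncated to 0: sub-background counts are never
  rewarded, mirroring the behaviour of the established scoring tools.
  The model deliberately omits protein-length normalization (lengths are
  not part of the count-table contract) and replicate-specific control
  matching; it is a fully specified, reproducible score, not an attempt
  to reproduce any external tool's numbers.

A prey is a **high-confidence hit** when, within a single bait
condition, mean SpC > 10 AND probability > 0.9 AND FC-A > 7 (all strict;
either condition may supply the passing triple). Requiring the three
criteria to hold in the *same* condition is the conservative reading of
the stringent-selection recipe; a prey scraping the SpC bar in one
condition cannot borrow its fold change from the other.

```{r}
sim <- simulate_bioid(n_prey = 300, seed = 42)
scores <- score_interactions(sim$counts, sim$design)
summarise(scores, hits = sum(is_hit), preys = dplyr::n())
```

## Bait-abundance normalization and the ratio R

Between-run variation in bait expression and purification efficiency
scales all of a run's counts. The correction divides every cell of bait
run *j* by `s_j = (bait self-SpC in run j) / (bait self-SpC in the
reference run)`, where the reference is by convention the first
wild-type run. After normalization the bait's own row is constant across
bait runs — that is the defining invariant, tested exhaustively.
Control runs are passed through untouched; they play no role in the
differential comparison.

For each prey, the normalized counts of the six bait runs get a +1
pseudocount, are log2-transformed, and averaged within condition to give
`L_A` and `L_B`. The differential ratio is

$$R = 2^{\,L_A - L_B},$$

i.e. the geometric-mean fold change of pseudocounted normalized counts.
Significance comes from a two-sample t-test on the same per-run log2
values. The default is the pooled-variance test with
`df = n_A + n_B - 2` (the plain reading of "two-sample t-test" with
triplicates); Welch's test is available via `bioid_config(welch =
TRUE)`. A hit is **A-preferred** when `R > 2` and `p < 0.05`,
**B-preferred** when `R < 0.5` and `p < 0.05`, otherwise **neutral**.
All inequalities are strict, so `R` exactly 2 is neutral.

Numerical edge cases, decided once and tested:

* **Zero variance in both conditions** (frequent with small integer
  counts): `p` is defined as 1 for equal means and 0 otherwise, with a
  warning. The alternative — dropping such preys — would silently
  remove exactly the preys with the most reproducible counts; this rule
  instead lets the `R > 2` effect-size gate decide.
* **Classification scope**: only selected hits are classified by
  default (`classify_all = FALSE`), because the three-way partition is a
  statement about the high-confidence interactome, not about background.
* **No per-prey multiple-testing adjustment** by default: the
  classification gates on raw `p` and the error rate is controlled
  globally by the permutation FDR below. Benjamini-Hochberg adjustment
  is available behind `adjust_p = TRUE`.

```{r}
prof <- suppressWarnings(run_profile(sim$counts, sim$design,
                                     bioid_config(seed = 42)))
glance(prof)
```

```{r, fig.width = 6, fig.height = 5}
autoplot(prof)
```

## Permutation FDR

The false discovery rate of the three-way classification is estimated by
condition-label permutation. The six bait runs admit `C(6,3) = 20`
balanced label reassignments; the observed labelling and its mirror are
excluded (the mirror swaps the two preferred classes and reproduces the
observed discovery *total* exactly, by the reciprocity `R -> 1/R`),
leaving 18 informative permutations. Each permutation reruns the
ratio/t-test/classification over the hit set, and

$$\widehat{FDR} = \frac{\text{mean permuted discovery count}}
                       {\text{observed discovery count}},$$

clipped to [0, 1]. Discoveries pool both preferred classes. If nothing
is discovered under any labelling the estimate is 0; if permutations
discover but the observed labelling does not, the ratio is undefined and
reported as `NA` rather than silently zero. Designs larger than 3+3 with
more than 500 reassignments are Monte-Carlo sampled (seeded). Because
normalization factors depend only on the run, not on its condition
label, the normalized matrix is computed once and shared by all
permutations.

## Gene-set fold enrichment

For downstream interpretation the package provides the classical
over-representation statistic over user-supplied GMT collections: fold
enrichment `FE = (k/n)/(K/N)` with the hypergeometric upper-tail
p-value `P(X >= k)`, where `k` is the overlap between a query (e.g. the
A-preferred hits) and a set of size `K` within a universe of size `N`,
and `n` is the query size. The EASE variant (one success removed before
the tail, more conservative for small overlaps) is available behind a
flag, since published screens often report DAVID/EASE numbers. No
ontology databases are bundled: printed enrichment values from any
specific study depend on database versions and are out of scope.

## The synthetic-data generator

`simulate_bioid()` emulates the study design end to end: triplicates of
two bait conditions plus triplicate controls, a shared contaminant
background, bait-abundance drift, and planted interactor classes.

| parameter | default | rationale |
|---|---|---|
| per-prey background rate | Gamma(shape 6, scale 0.5) | mean 3 SpC with moderate prey-to-prey spread: a typical low-level contaminant band |
| `interactor_boost` | 10 | true interactors average ~30 SpC, comfortably above the SpC > 10 gate for an average prey |
| `effect` | 8 | planted preferred preys satisfy `R = 8`, i.e. four times the classification threshold, split symmetrically in log space so the geometric mean stays at the interactor level |
| `nb_dispersion` | 0.3 | negative-binomial `variance = mu + 0.3 mu^2`, giving the ~50-60% coefficient of variation typical of triplicate spectral counts |
| `frac_A_pref`, `frac_B_pref`, `frac_shared` | 0.05, 0.05, 0.10 | a screen where one prey in five is a genuine interactor and half of those are condition-selective |
| `bait_self_counts` | 100, 80, 120, 90, 110, 70 | ±30% bait-abundance drift, injected multiplicatively into the bait-run means so that the reference-run normalization is exactly the correct inverse transform |

Because the drift enters the generative means multiplicatively, scaling
all bait self-counts by a constant changes nothing downstream — an
end-to-end test of the normalization. Rates below 0.01 are clamped so
evidence-free all-zero preys stay rare.

What the generator does **not** emulate: peptide-level identification
and shared-peptide ambiguity, protein-length bias in spectral counts,
correlated contaminant structure between runs (each cell is drawn
independently given its rate), and compositional effects of very
abundant preys on the counts of others. Passing recovery tests on this
generator therefore demonstrates that the statistical machinery inverts
the generative model it targets — not that any particular biological
screen meets these assumptions.

## Validation scale and reproducibility

The test suite validates the scoring and enrichment statistics against
brute-force oracles (explicit log-odds posterior; exhaustive
hypergeometric tail sums for universes up to 50), the t-test against the
textbook implementation to 1e-12, and the full pipeline on simulations
of 500-1000 preys: a null screen (no planted effect) for FDR
calibration, and a planted screen (5% preferred per condition, 8-fold
effect, dispersion 0.3) for recall and false-discovery proportion. These
sizes make the whole suite run in well under a minute while keeping
Monte-Carlo error small relative to the tested margins; the same
quantities are recomputed from scratch by `scripts/acceptance.R` under a
caller-supplied seed. At dispersion 0.3 with triplicates the pooled
t-test's power against an 8-fold effect is roughly 0.85-0.9, so
recall estimates around 0.8 are expected to fluctuate by a few points
across seeds.

## Known limitations

* Spectral counts are treated as given; no peptide-to-protein inference,
  length normalization or saturation correction.
* The probability model assumes Poisson sampling within the mixture
  components; overdispersed real data make the score conservative for
  preys with one discordant replicate (a prey needs all replicates
  enriched to approach 1).
* The permutation FDR with triplicates rests on 18 permutations: its
  own Monte-Carlo granularity is coarse, which is why the calibration
  test works at the level of discovery counts, not tail probabilities.
* The design is limited to two bait conditions against one shared
  control set; multi-bait panels require one profile per bait pair.
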