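---
title: "Dose–effect weighting of component, target and pathway scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose–effect weighting of component, target and pathway scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oilnet)
```

## The problem and the model

Network-pharmacology pipelines for herbal medicines connect chemical
components to protein targets and enriched pathways, but conventionally
treat every component as equally important. For a transdermally applied
essential oil two measurable properties argue otherwise: a component's
relative content in the oil (its GC–MS peak area percentage, *w*) and its
lipophilicity (log P), which governs partitioning into skin lipids and
hence how much of the applied dose is absorbed at all.

`oilnet` models the absorbed, effect-relevant amount of component *i* as a
product of these two factors. Writing *n* for log P (base 10, the standard
octanol–water convention — the oil/water concentration ratio is
10^*n*), the fraction of the compound residing in the oil phase is

$$f(n) = \frac{10^n}{10^n + 1},$$

interpreted as the transdermal absorption fraction: at *n* = 0 the compound
splits evenly (f = 0.5), and f(*n*) + f(−*n*) = 1 by symmetry. The weight
cascade is then

* **Z** = f(*n*) · *w* per component — the content that is actually
  absorbed;
* **T** = Σ Z over the *distinct* components hitting a target — duplicate
  edges in the input are collapsed first;
* **N** = Σ T over a pathway's member targets — members absent from the
  target table contribute 0, and a target shared by several pathways counts
  in each (no exclusivity).

Enrichment results are re-ranked by N in place of the enrichment p-value,
and docking scores are combined as **S = Z·A/B**, where A is the
component's raw docking score at a target and B the positive-control
drug's score at the same target, so S has the scale of Z and equals Z at
docking parity.

### Assumptions worth keeping in mind

The absorption fraction is an equilibrium partitioning argument, not a
kinetic flux model: it ignores molecular weight, skin hydration and
vehicle effects, and it saturates quickly (f > 0.99 above log P ≈ 2.1).
For typical sesquiterpene oils, where most components sit at log P 4–6,
Z is therefore dominated by content, and the weighting chiefly demotes
highly polar trace constituents. Content *w* is used as the raw "percent
of total" value; an optional `normalize` flag divides by the content sum,
which changes only the scale of every Z/T/N (the cascade is homogeneous of
degree 1 in content) and never a ranking.

## Parameters and defaults

| parameter | unit | default | role |
|---|---|---|---|
| `lfc_threshold` | log fold change | 1.2 | DEG screen, strict `>` |
| `p_threshold` | probability | 0.05 | DEG screen, strict `<` |
| `normalize` | flag | `FALSE` | rescale contents to sum 1 |
| `k` (`rank_shift_report`) | pathways | 5 | size of the head-to-head top lists |

The DEG thresholds use strict inequalities: a gene at exactly
|logFC| = 1.2 or p = 0.05 is *not* significant. The logFC column is taken
as supplied (its base is opaque to the screen), and the p-value column is
whatever the caller passes — unadjusted by default, adjusted if the caller
prefers. Fold-change model fitting itself (e.g. limma) is upstream of this
package, as are target prediction, interaction-network inference,
enrichment testing and the docking engine: all of these enter as exported
tables.

## Deterministic ordering and tie-breaks

Every ranked output is a total order so repeated runs are byte-identical:

* Z/T/N tables sort by descending score, ties by component name / target
  symbol / pathway id ascending.
* `rank_before` sorts by ascending enrichment p, ties by pathway id.
* `rank_after` sorts by descending N, ties by ascending enrichment p, then
  pathway id. Ranking is by N alone — the enrichment p enters only as a
  tie-break. Pathways whose members all lack T scores get N = 0 and sink
  to the bottom rather than being dropped, keeping the rank vector a
  permutation.
* Per-target docking rankings sort by descending S, ties by component name.

Kendall's tau between the two orderings is computed with
`stats::cor(method = "kendall")`; since rank vectors are permutations there
are no ties and the tau variants coincide. The test suite checks it against
an independent O(K²) concordant/discordant pair count.

## Numerical choices and degenerate inputs

* f(n) is evaluated as `plogis(n·ln 10)`, which is exact in the closed-form
  sense and numerically stable for large |n| where `10^n` would overflow.
* Kovats retention indices are only defined between bracketing alkanes:
  peaks outside the ladder span raise an error, never extrapolate. A peak
  exactly at an alkane's retention time gets RI = 100·carbon exactly (the
  bracketing convention assigns that alkane as the lower bracket, except at
  the final ladder entry, where it is the upper one — both choices agree
  analytically). For a ladder with non-consecutive carbon numbers the
  interpolation generalizes to 100·(Z + (Z₁−Z)·frac), which reduces to the
  classical formula on the consecutive C8–C40 ladder.
* Identification tables may print numbers with thousands-separator commas
  (retention indices like "1,467.285"); these are stripped before parsing.
  Duplicate component names are rejected — the content weight would be
  ambiguous.
* Missing docking pairs stay `NA` in the composite matrix. Imputing zero
  would silently demote a component that was simply never docked. B ≤ 0 is
  an error (the ratio is meaningless); negative A passes through with its
  sign, since some docking schemes are lower-is-better — the higher-is-
  better LibDock convention is documented, not enforced.
* Networks reject self-loops and collapse parallel edges; isolated declared
  components are dropped by default (mirroring the convention of hiding
  free proteins in interaction maps) and kept under `keep_isolates = TRUE`.
  Mean degree is defined as 2|E|/|V|, reported as 0 for an empty graph.
* Internal equality tests use a 1e-12 absolute tolerance against
  brute-force reference loops; everything upstream of floating-point
  summation order is exact.

## What the generators emulate — and what they do not

`sim_config()` fixes the synthetic study conditions once: 20 components,
29 key targets and 16 pathways (the scale of a single-herb transdermal
analysis); a 2000-gene expression table with 28 % of genes carrying a
planted |logFC| = 2.0 effect, which at zero noise yields 560 significant
genes under the default screen; component log P drawn from a normal with
mean 4.5 and sd 1.0 truncated to [−2, 8] (sesquiterpene-like
lipophilicity); edge probability 0.15 per component–target pair; and
docking scores whose A/B ratios are log-normal around parity on an
80–120-point control scale. Alkane retention times follow an affine trend
of ≈1.75 min per carbon from 4 min at C8 — the elution window of a routine
40→250 °C temperature-programmed run — plus jitter small enough to keep
the ladder strictly increasing.

Each generator draws from its own substream (a fixed offset added to the
config seed), so outputs are bit-identical across runs and adding one
generator call never perturbs another's draws; the caller's RNG state is
restored afterwards.

Deliberate simplifications: planted DE p-values are assigned directly
(constant 10⁻⁶ for planted genes, Uniform(0,1) for nulls) rather than
derived from a fitted expression model, so recovery tests exercise the
threshold rule only — which is all the screen itself implements. Contents
are a symmetric Dirichlet draw scaled to 95 %, lacking the long-tailed
peak-area structure of real chromatograms; edges are independent
Bernoulli, lacking target-promiscuity correlations; docking ratios carry
no binding-site structure. Passing tests on these inputs therefore
certifies the *arithmetic and contracts* of the pipeline, not the
biological fidelity of any particular dataset.

## The packaged fixtures

`table1_fixture()` returns the 20-component GC–MS identification table of
German chamomile volatile oil (contents and retention indices as printed;
the most abundant component is β-sesquiphellandrene at 18.527 %). No
partition coefficients are published for these components, so the fixture's
`log_p` column is empty; `demo_logp_synthetic.csv` supplies *illustrative,
synthetic* values for demonstrations and is labelled as such — no result
derived from it is a claim about the real oil.

The re-ranking demo (`demo_enrichment.csv` + `demo_tscores.csv`) is a
constructed regression fixture: its T values were chosen so that ranking
by p and ranking by N produce two specific top-5 lists sharing 3 pathways,
with the top pathway stable across both — the qualitative before/after
pattern this method is meant to exhibit. The intermediate tables that
would be needed to reproduce such a pattern from real data (per-component
log P, full target predictions) are not public, hence a constructed
fixture rather than a recovered one.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` compare the cascade against
brute force on 200 random instances of ≤10 components, ≤10 targets and ≤5
pathways; retention-index properties on 10,000 random peaks over random
ladders; DEG recovery over 20 zero-noise seeds (plus a 100-seed noisy run
checked against the closed-form normal exceedance probability Φ(1.6));
Kendall tau on 100 random permutations of up to 20 pathways; and docking
parity on 1,000 random triples. These sizes make every check exhaustive
relative to the arithmetic being verified while keeping the whole suite
in well under a minute.

## Known limitations

The absorption model is the crudest defensible transdermal proxy; it
should be read as a weighting heuristic, not a pharmacokinetic prediction.
T scores count each component once per target with no affinity weighting
(docking enters only in the separate composite S). N scores depend
entirely on the supplied pathway membership lists; whether those lists are
restricted to an intersected key-target set or left genome-wide is the
caller's modelling decision — the package computes over "members present
in the supplied T table", which reproduces either behaviour depending on
input. And the re-ranking changes emphasis, not evidence: a pathway with a
weak enrichment p does not become statistically better supported by a high
N, it is merely predicted to carry more of the absorbed dose.
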