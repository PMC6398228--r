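---
title: "Assessing taxonomic profilers: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing taxonomic profilers: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profassess)
```

This vignette explains the evaluation model behind `profassess`, the
conventions the package commits to where the field leaves room, and what the
synthetic-data generator does and does not emulate. The companion README
shows the surface API; here we document the *why*.

## The evaluation model

A taxonomic profile is, per sample and per rank, a vector of relative
abundances indexed by taxa. `profassess` restricts the rank universe to the
eight major ranks (superkingdom, phylum, class, order, family, genus,
species, strain); rows at other ranks ("no rank", subspecies, ...) are
ignored on input. Internally abundances are fractions in [0, 1]; the CAMI
Bioboxes format carries percentages on the 0–100 scale and is converted on
the way in and out.

**Normalization.** By default every profile — gold standard and predictions
alike — is rescaled per rank so non-empty ranks sum to exactly 1 before any
metric is computed. Without this, a tool that reports only half the sample
would be rewarded on error metrics relative to one that commits to a full
composition. Normalization can be disabled (`normalize = FALSE`) for inputs
already guaranteed to be on a common scale. Ranks whose percentages sum to
more than 100 are rescaled like any others, with a warning: such profiles
are internally inconsistent but common in practice, and silently refusing
them would help no one.

**Presence/absence metrics** (purity, completeness, F1, Jaccard) depend only
on the supports — the sets of taxa with strictly positive abundance — so
they are invariant to abundance rescaling. A taxon listed with abundance
exactly 0 is treated as absent everywhere, including on file input.

**Abundance metrics.** The L1 norm and Bray-Curtis distance are computed
over the *union* of the two supports, with absent taxa contributing their
full counterpart abundance. This convention is forced by the metrics' stated
extremes: two normalized vectors with disjoint supports must attain L1 = 2
and Bray-Curtis = 1.

## The taxonomy tree and EMD UniFrac

Both UniFrac variants are earth-mover's distances on the taxonomy tree built
from the union of the gold and predicted lineages, with a virtual root at
depth 0 and all branch lengths 1 (an edge that jumps over skipped ranks
counts the number of rank levels crossed, so node depth always equals rank
depth).

**Mass placement (weighted variant).** Each node receives the *residual*
abundance at its rank not already explained by its children:
`max(0, own abundance − sum of children's abundances)`. Placing raw
abundances on every node instead would stack ~8 units of mass per profile
and inflate the maximum distance to 72; the residual rule places total mass
exactly 1 per profile and yields the canonical maximum of 16 — twice the
tree height of 8 — attained by two single-lineage profiles in different
superkingdoms. Profiles whose children sum to more than their parent
(possible for inconsistent predictions) are clipped at 0 and rescaled back
to total mass 1, with a warning.

**Depth convention.** With strains at depth 8 the maximum weighted distance
is 16. We anchor every depth-related quantity on this convention; under it
the unweighted distance for a profile facing an empty counterpart is the sum
of the present nodes' depths, bounded by 8 times the total support size.

**Unweighted variant.** Indicator mass 1 per present node; totals may
differ, and the global surplus is created/destroyed at the root, i.e. it
pays for exactly the depth it travels. The same single post-order pass
computes both variants: the flow across each edge is the absolute net
subtree mass below it.

**Empty profiles.** The weighted distance between a distribution and an
entirely empty profile is undefined (there is no mass to compare), and the
package reports NA rather than inventing a value; the ranking layer already
treats NA as worst-in-cell, which is the appropriate penalty. The unweighted
variant remains well defined and is computed.

**Verification.** The tree-traversal distance is checked in the test suite
against an independent oracle that solves the transportation linear program
over node pairs with tree-path costs (`emd_oracle()`, built on
`boot::simplex`), on 200 random gold/perturbation tree pairs of up to 30
nodes, to 1e-9. The traversal is also exercised for symmetry, the triangle
inequality, the [0, 16] range, and exact local linearity (moving a fraction
ε of mass one edge farther adds exactly ε per edge).

## Diversity

Shannon diversity is computed as H = −Σ p ln p in nats over the support
only: profilers rarely enumerate absent taxa, so zero entries are excluded
rather than contributing 0·ln 0 terms. H ranges from 0 to ln S and
equitability E = H/ln S from 0 to 1; for S ≤ 1 the denominator ln S is 0 and
E is reported as NA rather than a conventional constant.

Rarefaction curves operate on presence sets per sample (the only
information a profile carries — there are no read counts to resample) and
average the accumulation curve over random sample orderings; 100
permutations by default, deterministic under the configured seed. Tests
compare against the exact permutation expectation on two-sample cases.

## Ranking

Within one (metric, rank, sample) cell the best tool scores 0, the next 1,
and so on. Two decisions the scoring rule leaves open:

* **Ties** share the better (minimum) score — a tool is never penalized for
  matching another exactly.
* **NA cells** (nothing predicted at a rank, undefined purity, undefined
  weighted UniFrac) receive the worst score in the cell: a tool that
  returned nothing at a rank must not outrank one that tried. All non-NA
  tools beat every NA tool; NA tools tie among themselves.

Per-metric scores are the sums over all (rank, sample) cells; UniFrac is a
whole-tree, per-sample quantity and contributes once per sample (rank
"all"), not once per rank — counting it eight times would silently
quadruple its default weight relative to the per-rank metrics. The overall
score is the weighted sum of per-metric scores with weights in [0, 10]
quantized to steps of 0.1, default 1 for completeness, purity, L1, and
weighted UniFrac. Re-weighting is a cheap re-run (`--metrics-weights`);
the HTML report is static with client-side column sorting only.

A tool that supplies no profile for a gold sample is scored on that sample
as an all-empty prediction (completeness 0, purity NA) rather than being
excluded — scores are sums over samples, so exclusion would reward
non-reporting. By contrast, a tool whose otherwise non-empty output simply
stops above some rank (e.g. no strain calls) gets NA at the unreported
ranks: "did not attempt this rank" and "attempted and found nothing
correct" are different failures, and the tables keep them distinguishable
("na" cells, never 0).

## The synthetic generator

`make_gold()` draws a random nested partition of `n_strains` strains into
taxa at each rank, giving every strain a complete, internally consistent
8-rank lineage, then draws per-sample strain abundances from a
Dirichlet(α) distribution and aggregates them up the tree, so parent
abundances equal the sum of their children and every rank sums to 100%.
The default α = 0.5 produces the uneven, few-dominant-taxa compositions
typical of real microbial communities; α is exposed because evenness tests
want both extremes.

`perturb()` turns a gold sample into a simulated profiler output via four
knobs: per-rank taxon dropout (missed organisms), spurious fresh lineages
(false-positive calls, generated outside the gold taxonomy so they are
unambiguous), multiplicative log-normal abundance noise (quantification
error), and rank truncation (tools that stop at genus or species). The
result is deliberately left un-normalized, like real tool output.

What the generator does *not* emulate: read-level simulation and its biases
(coverage, GC, chimeras), taxonomic mis-annotation (a predicted taxon that
is a *near* relative of a true one — here false positives are maximally
distant), shared mistakes between tools, and real-world taxonomy quirks
(intermediate ranks, unresolved lineages beyond simple rank skipping).
Passing tests therefore demonstrate correctness of the metrics and their
documented responses on clean, consistent profiles — not that any ranking
of real profilers on real data would be reproduced.

## Numerical choices and problem sizes

* Normalized rank vectors must sum to 1 within 1e-9; weighted UniFrac
  demands total-mass agreement within 1e-6 and is compared to the LP oracle
  at 1e-9.
* Round-trip tolerance for written percentages is 1e-6 (files carry six
  decimal places).
* Mean/standard-error cells in per-rank tables use the sample standard
  deviation over non-NA values divided by √n; a single value reports
  standard error 0.
* Overall-score ties are broken alphabetically for display only; the
  scores themselves are reported unmodified.
* The test suite's property checks run at deliberately small scale chosen
  to exercise every code path while keeping the suite quick: monotone
  perturbation-response checks average 20 seeds at 1 sample × 25 strains
  per condition; the oracle sweep uses 200 trees of ≤ 30 nodes; the
  self-assessment identity runs once at 10 samples × 100 strains.

## Known limitations

* No validation of taxids against an external taxonomy dump; lineage
  consistency is enforced only within the input profiles (a taxid with two
  different parents is an error).
* BIOM input maps greengenes-style prefixes (`k__` … `t__`, with `d__`
  accepted for domain) or plain positional lineages onto the eight ranks;
  exotic metadata layouts may need pre-processing.
* The unweighted UniFrac bound depends on the depth convention above;
  numbers computed under a strain-depth-7 convention differ by a factor
  of 8/7 at the extremes.
* Spider plots require at least three profilers, as radar axes with fewer
  spokes are unreadable; the assessment itself has no such limit.
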