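# profassess

Assessment and ranking of taxonomic metagenome profilers against a gold
standard.

Taxonomic profilers summarize a shotgun metagenome as the taxa present in the
community and their relative abundances, rather than assigning individual
reads. Different tools excel at different things: a clinical user hunting a
pathogen cares whether a taxon is *detected at all*, while an ecologist
tracking community dynamics cares whether *relative abundances* are right.
`profassess` takes one gold-standard profile and any number of predicted
profiles (multi-sample, in the CAMI Bioboxes profiling format or BIOM),
computes the field's standard evaluation metrics at each of the eight major
taxonomic ranks (superkingdom, phylum, class, order, family, genus, species,
strain), and ranks the profilers under user-chosen metric weights. It is
aimed at method developers benchmarking a new profiler and at users choosing
one for a particular dataset.

## Metrics

For rank *r*, let *x*<sub>*r*</sub> be the gold-standard relative abundance
vector and *x*<sub>*r*</sub>\* the prediction, both normalized per rank so
that Σ<sub>*i*</sub> (*x*<sub>*r*</sub>)<sub>*i*</sub> = 1 (this avoids bias
towards tools that report only part of the sample). With
supp(*x*<sub>*r*</sub>) = {*i* : (*x*<sub>*r*</sub>)<sub>*i*</sub> > 0}:

* **Presence/absence** — TP/FP/FN of taxon detection per rank;
  purity (precision) *p*<sub>*r*</sub> = TP/(TP+FP), completeness (recall)
  *s*<sub>*r*</sub> = TP/(TP+FN), their harmonic mean F1, and the Jaccard
  index of the two supports.
* **Abundance** — L1 norm Σ<sub>*i*</sub> |(*x*<sub>*r*</sub>)<sub>*i*</sub> −
  (*x*<sub>*r*</sub>\*)<sub>*i*</sub>| (range 0–2) and the Bray-Curtis
  distance (range 0–1; equals L1/2 for normalized vectors).
* **UniFrac** — earth-mover's distance between the two abundance placements
  on the rank-restricted taxonomy tree with unit branch lengths, computed by
  a single post-order tree pass. A node carries the residual abundance not
  explained by its children, so each profile places total mass 1 and the
  weighted distance ranges from 0 to 16 (twice the 8-level tree height). The
  unweighted variant uses presence indicators instead of abundances.
* **Alpha diversity** — richness *S*<sub>*r*</sub> = |supp|, Shannon
  diversity *H*<sub>*r*</sub> = −Σ *p* ln *p* (0 … ln *S*<sub>*r*</sub>) and
  equitability *E*<sub>*r*</sub> = *H*<sub>*r*</sub>/ln *S*<sub>*r*</sub>.
* **Beta diversity** — per tool and rank, Bray-Curtis distances between every
  pair of samples, plotted against the same distances in the gold standard
  (a perfect profiler lies on *y* = *x*).
* **Ranking** — within every (metric, rank, sample) cell the best tool scores
  0, the next 1, and so on (ties share the better score, NA is worst).
  Cell scores are summed per metric and combined with weights (default 1
  each for completeness, purity, L1, weighted UniFrac; any weight 0–10 in
  steps of 0.1). Lower overall score is better.

## Worked example

```r
library(profassess)

gold <- make_gold(n_samples = 3, n_strains = 30, seed = 7)
tools <- list(
  precise  = perturb(gold, perturbation_spec(dropout_rate = 0.3,
                     abundance_noise = 0.2, seed = 11), "precise"),
  complete = perturb(gold, perturbation_spec(spurious_rate = 0.4,
                     abundance_noise = 0.6, seed = 12), "complete"),
  shallow  = perturb(gold, perturbation_spec(rank_truncation = "genus",
                     abundance_noise = 0.3, seed = 13), "shallow")
)
bundle <- run_assessment(gold, tools)
bundle
#> <assessment_bundle>
#>  tools:   precise, complete, shallow
#>  samples: 3
#>  metrics: 882 tidy rows
#> <scoreboard> (lower is better)
#> # A tibble: 3 x 2
#>   tool_label score
#>   <chr>      <dbl>
#> 1 shallow       38
#> 2 complete      71
#> 3 precise       74
```

`precise` misses 30% of the taxa but invents none, so at the species level it
keeps purity 1.0 at completeness 0.69; `complete` finds every gold taxon
(completeness 1.0) but its spurious lineages pull purity down to 0.73;
`shallow` stops at the genus rank, so its species- and strain-level metrics
are NA (worst score in those cells) while it wins most cells at the six
ranks it does report:

```r
library(dplyr)
bundle$metric_table |>
  filter(rank == "species", metric %in% c("completeness", "purity", "l1")) |>
  group_by(tool_label, metric) |>
  summarise(mean = round(mean(value, na.rm = TRUE), 3), .groups = "drop") |>
  tidyr::pivot_wider(names_from = metric, values_from = mean)
#>   tool_label completeness      l1  purity
#> 1 complete          1       0.752   0.726
#> 2 precise           0.691   0.698   1
#> 3 shallow         NaN     NaN     NaN
```

`render_all(bundle, "outdir")` writes the tidy table (`results.tsv`),
per-tool and per-rank tables, all plots as PNG with their numeric series as
TSV, and a self-contained sortable `report.html`.

Command-line wrappers live in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/assess.R", package="profassess"))')" \
  -g gold.profile tool1.profile tool2.profile -o outdir \
  --metrics-weights completeness=1,purity=3,l1=3,unifrac_w=1
```

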