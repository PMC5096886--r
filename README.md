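# hubvuln

Hub vulnerability analysis of wavelet functional-connectivity networks, with
imaging-transcriptomics region mapping.

## What problem this addresses, and for whom

In several neurodegenerative diseases the most highly connected brain
regions ("hubs") appear to lose a disproportionate share of their functional
connectivity, and that selective vulnerability may track the regional
expression of disease-relevant genes (tau / *MAPT*, alpha-synuclein /
*SNCA*). Testing this requires stitching together two very different data
types — resting-state fMRI connectivity graphs and postmortem donor
microarray expression — with a long chain of methodological choices. This
package implements that chain end to end as tested, seeded, reproducible
code, for methodologists who want to study the pipeline's behavior and for
analysts who want a reference implementation: random Voronoi parcellation,
scale-2 MODWT wavelet correlation networks, motion QC, donor-expression
normalization and hemispheric mirroring, sample-to-region matching, and the
full permutation-statistics layer. A first-class synthetic-data generator
emulates the statistical structure of the source data (3 diagnostic groups,
hub-structured band-limited connectivity, expression-coupled attenuation,
6 donors with asymmetric hemisphere coverage) and records its ground truth,
so every estimator can be checked against planted parameters.

## The model in brief

For region time series $x_i(t)$, connectivity is
$z_{ij} = \operatorname{atanh} r_{ij}$ where $r_{ij}$ is the Pearson
correlation of the level-2 MODWT detail coefficients (0.0625–0.125 Hz at
TR = 2 s), unthresholded, negative weights retained. Then:

- **connection strength** (weighted degree): $s_i = \sum_{j \ne i} z_{ij}$
- **hubs**: $\{\, i : s_i > \bar{s} + 1.5\,\mathrm{sd}(s) \,\}$ on the
  control group's mean matrix
- **proportional loss**: $L_i = (s_i^{ctrl} - s_i^{dis}) / s_i^{ctrl}$,
  defined where $s_i^{ctrl} > 0$
- **regional expression**: donor samples normalized within donor (per probe,
  mean 0 / sd 1), mirrored across the midline under a permutation-tested
  symmetry assumption, matched to regions by nearest neighbor, averaged over
  QC-passing probes and donors
- **inference**: permutation tests with $p = (b+1)/(n+1)$, BH-FDR across
  regions, Bonferroni across genes; fluency analyzed as
  `fluency ~ group + hub_strength`

See `vignettes/hub-vulnerability-methods.Rmd` for assumptions, parameter
defaults, and every numerical choice.

## Worked example

```r
library(hubvuln)

scen <- scenario(n_regions = 60, n_subjects_per_group = 10, n_timepoints = 150)
st   <- simulate_study("study", scen, seed = 42, mask_shape = c(16, 16, 12), K = 60)
cfg  <- pipeline_config("study", "out", seed = 42, n_perm = 1000)
res  <- run_pipeline(cfg)
report(res)
```

prints (abridged):

```
== hub vulnerability analysis report ==

Regions retained: 60 (0 excluded by coverage)
Hubs (strength > mean + 1.5 sd = 9.074): 4, 5, 13, 20, 30, 40
Subjects excluded by QC: none

Expression ~ control strength (bonferroni correction, m = 2):
  MAPT [combined over QC-passing probes]: r = 0.210, p = 0.09191, corrected p = 0.1838
    probe MAPT_probe_1: r = 0.213, p = 0.1169
    ...
Control strength ~ proportional loss:
  PD: r = 0.336, p = 0.01299
  PSP: r = 0.422, p = 0.001998
...
Fluency ~ group + hub strength: F = 17.08 (df 1), p = 0.0003306; interaction F = 1.74, p = 0.1971
  post hoc control: r = 0.713, p = 0.02498
  post hoc PD: r = 0.709, p = 0.02597
  post hoc PSP: r = 0.543, p = 0.1089
```

Reading it: the six regions whose control-group strength exceeds the
mean + 1.5 sd threshold (9.074 z units) are the recovered hubs — here
exactly the generator's planted hub set. Control strength predicts
proportional connectivity loss in both disease groups (the planted
selective-vulnerability effect; attenuation ceilings 0.35/0.5 make the PSP
coupling the stronger one), and mean hub strength covaries positively with
verbal fluency across subjects (the planted slope of 5 score units per z
unit). The gene rows show combined and per-probe correlations with control
strength, with Bonferroni correction across the 2 genes; at this small
simulation size the expression effect (planted r = 0.3) does not reach
corrected significance — a calibrated miss, not a bug.

All QC, strengths, loss maps, per-gene tables and provenance (config and
seeds) are written to the output directory (`results.json`, TSV tables).

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/hubvuln.R simulate --out study --regions 60 --subjects 10 --seed 42
Rscript inst/cli/hubvuln.R run --input study --out out --seed 42 --perms 1000
```

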