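# darktaxa

`darktaxa` implements the computational pipeline behind large-scale insect
metabarcoding surveys of "dark taxa" — hyperdiverse families (gall midges,
scuttle flies, parasitoid wasps, ...) whose species are overwhelmingly
undescribed — together with the bibliometric machinery for quantifying how
neglected those families are. It is aimed at molecular ecologists and
biodiversity scientists who go from tagged COI amplicon reads to DNA
barcodes, from barcodes to molecular operational taxonomic units (mOTUs),
from mOTUs to family-level community structure, and from description
records to measures of taxonomic effort.

## What it computes

**Barcodes from reads.** Reads are demultiplexed by exact specimen tag
pairs (both orientations tried; no tag mismatch allowed, up to 2
substitutions tolerated in each degenerate primer under IUPAC matching).
A specimen's barcode is *called* only if the specimen has ≥ 50 assigned
reads and its dominant unique sequence has a read count > 10 that is at
least 5× the second-most-common count. Called barcodes then pass a length
filter (≥ 300 bp for 313 bp amplicons, ≥ 500 bp for 658 bp barcodes) and a
stop-codon screen under the invertebrate mitochondrial genetic code;
traps/samples with < 100 barcodes are dropped.

**mOTUs from barcodes.** Species proxies are delimited by *objective
clustering*: mOTUs are the connected components of the graph joining
sequence pairs with uncorrected p-distance ≤ *t* (single linkage),
conventionally *t* = 0.03 for species and 0.01 for pre-sorting. Distances
use pairwise deletion of gap/ambiguous positions.

**Community structure.** From a trap × family matrix of mOTU proportions
the package computes dominance rankings (mean per-trap proportion),
the variance in composition explained by family identity — the adjusted
R² of `lm(log(proportion + 0.01) ~ family)` — covariance-based PCA with
relative eigenvalues, single-site species turnover, clade-age
correlations, and sister-clade merge re-rankings.

**Taxonomic neglect.** The neglect index for a family is
`NI = N_mOTU / N_sp` (mOTUs detected across the survey over species ever
described). Its drivers are modelled as
`ln(NI) ~ ln(N_mOTU) + mean-of-logs body size` after an interaction
screen; description activity per decade (1980–2019) is related to NI by
correlation and a nested-model ANOVA; author dedication uses fractional
credit `S_i = Σ 1/N_auth_j` with a strict `S_i > 50` threshold; and a
ratio-based global richness estimate is corrected for an under-counted
focal family by dividing each endpoint by
`1 − (p_observed − p_assumed)`.

**Synthetic data.** Seeded generators produce multi-trap communities with
a controllable family profile, per-trap noise, and species turnover;
tagged amplicon reads with substitution errors and per-specimen depth
variation; and description bibliographies with controllable per-decade
intensities — each with a ground-truth table, so that every stage above is
testable end to end without any external download.

## Worked example

A small fully synthetic survey: 4 Malaise traps, 4 families with richness
shares 0.4/0.3/0.2/0.1, error-free reads at 60× depth, clustering at 3%,
and a simulated bibliography for the neglect stage.

```r
library(darktaxa)

cfg <- run_config(out_dir = file.path(tempdir(), "demo"), seed = 11,
  stages = list(simulate = TRUE, reads = TRUE, cluster = TRUE,
                community = TRUE, neglect = TRUE),
  scenario = community_scenario(n_traps = 4, n_families = 4,
    family_profile = c(0.4, 0.3, 0.2, 0.1), richness_mean = 40,
    count_model = "poisson", turnover = 0.9, abundance_shape = 1,
    seed = 1),
  read_spec = read_sim_spec(error_rate = 0, depth_mean = 60,
                            depth_dispersion = Inf),
  biblio = biblio_scenario(n_families = 4, intensity = 15),
  min_barcodes_per_sample = 1, top_n = 4)
report <- run_pipeline(cfg)
report
#> <run_report> stages: simulate, callbarcodes, cluster, community, neglect
#>   adjusted R2 (family model): 0.6314
#>   single-site species fraction: 0.9416
report$stats$top_families
#>   rank   family mean_proportion
#> 1    1 family01      0.34595310
#> 2    2 family02      0.32448889
#> 3    3 family03      0.25392977
#> 4    4 family04      0.07562824
```

All 8,700 simulated reads demultiplex (error rate 0), 145 specimens get a
called barcode, and clustering them at 3% recovers the simulated species:
the dominance ranking reproduces the generating profile order, family
identity explains 63% of the variance in log proportions across traps,
and 94% of species are found in a single trap (the scenario set turnover
to 0.9 of species *drawn* private; shared species that happen to land in
one trap add to the observed fraction). The neglect stage tabulates
per-family NI from the clustered mOTUs and the simulated bibliography:

```r
report$stats$ni_table
#>     family n_motu n_sp        ni
#> 1 family01     50   73 0.6849315
#> 2 family02     42   56 0.7500000
#> 3 family03     34   71 0.4788732
#> 4 family04     11   67 0.1641791
```

Every threshold above (2 bp primer mismatch, 50/10/5× calling rule, 3%
clustering, +0.01 offset, S-threshold 50, ...) is an explicit field of
`run_config()` and echoed to `run_config.json` beside the artifacts.

## Command line

`inst/cli/darktaxa.R` exposes the stages as subcommands:

```sh
Rscript inst/cli/darktaxa.R cluster --fasta barcodes.fasta --threshold 0.03 --out out/
Rscript inst/cli/darktaxa.R callbarcodes --reads reads.fastq --sheet sheet.tsv --amplicon 313 --out out/
Rscript inst/cli/darktaxa.R run --config config.json
```

Exit codes distinguish configuration (2), data (3) and computation (4)
errors.

## Documentation

The methods vignette (`vignettes/darktaxa-methods.Rmd`) describes the
models, the synthetic-data design and its limits, numerical choices, and
known limitations. Function-level documentation lives in the roxygen
comments under `R/`.
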