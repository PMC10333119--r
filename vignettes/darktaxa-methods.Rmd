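---
title: "darktaxa: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{darktaxa: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the scientific and numerical choices inside
`darktaxa`, in the spirit of a methods section: what each stage computes,
which parameters matter and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open.

## 1. From reads to barcodes

Large-scale insect barcoding tags every specimen's PCR product with a
specimen-specific oligo pair so that thousands of specimens can be pooled
on one flow cell. A merged read therefore has the layout

```
fwd_tag + fwd_primer + template + revcomp(rev_primer) + revcomp(rev_tag)
```

in an arbitrary orientation. `demultiplex()` tries both orientations and
assigns a read iff

* both tags match a sheet entry **exactly** (tags are the specimen
  address; a single tag error can silently move a read to another
  specimen, which is why tag mismatches are not tolerated), and
* both primers match with at most 2 substitutions, where IUPAC ambiguity
  codes in the primer (the COI mini-barcode primers are highly
  degenerate, e.g. `GGWACWGGWTGAACWGTWTAYCCYCC`) match any base in their
  set and never count as mismatches.

A read that matches in *both* orientations is ambiguous and left
unassigned; in practice this requires a near-palindromic template and is
vanishingly rare. Assigned reads are trimmed of tags and primers and
tallied into unique sequences per specimen.

`call_barcode()` then applies the dominant-sequence rule: a specimen with
fewer than 50 assigned reads yields no barcode; otherwise the most common
unique sequence is called iff its count exceeds 10 **strictly** and is at
least 5× the runner-up (inclusive). Both readings are deliberate, literal
interpretations of the rule's phrasing ("exceeding 10", "at least five
times"), and a tie for the top count yields no call because no *unique*
dominant sequence exists. These thresholds are arguments, not constants.

Quality filtering drops barcodes below 300 bp (for 313 bp amplicon sets;
500 bp for 658 bp sets) and barcodes whose translation contains a stop
codon under the invertebrate mitochondrial code (translation table 5, in
which only `TAA` and `TAG` are stops — `TGA` is tryptophan and `AGA`/`AGG`
are serine). The reading frame is fixed per dataset because a
primer-anchored amplicon has a fixed frame; the default frame 2 is the
frame of the standard 313 bp COI mini-barcode, and it is configurable
because other amplicons differ. Finally, any trap/sample with fewer than
100 barcodes is removed; this floor is applied *after* barcode calling
and quality filtering, i.e. it counts usable barcodes, not reads.

The ≥ 50-read floor counts **assigned** reads (after demultiplexing):
reads that fail tag or primer matching never reach a specimen's tally.

## 2. Species delimitation

`objective_cluster()` implements distance-threshold clustering: mOTUs are
the connected components of the graph whose edges join pairs at
uncorrected p-distance ≤ *t* (single linkage). This is the only
deterministic, parameter-free reading of threshold-based "objective"
clustering, and it is order-invariant: cluster ids are renumbered by
first appearance, so permuting the input permutes ids but never changes
the partition. Distances are uncorrected p-distances (not
Jukes–Cantor-corrected) because percent thresholds in the barcoding
literature are conventionally uncorrected; positions with a gap or
ambiguous base in either sequence are excluded pairwise, and pairs with
fewer than `min_overlap` (default 100 bp) compared positions are flagged
and never joined directly — a safety net only, since the upstream length
filter guarantees ≥ 300 bp. The pairwise matrix is computed in C++; the
test suite checks it against both a naive R implementation and
`ape::dist.dna(model = "raw", pairwise.deletion = TRUE)`, and checks the
clustering against an O(n³) transitive-closure oracle, the nesting of
partitions across thresholds, and exact recovery of simulated species.

Thresholds: 0.03 is the conventional species-level cut-off, 0.01 the
within-species threshold used when physically sorting specimens by
cluster. Alternative delimiters (ASAP, PTP) are out of scope, so claims
about robustness *across* delimitation methods are outside what this
package can establish.

## 3. Community composition

`build_community_matrix()` forms trap × family proportions of mOTUs (or
specimens), excluding mOTUs not identified to family *before*
normalisation. The dominance ranking is the unweighted mean of per-trap
proportions (ties broken by total mass, then name). For the statistical
analyses, families with ≤ 10 specimens overall or present in a single
sample are excluded — and the surviving proportions are deliberately
**not** re-normalised, so they keep their original denominators.

The headline statistic is the adjusted R² of the one-factor model

```
lm(log(proportion + 0.01) ~ family)
```

An offset is needed because traps lacking a family contribute zero
proportions. The offset is added to **all** values, not only zeros: when
a verbatim model formula (`log(Proportion + 0.01)`) and the surrounding
prose ("adding 0.01 to zero proportions") disagree, the formula is the
reproducible artifact, so the formula wins; the offset is a parameter if
anyone prefers the other reading. Logs are natural throughout.

PCA runs on the centred, unscaled community matrix (scaling would inflate
rare families; the proportions are already on one scale) and reports
relative eigenvalues λᵢ/Σλ. Turnover is the fraction of species present
in exactly one *site*, where sites are coarse units (one per
country/region), not individual traps. Clade-age correlation is a plain
Pearson test; the unit of observation (family × trap pairs vs mOTU-level
records) is left to the caller, since published usage is ambiguous.

## 4. Taxonomic neglect

The neglect index `NI = N_mOTU / N_sp` compares what a standardized
survey detects with what taxonomy has described; NI = 1 means one survey
season detected as many species proxies as two centuries of description.
Drivers are modelled as `ln(NI) ~ ln(N_mOTU) × mean-of-logs body size`,
where body size enters as `(ln(min) + ln(max))/2` of the family's range;
if the interaction is not significant at 0.05 the additive model is
refitted and reported (both fits are returned, plus the decision).

Description activity uses `N_sp10`, species described per family per
decade over 1980–2019. Zero cells receive a +1 offset before logging
(configurable); the decade-interaction test compares
`log(N_sp10) ~ log(NI)` against `log(N_sp10) ~ log(NI) × Decade` by
nested-model ANOVA — with 4 decades and 20 families this is an F test on
(6, 72) degrees of freedom. Author dedication splits each described
species' credit equally across its study's authors
(`S_i = Σ 1/N_auth_j`), and "highly dedicated" means `S_i > 50`
**strictly**: where the formula sentence (`S_i > S_threshold`) and prose
("describing ≥ 50 species") conflict, the formula wins. Credit is
conserved: summed scores equal species described, which the tests assert
to 1e-9.

The richness correction addresses ratio-based global estimates that
extrapolate from a reference fauna in which the focal dark taxon holds
share `p_assumed` of described diversity. If its true share is
`p_observed`, the extrapolation base is missing the gap, and each
endpoint is corrected as `x / (1 − (p_observed − p_assumed))`. This
divisor form was chosen because it is the simplest correction that
reproduces both published endpoints of the motivating example
(5.4/0.827 = 6.53 → 6.5 and 7.2/0.827 = 8.71 → 8.7 million species at
shares 2.7% → 20%); reported values are rounded half-away-from-zero to
one decimal to match how such estimates are printed. The function is
monotone increasing in `p_observed` and degrades to the identity (with a
warning) when the observed share does not exceed the assumed one.

## 5. The synthetic world

The generators are first-class, tested code — the package's substitute
for a 225,000-specimen survey that cannot be rebuilt at desk scale.

**Communities** (`simulate_community()`). Each trap draws per-family
species counts around a shared simplex profile `w` with per-trap
log-normal noise (`profile_noise_sd`), via negative-binomial, Poisson or
deterministic rounding (`count_model`). Defaults state a plausible survey:
a decreasing geometric profile over 10 families (leading share 25%,
matching the observation that a single family can hold ~20% of per-trap
richness), 300 expected species per trap (inside the 69–3,426 per-trap
range of real Malaise surveys), turnover 0.976 (the published single-site
fraction for dominant families), and specimen counts per species
occurrence of `1 + Geometric(0.6)` — no abundance model is published for
these surveys, so any heavy-tailed choice is defensible; the geometric is
the simplest and is configurable. Species are allocated to traps so the
realised fraction of single-trap species tracks `turnover` (shared
species occupy `shared_sites` = 2 traps, filling trap capacities
greedily).

Sequences are built on a 313 bp stop-free template: every species gets
random bases at ~13% signature positions kept ≥ 5% pairwise divergent by
rejection sampling, and each specimen carries at most one private
substitution at a non-signature position, capping intra-species
divergence below 1%. The 1%/5% separation makes the 3% threshold
unambiguous *by construction*: a green recovery test establishes that
clustering, counting and the community statistics are implemented
correctly — it says nothing about threshold sensitivity on real data,
where intra/inter-species divergences overlap. Stop codons are avoided at
every mutation step so the quality filter is exercised as a pass-through
on clean data (dedicated fixtures exercise its rejections).

**Reads** (`simulate_reads()`). Reads follow the tag–primer–template
layout with per-read realisation of degenerate primer positions,
per-specimen depth (negative binomial or fixed), uniform substitution
errors, and random orientation. No indels, chimeras, or quality-score
model (a constant placeholder is written): the demultiplexer is
positional, so indel realism would test nothing it can use.

**Bibliographies** (`simulate_bibliography()`). Species counts per
family × decade are Poisson around the scenario intensities; species are
grouped into geometric-sized studies with author teams drawn from a
per-family pool. This reproduces the structure the scoring functions
consume (shared credit, per-decade binning) but not real-world
complications: author-name synonymy, superfamily reassignments, or
taxa described outside the focal families.

All generators run under an isolated RNG seed (the caller's `.Random.seed`
is restored) and are bitwise reproducible; the pipeline derives per-stage
seeds from one top-level seed.

## 6. Numerical and degenerate-input choices

* Equal top-two read counts → no barcode (no unique dominant sequence).
* `NA` p-distances (overlap < `min_overlap`) never create cluster edges;
  such pairs can still co-cluster through intermediates.
* Distances exactly at the threshold join (`≤`, not `<`).
* `variance_explained_by_taxon()` refuses designs with one observation
  per family (no residual degrees of freedom).
* A constant community matrix yields all-zero relative eigenvalues with a
  warning rather than 0/0.
* `fit_neglect_drivers()` with constant body size drops the degenerate
  predictor and reports the univariate fit; exact collinearity errors.
* Empty traps (or traps whose every mOTU is unidentified) are dropped
  from the community matrix with a warning.
* Pipeline configs are JSON (`jsonlite`), not TOML/YAML — no TOML/YAML
  parser is available in the supported dependency set; the config
  contract (every threshold explicit, seed echoed) is unchanged.

## 7. What a green test establishes — and limits

The acceptance-style tests verify: exact boundary behaviour of the
calling rule; equivalence of the clustering with brute-force connected
components and partition nesting across 1–5%; exact end-to-end recovery
of per-trap richness, profile order, and near-unit adjusted R² on a
noise-free 20-trap scenario; 3-SE coverage of the driver-model
coefficients over 500 replicates and a 3–7% type-I error of the decade
interaction test over 1,000 null replicates. Because the synthetic world
enforces clean divergence separation, perfect tags, and substitution-only
errors, these results validate the *implementation*, not the field
performance of the thresholds. Published dataset-scale statistics (e.g.
two-thirds of compositional variance explained by family) depend on the
full multi-country dataset and external reference tables and are not
reproduced here.

Known limitations: no paired-end merging, nanopore error correction, or
multiple sequence alignment (inputs are assumed ungapped or pre-aligned);
no ASAP/PTP delimitation; exact-only tag matching; no indel/chimera
simulation; author-name disambiguation and family-rank remapping beyond a
user-supplied table are out of scope.
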