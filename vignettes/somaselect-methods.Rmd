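---
title: "somaselect: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somaselect: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaselect)
```

# The model

`somaselect` measures selection on somatic (and germline) substitutions by
contrasting the observed split of substitutions between two effect classes
with the split expected if mutations landed uniformly and persisted
indifferently. The machinery has three layers.

**Site counting.** Every coding position admits three single-base changes.
Each possible change contributes 1/3 of a site to the class of its
amino-acid effect under the standard genetic code: synonymous changes to S,
amino-acid-altering changes (missense and stop-gain) to N. Summed over a
gene, N + S equals the counted coding length — a conservation identity the
test suite asserts for every gene. This is the unweighted Nei–Gojobori
construction: no transition/transversion weighting, no context model. The
functional analogue partitions the *missense* possible changes by a
predictor — a SIFT-like score table (more functional, MF, when score
≤ 0.05, the predictor authors' recommended damaging cutoff; the boundary
value itself is damaging) or a PolyPhen-like class table (MF when possibly
or probably damaging) — giving MF and LF site totals per scheme. Stop-gain
changes are deliberately outside the MF/LF domain: such predictors score
amino-acid substitutions only.

**Substitution counting.** Somatic calls arrive as a minimal MAF-style
table. Within one tumor a substitution is counted once (deduplication);
across tumors every recurrence is counted, because the same somatic change
in two patients arose by two independent mutations. Substitutions are
classified by translating the affected codon; records whose reference base
disagrees with the CDS are rejected and logged, never silently fixed.
Germline variants arrive as a sites-only VCF, are split per alternate
allele, counted once per segregating site, and filtered to allele
frequency strictly above 0.1 by default — common variants have been
exposed to selection long enough to carry its signature, rare ones have
not.

**Ratios and tests.** For a gene group,
`dN/dS = (n/N)/(s/S)` and `dMF/dLF = (mf/MF)/(lf/LF)`. Each ratio is
tested against 1 with a 1-df chi-square comparing the observed
substitution split to the site-composition split. Two groups are compared
with a 2×2 chi-square after dividing one group's numerator count by
`cf = (N_a/S_a)/(N_b/S_b)`, so that a group with proportionally more
non-synonymous *sites* is not mistaken for a group under weaker selection.
When the two compositions match, cf = 1 and the corrected test reduces
exactly to the ordinary 2×2 chi-square (asserted to 1e-9 in the tests).

# The inactivation filter and the treatment of nonsense substitutions

After a truncating (nonsense or frameshift) event inactivates a gene copy
in a tumor, later mutations of that gene in that tumor are presumed free
of selection. The filter therefore removes, per (patient, gene) containing
a truncating event, the *other* records of that pair. Two design choices
deserve explanation because the conventions in the literature are loose:

- **Nonsense substitutions count as non-synonymous.** Stop-gain possible
  changes alter the protein, so they contribute to N; the conservation
  identity N + S = coding length forces this. Counting the substitutions
  but not the sites (or vice versa) would build a systematic bias into the
  estimator: with stop-gains in N but truncating substitutions excluded
  from n, a selection-free cohort would read dN/dS = 392/415 ≈ 0.94 (the
  missense share of non-synonymous changes over the sense codons), not 1.
  Germline classifiers (SnpEff-style) likewise label stop-gains
  non-synonymous, so this keeps the somatic and germline numerators
  comparable.
- **The inactivating record itself is retained** (`drop_trigger = FALSE`,
  the default): the truncating substitution *was* exposed to selection —
  it is the event whose consequence exempts the later ones. Setting
  `drop_trigger = TRUE` removes it too, for sensitivity analysis; the
  headline ratios move by well under the statistical noise either way
  because truncating events are a few percent of records.

With these two choices the estimator is unbiased under neutrality, which
the calibration suite verifies directly.

# Expression breadth and gene groups

Genes are classified by the number of the 16 profiled tissues in which
they are expressed: above 100 units (strict) for intensity platforms, at
least 1 RPKM for RNA-seq. *Globally expressed* means all 16 tissues;
a relaxed mode (14–16) is available for sensitivity analysis and always
yields a superset of the strict global set. The analysis contrasts global
genes with non-global genes, subdivided by expression in the focal tissue
(the tumor's tissue of origin). Breadth histograms use bins
0, 1–3, 4–6, 7–9, 10–12, 13–15, 16; only the extremes (16, and 0–3) are
anchored by the analyses this package reproduces, so interior bin edges
are configurable and the defaults are simply uniform 3-wide bins.

# The synthetic-data generator

The generator emulates the statistical structure the estimators assume,
not tumor biology:

- **Gene models**: ATG followed by stop-free codons with bases drawn at
  GC = 0.52 (typical human coding GC), lengths uniform over multiples of 3
  in 300–1500 nt; one gene in ten gets a shorter second transcript to
  exercise longest-transcript selection. Census and essentiality flags are
  Bernoulli at 2.5% (the census share of screened human genes) and 20%.
- **Mutation and selection**: raw mutations are uniform over coding
  positions with the three alternates equally likely — matching the
  unweighted site counting — at 30 expected mutations per patient per Mb
  of CDS. Real exomes run nearer 2/Mb, but a 200-gene desk-scale cohort
  (~0.18 Mb) needs the higher rate to yield totals (~1,600 substitutions
  per cohort) from which ratios are statistically meaningful; the rate was
  fixed a priori and scales counts, not ratios. Selection is acceptance
  sampling: synonymous changes always retained, non-synonymous retained
  with probability `nonsyn_retention` (1 = neutral), more-functional
  missense changes boosted by `mf_boost` (product clipped at 1 with a
  warning). This reproduces exactly the quantities the estimators target:
  pooled dN/dS recovers `nonsyn_retention`, dMF/dLF recovers `mf_boost`.
  Planted nonsense/frameshift events and within-patient duplicates
  exercise the filters.
- **Germline panels**: segregating sites thinned by strong purifying
  selection (retention 0.2, chosen because common human polymorphism shows
  germline dN/dS ≈ 0.2), allele frequencies Beta(0.25, 2) — a
  rare-dominated spectrum.
- **Expression**: global genes (fraction 0.4, the background global-
  expression rate among profiled human genes) exceed the RPKM threshold in
  all 16 tissues; the rest draw breadth uniformly from 0–13 — leaving a
  margin below the strict cutoff so globality is unambiguous — and include
  the focal tissue with probability 0.5.

Everything is reproducible from a single integer seed; each generator
reseeds from `seed` plus a fixed offset, so the somatic cohort does not
change when, say, only the germline panel is regenerated.

**What a green calibration does not establish.** The generator has no
clonal structure, no mutational signatures or trinucleotide context, no
copy-number events, no transcript-annotation ambiguity, and selection acts
per mutation rather than per cell lineage. Green calibration tests show
the estimators recover the parameters of *this* stated world; they do not
validate the biological assumptions (e.g. that synonymous sites are
neutral) on real cohorts.

# Numerical and procedural choices

- Chi-square tests are two-sided, 1 df, without Yates continuity
  correction by default (cohort-scale counts make it irrelevant;
  `correct = TRUE` is available). A test is *refused* — NA statistics,
  never a fabricated p — when an expected count falls below 5. Degenerate
  2×2 margins (e.g. annotation = universe) return p = 1.
- The per-gene screen includes genes with at least one synonymous
  substitution, flags raw p < 0.05 with ratio > 1, reports a stricter
  p < 0.001 tier, and emits Benjamini–Hochberg q-values as an auxiliary
  column only — the flag reproduces the raw-p convention of the analyses
  this package follows. Because refused genes carry NA p, the screen's
  false-flag calibration (≈ α/2 under neutrality: two-sided test plus the
  direction constraint) is evaluated over genes whose test ran.
- Ratios with a zero denominator count are reported as flagged undefined
  values (`NA` + `undefined = TRUE`), never as infinities; zero site
  totals are an error for single-group statistics and propagate as NA
  rows with a logged reason inside the pipeline.
- Ties in longest-transcript selection break to the lexicographically
  smallest transcript id, making the gene set reproducible.
- Codons containing ambiguity codes are skipped whole and logged
  (a partial codon cannot be enumerated); an internal stop codon fails
  validation outright, while a terminal stop codon is silently excluded
  from counting.
- External CDS coordinates are 1-based; protein position is
  `ceiling(cds_pos / 3)`.

# Known limitations

- Unweighted site counting ignores transition/transversion bias and
  context-dependent mutation; on real cohorts this biases dN/dS for both
  the somatic and germline arms (largely cancelling in comparisons, but
  not exactly).
- The cf correction rescales one numerator count and then applies a
  standard 2×2 chi-square to a non-integer table; this is the intended
  published procedure, but the corrected count is no longer a multinomial
  observation, so the test is approximate.
- Functionality tables are taken at face value; predictor biases
  (reference-allele bias, shallow-conservation bias) pass straight
  through. Unscored missense changes drop out of both numerator and
  denominator, which is unbiased only if scoring coverage is unrelated to
  functional class.
- The pipeline analyzes one transcript per gene; splice-aware coordinate
  mapping and multi-transcript counting are out of scope.
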