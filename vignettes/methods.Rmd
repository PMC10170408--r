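---
title: "Models and methods behind tcrconverge"
author: "tcrconverge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrconverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrconverge)
```

# Scope

`tcrconverge` analyses bulk TCR-beta repertoire sequencing of solid-tumour
samples at the rearrangement-file level: T-cell quantification, clonality
through Hill evenness profiles, sequence-convergence networks at Levenshtein
distance 1, public/private clonotype stratification, and Morisita-Horn
repertoire overlap. It starts from immunoSEQ-style tab-separated exports;
raw-read processing, V(D)J annotation, and germline alignment are upstream
of the package and out of scope.

# Data model

A **clonotype** is the set of T cells sharing one CDR3-beta amino-acid
sequence; because the amino-acid string determines its own length, the
sequence alone is the clonotype key, and nucleotide rearrangements that
translate to the same peptide are merged on reading. Abundance is counted
in **templates** — rearranged DNA molecules, each a proxy for one T cell.
Nonproductive rearrangements (out-of-frame, stop codons, or any character
outside the 20-letter alphabet) are retained in storage but excluded from
every analysis by default, since all reported quantities concern productive
templates.

# T-cell fraction and coverage

With input DNA mass $m$ (ng) and 6.6 pg of DNA per diploid genome, the
number of nucleated-cell equivalents is $G = 1000\,m / 6.6$ and the T-cell
fraction is $T/G$ for total productive templates $T$. Values above 1 are
arithmetically possible with inconsistent inputs and produce a warning, not
an error.

Sequencing **coverage** is defined here as total reads divided by total
templates — the standard depth notion for template-barcoded multiplex PCR —
because the upstream assay does not export a coverage field. Samples under
a configurable threshold (default 5 reads/template) are excluded from all
analyses beyond quantification, with every exclusion reported. When a
patient contributes replicates, fraction comparisons use one dataset per
patient, chosen as the replicate with the highest coverage (a deterministic,
QC-aligned rule; the choice is config-exposed because no canonical rule
exists).

# Hill diversity, evenness, and the clonality index

For clone frequencies $p_i$ the Hill diversity of order $q$ is

$$^qD = \Big(\sum_i p_i^q\Big)^{1/(1-q)}, \qquad
  ^1D = \exp\Big(-\sum_i p_i \log p_i\Big),$$

evaluated on the default grid $q = 0, 0.2, \dots, 10$ (51 points). $^0D$ is
the observed richness $SR$, $^1D$ the exponential Shannon entropy, $^2D$
the inverse Simpson index; orders within $10^{-12}$ of 1 use the Shannon
limit. The **evenness profile** $E(q) = {}^qD/SR$ removes the dependence on
sampling depth, and the **clonality index** is

$$\mathrm{clonality} = 10 - \int_0^{10} E(q)\, dq,$$

integrated by composite Simpson's rule on the grid (the grid's 50 equal
intervals make Simpson exact for cubics; a trapezoid option exists for
sensitivity checks). The index lives in $[0, 10)$: 0 for a perfectly even
repertoire, larger for oligoclonal ones. Frequencies are template
proportions; no rarefaction is applied, because evenness normalization is
the comparison surface. One degenerate corner is documented rather than
patched: a strictly monoclonal repertoire ($SR = 1$) has $E \equiv 1$ and
clonality 0, indistinguishable from a perfectly even repertoire; the
profile constructor warns when $SR < 2$.

# LD = 1 convergence networks

Within one repertoire, nodes are the unique CDR3 sequences and undirected
edges join pairs at Levenshtein distance exactly 1. Edges are found without
the $O(n^2)$ distance matrix: substitution pairs by hashing each sequence
once per position with that position masked (two distinct equal-length
sequences share a masked key iff they differ at exactly that position), and
single-indel pairs by hashing the deletion variants of the longer length
class against the shorter one. The package's test suite proves this fast
path identical to the all-pairs dynamic-programming oracle on randomized
cohorts, including adversarial low-alphabet inputs. The **connectivity
fraction** is edges/nodes, with isolated nodes kept in the denominator.

## Power-law goodness of fit

Degree distributions are tested against a discrete power law
$p(x) \propto x^{-\alpha}$, $x \ge x_{min}$, normalized by the Hurwitz
zeta function. $x_{min}$ is chosen by Kolmogorov-Smirnov minimization over
candidate cutoffs, $\alpha$ by maximum likelihood above the cutoff, and the
goodness-of-fit p-value comes from a semiparametric bootstrap: each
replicate draws the tail from the fitted model and the body from the
empirical data below $x_{min}$, is refitted from scratch, and the p-value
is the fraction of replicates whose KS distance reaches the observed one.
A fit with $p > 0.1$ counts as a plausible power law. Numerical choices:
degree-0 nodes are excluded from the fit sample (the discrete power law has
support on $x \ge 1$) but still count as network nodes; candidate cutoffs
must leave at least 10 tail observations and 2 distinct values, and at most
80 candidates are scanned (rank-uniform thinning) to bound refit cost; the
default bootstrap size is 1000, with 200 used in tests and 100 in the
per-sample pipeline stage for speed — p-value resolution degrades
accordingly. The exact sampler inverts the tabulated discrete CDF out to
the $1 - 10^{-8}$ quantile and falls back to the standard continuous
approximation beyond it.

# Public and private clones

The **sharing level** of a clone is the number of distinct patients in
whom it is detected — replicate aliquots and multiple lesions of one
patient count once — and a clone is **public** when that number exceeds 1.
To compare convergence between classes despite the numerical dominance of
private clones, each repertoire's public and private clones are subsampled
to 1000 each (whole class with a flag when smaller), and class-internal
LD = 1 networks are built; subsampling seeds derive deterministically from
a master seed plus the sample id. Pathology-database matching defines two
top-decile sets per repertoire — the union of the top 10% by degree and
top 10% by sharing level, versus the top 10% by template count — and
counts exact-sequence (LD = 0) hits; decile ranks break ties
lexicographically so the sets are reproducible.

# Morisita-Horn overlap

For template counts $x, y$ on the union clone axis with totals $X, Y$:

$$MH = \frac{2\sum_i x_i y_i}
  {\big(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2\big)\, X\, Y},$$

0 for disjoint supports, 1 for proportional frequencies, invariant under
rescaling of either vector. The whole matrix is computed as one sparse
cross-product of the frequency matrix. Pairs are labelled
`within_lesion_replicate`, `within_patient_between_lesion`, or
`between_patient` from the manifest; by default overlap summaries use the
QC-retained cohort (the alternative — overlap before exclusion — is a flag
away, since the order is a genuinely open choice).

# Cohort statistics

Group contrasts use the two-sided Welch $t$-test and $t$-based 95%
confidence intervals, implemented from the closed forms and cross-checked
against `stats::t.test` in the test suite; regressions are ordinary least
squares via `stats::lm` with coefficient CIs. Significance is read at 0.05
without multiplicity correction — a reporting convention, not a code path.
On real cohorts the connectivity-fraction-versus-size relation is reported
through the linear fit plus residual diagnostics; the package deliberately
does not adjudicate between linear and exponential growth descriptions.

# The synthetic cohort generator

The generator exists so that every pipeline stage can be validated against
planted ground truth without patient data. Its defaults are the emulated
study conditions and are not tuning knobs:

* **Design**: 35 / 35 / 15 patients in no-NACT, short-interval and
  long-interval groups; 3 patients contribute a second aliquot of the same
  lesion and 4 a second lesion; one rearrangement TSV per sample plus a
  manifest.
* **T-cell fractions**: log-normal per group with means 6.3%, 10.6%, 6.2%
  (log-scale SD 0.4, matching the reported group CI widths); the input DNA
  mass is set by inverting the fraction formula, so quantification is exact
  on synthetic data and per-sample truth is recovered identically.
* **Abundance**: clone template counts are i.i.d. discrete power-law draws
  with a per-group exponent — the single evenness knob — above a lower
  cutoff of 5 templates. The cutoff keeps template depth realistic
  (about 7 templates per clone, roughly 67,000 templates per sample at the
  configured richness) and makes aliquot replicates reproducible at the
  observed level; with cutoff 1 the clonality-calibrated exponents would
  force singleton-dominated repertoires whose replicate overlap is far
  below what technical replicates show. Exponents 4.53 / 4.08 / 4.14 were
  calibrated once, by simulation at the configured richness range, to mean
  clonality of about 5.0 (no-NACT) and 5.8 / 5.7 (NACT groups).
* **Richness**: uniform 1,500-20,000 unique clones per sample.
* **Public pool**: 20,000 motif clusters of 5 sequences (a seed plus four
  single-substitution interior mutants, so seed-mutant distance is exactly
  1); each sample draws 22% of its clones from the pool, entering clusters
  in random order and taking each member with probability 0.5. These three
  numbers jointly set the public share of cohort clones (about 7%, inside
  the intended 5-10% band) and the public-class subsampled connectivity
  (about 0.19 versus about 0.002 for private clones).
* **Reads**: per-sample reads-per-template is log-normal with median 9
  (log-scale SD 0.45), so that roughly 9% of samples fall below coverage 5
  and exercise the QC gate the way the emulated cohort did.
* **CDR3 sequences**: lengths normal(15, 2) truncated to 8-25, first
  residue C, last F, uniform interior. Private clones are independent
  random sequences.

What the generator does **not** emulate: V(D)J recombination biases and
generation probabilities (real public clones arise from convergent
recombination, not from a literal shared pool), nucleotide-level
clonotypes, V/J gene usage structure, sampling depth varying with richness,
and the long upper tail of real richness (up to ~67,000 clones). Passing
the pipeline's recovery tests therefore demonstrates correctness of the
statistical machinery under the planted model, not biological fidelity of
any particular number.

# Problem sizes and determinism

The test suite validates operations at cohort scale (the full 85-patient
default cohort, plus 20 regenerated cohorts for the group-contrast power
check) and uses scaled-down cohorts of 10 patients with richness 300-700
for unit tests of plumbing. The acceptance script runs the complete
pipeline once on the default cohort with 1000-clone class subsamples and
100 bootstrap replicates per degree distribution. All randomness flows
from explicit seeds: identical configuration and seed reproduce
byte-identical cohort files and summary tables.

# Known limitations

* The coverage definition and the replicate-selection rule are plausible
  conventions, config-exposed, not vendor specifications.
* The bootstrap GOF p-value has resolution $1/n_{boot}$; at the pipeline
  default of 100 replicates, p-values near the 0.1 plausibility threshold
  are coarse.
* Clonality of monoclonal repertoires is 0 by construction (see above).
* Between-patient overlap in synthetic cohorts (~0.003) sits slightly above
  the near-zero level seen between real patients because pool clones are
  drawn independently per sample; the ordering of the three comparison
  classes is preserved.
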