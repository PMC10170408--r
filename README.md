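# tcrconverge

Clonality and sequence-convergence analysis of bulk TCR-beta repertoires
from solid-tumour samples, for immunologists and bioinformaticians working
with immunoSEQ-style rearrangement exports — for example, comparing T-cell
infiltration and clonal expansion between chemotherapy-exposed and
unexposed tumour cohorts.

The package covers five analysis surfaces:

* **Quantification** — the T-cell fraction of a sample is
  `templates / genomes`, where one rearranged DNA template proxies one
  T cell and `genomes = input DNA (pg) / 6.6 pg`; samples under a
  reads-per-template coverage threshold (default 5) are excluded from
  downstream analyses.
* **Clonality** — Hill diversity `D(q) = (Σ pᵢ^q)^(1/(1−q))` on
  `q = 0 … 10` (step 0.2), evenness `E(q) = D(q)/D(0)`, and a clonality
  index `10 − AUC(E)` (composite Simpson), in `[0, 10)`, higher = more
  oligoclonal.
* **Convergence networks** — nodes are unique CDR3 amino-acid sequences,
  edges join pairs at Levenshtein distance 1 (found by masked-position and
  deletion-variant hashing, proven equal to the all-pairs DP distance);
  degree distributions are tested against a discrete power law with
  KS-optimal `xmin`, maximum-likelihood `α`, and a semiparametric
  bootstrap goodness-of-fit p-value.
* **Public/private structure** — a clone's sharing level is the number of
  patients carrying it (public = more than one); class-wise connectivity
  is compared on 1000-clone subsamples, and top-decile clone sets are
  matched against a pathology-associated TCR database at exact identity.
* **Overlap** — pairwise Morisita-Horn index
  `MH = 2Σxᵢyᵢ / [(Σxᵢ²/X² + Σyᵢ²/Y²)·X·Y]`, stratified into
  between-patient, within-patient/between-lesion, and aliquot-replicate
  comparisons.

A synthetic cohort generator (`cohort_config()`, `generate_cohort()`)
emulates a three-arm neoadjuvant-chemotherapy cohort — group-specific
T-cell fractions and clonality, a planted public clone pool organised in
LD = 1 motif clusters, replicate aliquots and second lesions — with full
ground truth, so every stage is testable without patient data.

## Worked example

```r
library(tcrconverge)

tsv <- system.file("extdata", "example_rearrangements.tsv",
                   package = "tcrconverge")
rep <- read_rearrangement_file(tsv, sample_id = "example")
rep
#> TCR repertoire 'example' (patient NA, group NA)
#>   40 clonotypes, 255 templates, 2236 reads

t_cell_fraction(rep$total_templates, input_dna_ng = 660)
#> [1] 0.00255
sequencing_coverage(rep$total_reads, rep$total_templates)
#> [1] 8.768627

prof <- diversity_profile(rep$records$templates)
prof
#> TCR diversity profile
#>   richness (D at q=0): 40
#>   q grid: [0, 10] in 51 points
#>   clonality index (10 - AUC of evenness): 3.623
```

The clonality index of 3.62 marks a fairly even repertoire: its evenness
curve keeps about 65% of its area, i.e. effective clone numbers stay high
across diversity orders. A network over the same clonotypes:

```r
net <- build_ld1_network(rep$records$cdr3_aa)
net
#> LD=1 convergence network: 40 nodes, 0 edges (connectivity fraction 0.0000)
```

Forty random-length CDR3s share no single-edit neighbours — convergence
only appears when related sequences are present, as in the synthetic
cohorts:

```r
sim <- generate_cohort(cohort_config(seed = 1))
cohort <- build_cohort_table(sim$repertoires)
res <- run_repertoire_pipeline(cohort, out_dir = "report", n_boot = 100,
                               seed = 1)
res$sharing_summary$pct_public     # share of cohort clones seen in >1 patient
res$mhi_class_summary              # overlap by comparison class
```

`run_repertoire_pipeline()` writes the full report bundle (quantification,
exclusions, clonality and diversity profiles, network summaries,
power-law fits, degree-versus-sharing, class connectivity, MHI matrices,
group tests, regressions) as CSVs under `out_dir`.

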