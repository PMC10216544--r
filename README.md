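# cdr3profiler

`cdr3profiler` characterizes T-cell receptor β-chain CDR3 immune
repertoires from rearrangement tables, the kind of per-clonotype export
produced by bias-controlled immune sequencing assays. It was built for
small clinical cohorts — e.g. lung edema fluid from ARDS (acute
respiratory distress syndrome) patients versus non-ARDS lung-injury
controls — where each sample yields tens to thousands of unique CDR3
junctions and the questions are: how clonal is each sample, what do the
CDR3 peptides look like biochemically, how immunogenic are they
predicted to be, and which clonotypes are shared between patients.

## What it computes

Starting from a table with one row per unique CDR3 nucleotide sequence
(template count, frame call, sample label; immunoSEQ-style or AIRR
Rearrangement column names):

* **Translation & productivity** — standard-genetic-code translation of
  the junction read from the conserved V-gene cysteine codon; a
  rearrangement is *productive* iff it is in frame and stop-free.
  Junction anchors (C…F/W) are flagged but do not affect productivity.
* **Length distributions** — per-sample sum productive frequency by CDR3
  length (nt or aa scale) and population-moment summaries (mean,
  variance, skewness, excess kurtosis).
* **Simpson clonality** — with clone frequencies
  `p_i = templates_i / Σ templates` over productive clones, Simpson's
  index is `Σ p_i²` and clonality is `√(Σ p_i²)`: ~0 for an even sample,
  1 for a monoclonal one.
* **Isoelectric points** — the pH where the Henderson–Hasselbalch net
  charge over the peptide's ionizable groups crosses zero, found by
  bisection on [0, 14] with a configurable pKa table.
* **Residue-property composition** — occurrence counts and percentages
  per IUPAC-IUB style property group (Aliphatic, Aromatic, Sulphur,
  Basic, Acidic, Aliphatic hydroxyl, and the two aminoacyl-tRNA
  synthetase classes, which partition all residues).
* **Immunogenicity scoring** — class I pMHC enrichment model: score =
  Σ over unmasked positions of (residue log-enrichment × position
  importance), MHC anchor positions 1, 2 and the C-terminus masked;
  score > 0 is called positive. The packaged weight table is replaceable.
* **Clone sharing & conservation** — exact-match clonotype sharing
  across samples (aa level by default, nt behind a flag) and
  Clustal-style `* : .` column conservation symbols for equal-length
  shared sets (strong/weak Gonnet PAM 250 groups).
* **Group comparison** — Dunn's pairwise rank test with midrank tie
  correction, `z = (R̄_a − R̄_b) / √((N(N+1)/12 − T)(1/n_a + 1/n_b))`,
  `T = Σ(t³ − t)/(12(N − 1))`, two-sided normal p-values, optional
  Bonferroni/Holm adjustment.
* **Synthetic cohorts** — a seeded generator (Dirichlet or power-law
  clone frequencies, multinomial template sampling, configurable
  nonproductive fraction and planted shared clones) that provides ground
  truth for every stage.

## Worked example

```r
library(cdr3profiler)

sim    <- simulateCohort(simulationConfig(seed = 42))
cohort <- translateRepertoire(sim$cohort, verbose = FALSE)
cohort
#> CDR3Cohort: 7 sample(s) [ARDS=4, non_ARDS=3]
#>   unique rearrangements per sample: 1060, 1088, 754, 376, 153, 29, 157 (total 3617)
#>   provenance: synthetic cohort (model dirichlet, alpha 2, seed 42)

print(cohortClonality(cohort), digits = 3)
#>    sample_id    group n_clones simpson_index simpson_diversity clonality
#> A1        A1     ARDS      953       0.00161             0.998    0.0401
#> A2        A2     ARDS      980       0.00156             0.998    0.0395
#> A3        A3     ARDS      680       0.00227             0.998    0.0476
#> A4        A4     ARDS      339       0.00442             0.996    0.0665
#> N1        N1 non_ARDS      138       0.01096             0.989    0.1047
#> N2        N2 non_ARDS       27       0.05111             0.949    0.2261
#> N3        N3 non_ARDS      142       0.01100             0.989    0.1049

sharedClones(cohort)
#>         sequence  samples n_samples        groups       sharing
#> 1 CNPCTHEWGIASKF A2,A3,A4         3          ARDS  within_group
#> 2 CPTLGEIEMRFLNF A2,A3,A4         3          ARDS  within_group
#> 3 CRATSYLLPTTGTF A2,A3,A4         3          ARDS  within_group
#> 4 CSKGGAYIYHRSAF A2,A3,A4         3          ARDS  within_group
#> 5 CSYSCTAAQAESAF    A3,N3         2 ARDS,non_ARDS between_group
```

Clonality spans ~0.04 (the largest, most even samples) to ~0.23 (the
27-clone sample, whose floor is `1/√27 ≈ 0.19`), and the shared-clone
report recovers exactly the generator's planted pattern: four sequences
shared within three same-group samples plus one shared across groups.
`runReport(cohort, "report/")` runs every stage and writes the per-stage
TSVs, a combined per-sample summary, figures and a MANIFEST.

To analyze real data instead:

```r
cohort <- readRearrangements("rearrangements.tsv", dialect = "auto",
                             metadata = "sample_groups.tsv")
runReport(translateRepertoire(cohort), "report/")
```

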