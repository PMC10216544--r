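---
title: "Methods: CDR3 repertoire characterization with cdr3profiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDR3 repertoire characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3profiler)
```

# Scope and data model

`cdr3profiler` analyzes TCRβ CDR3 repertoires at the clonotype level: the
unit of observation is one unique CDR3 nucleotide junction in one sample,
with an abundance given in sequencing *templates* (input DNA molecules
attributed to the clonotype by bias-controlled amplification). The package
deliberately starts downstream of the wet-lab assay and the vendor
analyzer: it consumes a plain rearrangement table (immunoSEQ-style or AIRR
Rearrangement column names), not raw reads, and does no V/D/J gene-level
calling.

Two S4 containers hold the data: `CDR3Repertoire` (one sample;
rearrangements de-duplicated on the nucleotide sequence with template
counts merged by summation, so template mass is conserved) and
`CDR3Cohort` (samples with clinical group labels, which always come from
an explicit metadata table, never from sample names).

# Translation and productivity

Junctions are translated with the standard genetic code from position 1 —
the junction convention starts at the first base of the conserved V-gene
cysteine codon and ends with the conserved J-gene residue, so a complete
junction begins with C and ends with F or W. A trailing partial codon
marks the record out of frame; its complete codons are still translated
for inspection. **Productive** means in frame and stop-free. Two rules
here are genuine choices:

* Anchor conservation (C…F/W) is reported as a flag but does not affect
  productivity. Common rearrangement pipelines treat anchors as a
  property, not a filter, and making it a filter would silently drop
  records a user can easily filter explicitly.
* When the source file carries its own frame call, the file wins and the
  disagreement is warned about. The file may encode assay-level evidence
  the sequence alone cannot (e.g. a vendor's frame assignment from a
  longer read); recomputation remains the default when the file is
  silent. Supplied amino acid sequences are cross-checked but the
  computed translation is the single source of truth downstream.

# Length statistics

The per-sample length distribution uses the *sum productive frequency*:
each productive clonotype contributes `templates / total productive
templates` at its length, so the distribution describes where template
mass sits, not just which lengths occur. Lengths are reported on the
nucleotide scale by default (junction lengths in nt, multiples of 3 when
in frame) with the amino acid scale behind a flag; outputs always label
the scale, since summary numbers on the two scales are easy to confuse
(a "length 47" is meaningful only with its scale attached, and published
repertoire summaries have mixed the two).

Moment summaries use population (n-denominator) central moments;
kurtosis is *excess* kurtosis (normal → 0) and skewness the standardized
third moment. These conventions are fixed and documented because the
estimator flavor cannot be inferred from summary values alone; a
`weighted` switch selects template-frequency weighting (the default,
matching the sum-productive-frequency axis) or one-count-per-clonotype
weighting, since published summaries rarely state which was used.
Degenerate single-length distributions return variance 0 and `NaN`
skewness/kurtosis with a warning rather than an error.

# Simpson clonality

With productive clone frequencies `p_i`, Simpson's index is `Σ p_i²`,
Simpson's diversity its complement, and Simpson clonality `√(Σ p_i²)` —
1 for a monoclonal sample, `1/√n` for n perfectly even clones. The
plug-in (maximum-likelihood) form is used on purpose: clonality here
measures the evenness of the *sample*, which is what makes samples with
different input amounts comparable, so unbiased pool-level corrections
(e.g. `n(n−1)` denominators) are deliberately not applied. An
all-rearrangements mode exists behind a flag; the default is productive
clonality.

# Isoelectric point

The net charge of a peptide at a given pH is the Henderson–Hasselbalch
sum over its ionizable groups: positive terms `1/(1+10^(pH−pKa))` for
the N-terminus and each K/R/H side chain, negative terms
`1/(1+10^(pKa−pH))` for the C-terminus and each D/E/C/Y side chain. The
charge is strictly decreasing in pH, so the pI is the unique root,
found by bisection on [0, 14]; iteration stops at |charge| < `tol`
(default 1e-4 charge units) or an interval below 1e-6 pH. The default
pKa table (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1,
C 8.5, Y 10.1) is a widely used published set; because every pI tool
ships slightly different constants, the table is a plain named vector
argument so any tool's constants can be matched exactly. Asx/Glx
ambiguity codes (B, Z) have no defined pKa and are rejected with a
clear error rather than guessed.

# Residue-property composition

Composition uses an IUPAC-IUB style grouping: six physicochemical
groups (Aliphatic G,A,V,L,I; Aromatic F,W,Y; Sulphur C,M; Basic K,R,H;
Acidic B,D,E,N,Q,Z; Aliphatic hydroxyl S,T) plus the two aminoacyl-tRNA
synthetase classes, which partition all residues — so the two class
percentages always sum to 100, a useful internal check. Groups overlap
(a residue can sit in one physicochemical group and one class), so
percentages are always on the total residue count. Counts are over
productive clonotype sequences, unweighted by templates, matching the
"times found" convention of raw occurrence tables; template weighting
is available behind a flag. Both per-sample and per-group pooled tables
are emitted, since published group-level tables leave the per-sample
view implicit.

# Immunogenicity scoring

The class I pMHC immunogenicity score of a peptide is the sum over
unmasked positions of a per-residue log-enrichment weight times a
position-importance weight. The model encodes two observations from the
epitope-immunogenicity literature: aromatic and large residues are
enriched among immunogenic peptides, and the TCR-facing middle of the
presented peptide (P4–P6) matters most, while MHC anchor positions 1, 2
and the C-terminus are masked. The packaged weight file transcribes the
published enrichment model of the IEDB class I immunogenicity predictor
(Calis et al. 2013); its header records that provenance, and every
scoring function takes the model as an argument so a different table
(or a re-derived one) drops in without code changes.

Decisions worth stating:

* Each whole CDR3 is scored once by default. CDR3 junctions are not
  themselves 9-mer epitopes, so treating the full sequence as the
  scored unit is an interpretation; a sliding-9-mer mode (maximum
  window score) is provided for users who prefer epitope-length
  windows.
* For peptides longer than the 9-position importance template, interior
  positions beyond position 8 reuse the central-position weight — a
  documented extrapolation, flat across the extended middle.
* Positive means score strictly greater than 0; a score of exactly 0
  (e.g. under an all-zero table) is non-positive.
* Group differences in score spread are tested with an F-test on the
  two groups' score variances by default. No canonical test exists for
  this contrast, so the test function is an argument
  (`immunogenicityVarianceTest(..., testFun = )`); with repertoire
  scores that are clearly non-normal, a permutation variance test is a
  reasonable substitute.

# Clone sharing and conservation symbols

Sharing is exact string match of productive CDR3s across samples, at
the amino acid level by default: convergent recombination means
distinct nucleotide junctions can encode the same peptide, and the
peptide is the immunologically meaningful unit. Nucleotide-level
sharing is behind a flag. Shared sets of one length are annotated
column-by-column with Clustal symbols: `*` for full conservation, `:`
when the column's residues all fall in one "strong" group (Gonnet
PAM 250 substitution score > 0.5), `.` for one "weak" group (score in
(0, 0.5]), space otherwise. The strong/weak group lists are the ones
published with Clustal X/Omega and are replaceable arguments, since the
threshold-to-group mapping is itself only "roughly equivalent" to the
matrix criterion. Gapped multiple alignment of unequal-length sets is
out of scope and delegated to an external aligner.

# Dunn's rank test

All observations are ranked globally with midranks for ties; each pair
of groups is compared with
`z = (R̄_a − R̄_b) / sqrt((N(N+1)/12 − T)(1/n_a + 1/n_b))`, tie
correction `T = Σ(t³−t)/(12(N−1))`, and a two-sided normal p-value.
Without ties `T = 0` and the statistic reduces to the classical form.
Unadjusted p-values are the default — single reported pairwise
contrasts are customarily unadjusted — with Bonferroni and Holm behind
a flag. The `cloneFrequencyComparison()` preset feeds each sample's
per-clone productive frequencies in as that sample's observations; it
is labelled an interpretation, because "comparing the frequency of
clonal sequences across samples" admits several operationalizations
(per-clone frequencies, per-sample maxima, top-k means) and the
per-clone version uses all the data while still being dominated by each
sample's expanded clones. When every observation is identical the
statistic is undefined and reported as `NA` with a warning.

# The synthetic generator

Because suitable clinical repertoires cannot be bundled, the generator
produces cohorts with the statistical structure the analyses assume,
with every draw seeded:

* **Design**: 4 ARDS-like + 3 non-ARDS-like samples; unique clone
  counts per sample uniform on 56–1560 (ARDS) and 25–169 (non-ARDS);
  productive junction lengths uniform on the multiples of 3 in 21–69 nt
  (ARDS) and 30–66 nt (non-ARDS) — the ranges a small lung edema fluid
  cohort of this design exhibits.
* **Junctions**: a TGT/TGC first codon and TTT/TTC last codon (so every
  productive clone translates to C…F) around uniform sense codons. This
  is *not* a VDJ recombination model: no gene segments, no insertion/
  deletion profile, no codon-usage bias.
* **Frequencies**: symmetric Dirichlet with concentration α = 2 by
  default — one interpretable evenness knob; the plug-in expectation
  `E[Σp²] ≈ (1+α)/(1+kα)` puts Simpson clonality roughly in 0.04–0.24
  across the design's sample sizes, the band such cohorts occupy. A
  power-law mode (`p_i ∝ i^−s`, default s = 1.5) is available because
  real repertoires are heavier-tailed than any Dirichlet.
* **Templates**: multinomial at a per-group depth (20 000 ARDS, 6 000
  non-ARDS — ARDS samples of this design yield more templates); clones
  drawing zero templates are unobserved and dropped; planted clones are
  guaranteed at least one template.
* **Nonproductive clones**: a configurable fraction (default 0.1, a
  typical order for template-level exports that retain nonproductive
  rearrangements) realized by deleting one nucleotide (frameshift) or
  replacing an interior codon with a stop, chosen at random.
* **Shared-clone plan**: by default 4 sequences planted into three
  same-group samples and 1 across groups, all productive, all of one
  length (42 nt → 14 aa columns), giving an exactly known sharing
  pattern and an annotatable equal-length set.

What passing tests on synthetic cohorts does **not** show: behavior
under real codon-usage and VDJ-driven length/sequence biases, PCR or
sequencing error, or realistic immunogenicity score distributions —
under uniform sense codons roughly half of synthetic CDR3s score
positive, whereas real repertoires of this kind sit nearer 28–34%.
Ground-truth recovery (sharing patterns, nonproductive fraction,
clonality ordering in α) is what the synthetic tests certify.

# Numerical and testing choices

* pI bisection: default `tol` 1e-4 charge units; tests drive `tol` to
  1e-8 so the 1e-6-pH interval criterion governs, and compare against
  an independently coded fine-grid (2e-4 pH) root scan.
* Moments: population denominators throughout; no small-sample
  corrections anywhere, so values are exactly reproducible from the
  distribution table.
* Test problem sizes were chosen to keep the suite fast while leaving
  no estimator in an asymptotic grey zone: 1 000 random junctions for
  the translation oracle, 500 peptides for the pI oracle, 200 random
  datasets plus 2 000 null simulations for Dunn's test, 1 000-clone
  repertoires for nonproductive-fraction recovery, and a 5-point α grid
  × 3 seeds for the clonality-monotonicity check.
* The full suite and the acceptance script each run in well under a
  minute on one CPU.

# Known limitations

* No gapped MSA, no V/D/J annotation, no rarefaction or pool-level
  diversity estimation — each is either delegated or out of scope.
* The immunogenicity constants are transcribed, not re-derived; users
  needing certified agreement with the reference predictor should
  supply that tool's current table via `readImmunogenicityModel()`.
* Group comparison assumes exchangeable observations within samples;
  per-clone frequencies within a sample are weakly dependent (they sum
  to 1), which Dunn's test ignores, as does any rank test applied this
  way.
* The generator's realism limits are listed above; treat synthetic
  percent-positive immunogenicity and composition values as pipeline
  checks, not biological expectations.
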