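---
title: "Methods: single-cell BCR repertoire analysis with repclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell BCR repertoire analysis with repclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repclone)
```

# Scope and model

`repclone` analyses paired heavy/light chain B cell receptor (BCR)
repertoires obtained one cell at a time, the setting of cerebrospinal-fluid
(CSF) B cell studies in autoimmune encephalitis where only tens of
antigen-binding B cells can be recovered per patient. The scientific
question such studies ask is whether *convergent* (public) clones — the
same heavy V gene, J gene and junction amino acids arising independently in
different patients — exist, and whether whole paired-chain clonotypes are
shared. At that scale every definition matters, so the package implements
the full chain of definitions explicitly and validates it against a
ground-truthed simulator.

## V(D)J annotation

Each read is assigned segments by local alignment (match +2, mismatch −2,
gap open 5, gap extend 1, penalties positive; a gap of length $L$ costs
$5 + L$) against a germline reference:

1. **V first.** The best-scoring V allele over both orientations fixes the
   read orientation and locus. Reads whose best V score is below
   `v_min_score` (50) are *unannotatable* and are excluded with a logged
   count. The reverse orientation is skipped when the forward score is
   already above a bound the reverse strand cannot reach (`rc_skip_score`,
   300 by default), which halves alignment work without changing results.
2. **J only 3′ of the V span** (minimum score 20).
3. **D (heavy chains only) strictly between** the V and J spans, requiring
   at least `min_d_length` = 5 aligned nucleotides — the conventional floor
   below which D assignments are noise.

Exact score ties are reported as comma-separated multi-calls in
lexicographic order (`tie_margin = 0`); this is what produces the familiar
multi-D listings such as `IGHD1-26*01,IGHD2-2*03,IGHD2-8*01` when the D
core is too short to discriminate alleles.

**Junction and CDR3.** The junction is the nucleotide span from the
conserved 2nd-CYS codon of the V segment through the conserved W/F codon of
the J segment's \[W|F\]GxG motif, inclusive; the CDR3 strips the two anchor
residues. Anchor positions travel in a sidecar table next to the germline
FASTA rather than being re-derived from gapped IMGT numbering (out of
scope); they are mapped onto the query through the alignment columns, so
modest indels would not break the mapping. If an anchor fails to map, or
the mapped cys codon no longer translates to C, the junction is undefined:
the record is kept, flagged, and classified non-productive. All
coordinates in the package are 1-based and closed, the R/Bioconductor
convention.

**Productivity.** A rearrangement is functional iff the junction length is
a multiple of 3 and the translated V-start→J-end region, in the frame
anchored on the junction, contains no stop codon.

**Mutation counting.** V-region mutations are mismatched aligned columns
5′ of the cys codon; the denominator is the aligned (gap-free) column
count of the same region, so `mutation_rate = v_mutation_count /
v_germline_aligned_length`. The junction is excluded because its N
region has no germline counterpart. Junction-region mismatches against the
V/J germline overlap are reported separately as `cdr3_shm` — a documented
convention for the quantity sometimes printed alongside shared-clonotype
tables, not folded into the rate.

## Cells, clones, clonotypes

* **Completeness.** A cell is *complete* when it has ≥1 heavy and ≥1 light
  chain and at most one of the two classes is supernumerary (1H+1L, 1H+2L,
  2H+1L, ...); cells with ≥2 of both classes at once, or only one class,
  are *incomplete* — their pairing cannot be determined. `n_complete +
  n_incomplete = n_cells` always.
* **Clone.** Records from the same locus whose V call sets intersect,
  whose J call sets intersect, and whose junction amino acids are
  identical. Because the rule is an intersection over tied multi-calls,
  membership is closed transitively with a union-find, and the test suite
  checks the partition against a brute-force pairwise-closure oracle.
  Matching defaults to **allele level** — published shared-clone tables
  print alleles (`IGHV1-18*04`) even where the prose says "V genes" — with
  a `level = "gene"` switch for the looser reading. D is deliberately NOT
  part of the clone key: the definition names only V, J and the junction
  amino acids, and tolerated D ambiguity is exactly why multi-D listings
  appear.
* **Common clones** are clones spanning ≥ `min_patients` (default 2)
  distinct patients; the per-patient member counts form the
  clone-by-patient occurrence matrix that repertoire heat maps display.
* **Clonotype.** The paired-chain identity: heavy V and J, heavy CDR3,
  light locus, light V and J, light CDR3. Only complete cells
  participate. For a complete cell with one supernumerary class every
  heavy×light pairing is a candidate, but a cell counts at most once per
  clonotype group — the pairing rule for such cells is not stated in the
  literature this package follows, so the permissive candidate/unique-count
  convention is a documented package choice. Clonotype identity requires
  amino-acid identity only (no nucleotide-level CDR3 agreement), matching
  the printed definition.
* **CDR3 search** is Hamming distance at equal length (default exact);
  cross-cohort clone overlap is exact key equality on `(V set, J set,
  CDR3)` at a declared matching level, refusing mixed levels.

Light-chain clone analysis reuses the same operations with locus IGK/IGL;
there is no separate code path.

## Statistics

Usage tables weight tied multi-calls fractionally ($1/|\text{ties}|$ per
record, $1/(|V||J|)$ per V-J cell) so each record carries total weight 1
and the V-J matrix margins equal the usage counts — a cross-module
invariant under test. CDR3 length distributions report the integer
histogram, all modal lengths, and Shapiro-Wilk normality (undefined below
n = 3 or at zero variance). Group comparisons follow the normality-gated
rule standard in this literature: Shapiro-Wilk per group at α = 0.05;
two groups → Student's t (both normal) or Wilcoxon rank-sum; ≥3 groups →
one-way ANOVA or Kruskal-Wallis (the non-normal ≥3 branch is a package
choice; two-group flows dominate in practice). Degenerate all-equal
comparisons report statistic 0 and p = 1 by convention. α is fixed at
0.05 two-tailed and no multiple-testing correction is applied anywhere,
matching the analysis style the package reproduces. Kappa/lambda balance
is tested with a two-sided exact binomial test against 0.5.

# The simulator and what it does (not) show

The simulator exists because raw patient sequences in this field are
rarely deposited; it generates cohorts with known truth so every analysis
stage can be validated end to end. The generative model is deliberately
the simplest one that exercises every stage:

* germline V (+D) + J concatenation with uniform exonuclease trimming on
  `[0, trim_max]` per end (capped so conserved anchors survive) and
  uniform-random untemplated N insertions up to `n_insert_max` per side;
* productivity forced by construction (the insertion length is adjusted so
  the junction frame closes, and junction N bases are resampled under a
  bounded retry until stop-free) for a configurable `productive_fraction`
  (default 1), the remainder emitted frameshifted;
* independent per-site substitution SHM at rate μ, no indels, no hotspot
  structure, no gene conversion, no sequencing error model;
* planted convergent clones: fixed V, J and junction nucleotides emitted
  in chosen patients; SHM on planted chains spares the junction,
  modelling the antigen-driven conservation that defines a convergent
  clone and keeping the planted truth exact at μ > 0;
* incomplete cells: a configured fraction of (non-planted) cells either
  loses one whole chain class or has both chains duplicated with fresh SHM
  (a doublet mimic). Duplicating a single chain would yield 1H+2L — which
  the completeness rule classifies complete — so supernumerary cells are
  made two-of-both by design.

Defaults model the targeted study conditions: 12 patients × 8 cells
(CSF single-cell scale), geometric 2-fold skew over alleles (usage
preference "very obvious"), μ = 0.005 (hypomutated), λ-skewed light
chains (0.65/0.35), 15% incomplete cells, trim ≤ 4 nt, N inserts ≤ 6 nt.

The bundled germline reference is **synthetic**: random stop-free
sequences carrying real-style IMGT allele names with the conserved anchors
built in, different genes of a locus ≥10% divergent and alleles of one
gene 2 nt apart. Passing tests therefore demonstrate correctness of the
*definitions and algorithms*, not performance on real IMGT alleles, whose
within-family similarity is far higher; allele-level call accuracy on real
data would be correspondingly lower and is not claimed. Likewise the
independence of SHM sites means mutation-rate recovery here does not
validate hotspot-aware SHM estimation.

# Numerical and design notes

* Alignment is `Biostrings::pairwiseAlignment` (C-backed); the test suite
  holds it against an independently written brute-force affine-gap dynamic
  program on 500 random instances.
* Problem sizes in the validation suite were chosen to make the
  statistical assertions sharp at desk scale: 2 patients × 500 cells for
  gene-level recovery (≥99%) and SHM recovery (within 3 standard errors of
  μ = 0.01), 5,000 draws for usage recovery (±0.03), 200-replicate
  binomial bands for the SHM model.
* Shapiro-Wilk on *integer-rounded* normal draws is reliably rejected at
  n = 200 because of ties — a property, not a bug, confirmed against an
  independent implementation; the normality gate is therefore validated on
  continuous draws, and real CDR3-length vectors (small n, strong modes)
  are expected to test non-normal, as published cohorts do.
* Determinism: a cohort is a bit-level deterministic function of
  config + seed; the pipeline consumes one seed in a fixed stage order and
  every stage re-reads the previous stage's TSV, so single stages can be
  re-run reproducibly from intermediates.
* Ties in clone/clonotype output order are broken lexicographically after
  sorting by patient span, making outputs order-invariant to input
  permutation (tested).

# Known limitations

No lineage reconstruction, no nucleotide-distance clonal clustering, no
isotype calling from constant regions (isotype is an optional label), no
IMGT gapped numbering, no indel-aware SHM, and no acquisition of external
databases — cross-cohort comparisons operate on user-supplied clone
tables (AIRR or MiXCR-style dialects).
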