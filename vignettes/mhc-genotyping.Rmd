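---
title: "Genotyping multilocus MHC variation from tagged amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping multilocus MHC variation from tagged amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

## The problem

MHC class I genes of many birds form expanded, recently duplicated families:
a single degenerate primer pair co-amplifies exon-3 fragments from up to
~19 loci, and alleles are shared among loci, so locus assignment is
impossible and an individual's genotype is its *set* of distinct allele
sequences. Amplicon pyrosequencing resolves such sets at population scale,
but PCR mutations, PCR chimeras and sequencing errors generate tens of
thousands of spurious variants per run. This package implements the whole
desk-side pathway — artefact filtering, the depth model that justifies the
coverage threshold, functional annotation, selection statistics and
supertype clustering — together with a ground-truth simulator, so that
every stage is testable without access to a sequencing run.

## Demultiplexing model

Reads have the layout `MID_f | primer_f | insert | rc(primer_r) | rc(MID_r)`
on either strand (sequencing adaptors are assumed trimmed upstream). A read
is assigned only when *both* 10-bp MID tags and *both* primers match
completely; primer matching is against the IUPAC degenerate pattern with no
mismatches by default (`max_mismatch` exists but 0 mirrors the
complete-tags-and-primers convention of MHC amplicon extractors), and any
read containing an `N` is unassigned. Inserts are reported on the
forward-primer strand, so the two sequencing directions of one amplicon
collapse to a single variant. MID pairs are reused across plate regions;
the region identifier therefore travels with the reads (from the file or
lane) and never comes from sequence content.

## The five-step validation and its assumptions

The procedure encodes six assumptions about artefacts: frame-shifted
lengths are errors; sequencing errors are rare globally and per individual;
PCR mutants and chimeras co-occur with their parent alleles and are rare
globally; real alleles occur at least twice within an individual and in at
least two independent amplifications; and genotypes are only reliable above
a minimum read depth.

Operationally (defaults in `validation_config()`):

1. **Size filter** — inserts not 212/215/221 bp are removed globally.
2. **Global rarity** — variants with fewer than 4 copies in the whole
   dataset are removed.
3. **Coverage** — individuals with fewer than 200 retained reads are
   dropped entirely (see the depth model below).
4. **MPAF classification** — the maximum per-amplicon frequency of a
   variant is its highest within-individual read fraction. Below 0.01 the
   variant is removed. In the closed band [0.01, 0.025] it is examined in
   its three highest-frequency carriers (ties broken by frequency
   descending, then sample id) and removed only if *explainable in all of
   them*; above the band it is kept unexamined.
5. **Per-individual screen** — singletons are removed; 2–4-copy variants
   are removed in an individual iff explainable there; ≥5 copies are kept.

"Explainable" means: differs by exactly one substitution from a strictly
more common co-occurring variant, or equals a single-breakpoint
concatenation `a[1..k] + b[k+1..]` of two strictly more common
co-occurring variants. Three choices deserve emphasis, each made once and
fixed:

* **Strictly more common.** Equal counts are not parents; otherwise two
  equally supported true alleles that happen to be 1-bp apart would
  annihilate each other.
* **Boundary convention.** Rejection is `MPAF < 0.01` and the review band
  is closed, `[0.01, 0.025]`, matching a screen that examined variants *at*
  0.01 and deleted those *below* it.
* **Scope of removal.** Step 4 removes a variant everywhere (it is judged
  at dataset scale); step 5 removes it only in the individual where it is
  explainable.

Counts are recomputed after every step, strictly in order; step 2 totals
are computed before low-coverage individuals are dropped (the listed order
of the procedure). A review-band variant is judged against per-carrier
counts, not pooled ones, consistent with examining its top three carriers.
The chimera test accepts parents of different (valid) lengths and only
exact concatenations — the strictest form of the visual rule it automates.
The whole procedure is checked in the test suite against a brute-force
re-derivation on small tables, and is monotone: relaxing any threshold can
only grow the genotypes.

## The coverage model

The 200-read floor is justified by a worst-case depth model: a fully
heterozygous individual with `m` loci has `2m` distinct alleles amplifying
equiprobably, and a genotype is safe when every allele is sequenced at
least `r` times. `coverage_confidence(n, m, r)` evaluates this probability
exactly by inclusion–exclusion over the alleles that fail to reach `r`
copies, with the inner joint probabilities computed by dynamic programming
over bounded counts in log space (stable to at least n = 10^4).
`min_reads(m)` scans upward — the probability is nondecreasing in n — and
reproduces 9, 23, 39 and 55 reads for m = 1–4 at r = 2, f = 0.95. The
increment is almost exactly linear in m, so `extrapolate_min_reads()`
extends the last exact increment (16 reads per locus anchored at m = 4),
giving 151 and 199 reads for 10 and 13 loci; ordinary least squares over
the four exact points does *not* reproduce those two figures, which is why
the anchored-increment rule was adopted. The exact values are verified in
the tests against closed-form binomial arithmetic (m = 1) and a
100,000-draw multinomial Monte Carlo (m = 2, 3).

The model deliberately assumes equal amplification of all alleles; unequal
amplification efficiencies would raise the required depth and are outside
its scope.

## Functional annotation

Alleles are translated in a configurable frame (`frame_offset`, default 0;
the amplicon is an internal fragment of exon 3, so the frame is a
documented configuration choice, not something the package infers) and
premature stops are counted with the trailing partial codon ignored.
Group assignment operationalises a tree-based partition the package does
not itself compute: given labelled reference exemplars (pseudogene family,
a putatively non-functional cluster, the functional remainder), each
allele takes the group of its nearest equal-length exemplar by p-distance
under a maximum-distance gate (default 0.1); stop-bearing alleles inside
the pseudogene gate are pseudogenes, other stop-bearers are flagged
non-functional wherever they fall, and alleles beyond every gate are
unassigned. Nearest-reference assignment is an operationalisation — the
original delineation is phylogenetic and partly visual — and is documented
as such.

Nucleotide diversity (mean pairwise p-distance), mean pairwise differences
and segregating sites are computed within each length class only;
cross-class comparisons would need an indel alignment, which can be
supplied pre-aligned instead. Sequences differing only in length are
distinct alleles; nothing is collapsed.

## Selection statistics

The Nei–Gojobari method counts, per codon, synonymous and nonsynonymous
*sites* (each position contributes the fraction of its viable single-base
changes that are synonymous; with the complement this sums to exactly 3)
and *differences* (codons differing at several positions are averaged over
all shortest mutational pathways). Changes that create stop codons are
excluded from site denominators, and pathways crossing a stop are dropped
(with an all-pathways fallback if every pathway is blocked, so a pair is
never silently lost). Proportions are corrected with Jukes–Cantor,
`d = −(3/4)·ln(1 − (4/3)p)`; saturated pairs (p ≥ 3/4) are excluded
pairwise with a warning, and a site class in which *every* pair saturates
returns an NA row rather than failing the run.

The codon-based Z-test reports mean pairwise dN and dS over a site-class
mask, with standard errors from a seeded bootstrap over codon sites
(default 1000 replicates; the bootstrap is the conventional variance
estimator for this test, and an analytical variance could differ in the
third decimal). `Z = (dN − dS)/se(dN − dS)` with a one-tailed
`p = 1 − Φ(Z)`; when Z ≤ 0 the p-value is reported as 1, mirroring how
such tables print the no-evidence case. Site masks (positively selected
sites from codon-model analyses, antigen-binding sites from structural
superimposition) are *inputs* — the likelihood machinery that identifies
them is external to this package by design.

## Supertypes

Functional alleles are reduced to their binding-site residues, each residue
encoded by the five z-descriptor scales (Sandberg et al. 1998): z1
hydrophobicity, z2 steric bulk, z3 polarity, z4/z5 electronic effects. The
table is embedded as the exported constant `z_descriptors` and can be
replaced by any table of the same shape. K-means (seeded, 50 restarts by
default) is run for k = 1..k_max and scored with
`BIC(k) = n·ln(WSS_k/n) + k·ln(n)` — the convention of the find.clusters
approach, recorded here so results are comparable across tools. Because
"the BIC decreases by a negligible amount" is subjective, the elbow is
automated as the argmax of the BIC curve's second difference, and a manual
`k` override exists for the visual-elbow workflow. DAPC retains the fewest
principal components reaching a target variance fraction (default 0.93)
and computes discriminant axes on the cluster labels; when clusters are
perfectly separated (zero within-group variance, common on small synthetic
pools) the standard LDA fit is singular and a ridge-regularised
generalised-eigen computation supplies the same axes. Supertype genotypes
are the set-collapse of allele genotypes through the labels.

## The simulator: what it emulates and what it does not

`sim_config()` defaults encode the study conditions of a large
bidirectional 454 survey of a wild passerine MHC class I system:

* up to 16 diploid loci with allele sharing across loci; allele pools in
  three length classes (212/215/221 bp, the shorter classes carrying
  codon-aligned deletions of a shared ancestral insert) with ~5% per-allele
  divergence, giving ~10% pairwise diversity as seen in real allele
  catalogues;
* per-individual depth from a negative binomial moment-matched to mean 286
  and SD 173 (the dispersion is far super-Poissonian, which is why a
  Poisson law was rejected), truncated at ≥1;
* three error processes applied to the insert, in biological order: PCR
  substitutions (default 2×10⁻⁴/base), two-parent single-breakpoint
  chimeras (1% of reads, breakpoint uniform on internal positions —
  matching the detection operator's model exactly), then sequencing
  substitutions (10⁻³/base) and indels (5×10⁻⁴/base, optionally
  homopolymer-weighted; uniform by default since no published rate table
  exists for this chemistry).

The error rates are simulator parameters, not estimates — the source
surveys report artefact *outcomes*, not per-base rates. The defaults were
chosen once so that the simulated funnel behaves like a real one (a
minority of reads lost to indel length shifts at the size filter, a large
cloud of rare substitution variants removed by the global-rarity and MPAF
screens, recurrent chimeras surviving into the explainability steps) and
were not adjusted afterwards. What the simulator does **not** model:
per-cycle PCR kinetics (chimeras form once, not recursively), quality
scores (FASTQ output carries a constant placeholder), tag/primer errors
(reads with damaged tags would simply be discarded upstream), and
contamination.

Passing the recovery tests on this generator therefore shows that the
pipeline's bookkeeping and filtering logic are correct under a realistic
error composition; it does not certify performance on a particular real
chemistry, whose error spectrum must be measured, not assumed.

## Problem sizes and numerical choices in the tests

The test suite exercises the pipeline at the scale the method targets
where that is informative, and at reduced scale where only correctness is
at stake: genotype recovery runs at 200 individuals under the default
depth law (mean Jaccard ≥ 0.9 against ground truth; observed ≈ 0.997),
and the zero-error check uses 60 individuals at ample depth (mean 800) so
that exact recovery isolates bookkeeping from multinomial sampling noise —
at default depth the coverage model itself predicts occasional sub-r
sampling of rare alleles, which is a property of the depth, not a bug in
the plumbing. Oracle-equivalence checks use small tables (≤8 variants × ≤4
samples) against brute-force re-derivations; dN/dS is verified against
pathway enumeration to 10⁻⁶; cluster-count recovery is checked for 2–6
planted archetypes over 50 seeded runs. Determinism is asserted at
byte-identical level on written artifacts.

## Known limitations

* Locus assignment, phasing and copy-number estimation are out of scope:
  the diploid bound `ceiling(max alleles / 2)` is the only locus-number
  statement the data support.
* The MPAF review band automates a procedure that was partly visual; on
  real data a curator may disagree with the strict-concatenation chimera
  rule in edge cases.
* Group assignment needs reference exemplars; without them all stop-free
  alleles are provisionally functional.
* The coverage model assumes equal amplification across alleles.
* π across length classes is not computed (no internal aligner).
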