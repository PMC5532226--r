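---
title: "wrkykit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wrkykit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures wrkykit implements, the
tunable parameters and their defaults, what the synthetic-data generators do
and do not emulate, and the design decisions taken where the methodology was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The domain model

A WRKY domain is modelled as a conserved heptapeptide followed, within a
bounded window, by a zinc finger `C-X(m)-C-X(n)-H-X-[H|C]`. The scanner
treats the two parts separately:

* **Heptapeptide search** (`find_heptapeptides`). Every 7-mer within Hamming
  distance `max_mismatch` of `WRKYGQK` is a candidate; overlapping candidates
  are resolved by keeping the lower-distance hit, ties to the leftmost.
  `max_mismatch` defaults to **2** because the most diverged variant observed
  in the bamboo family table (`CRKYGQA`) sits exactly at distance 2; larger
  values admit essentially random 7-mers.
* **Zinc-finger search** (`find_zinc_finger`). The first match downstream of
  the heptapeptide wins, with a fixed tie-break order — smallest first-Cys
  position, then smallest m, then smallest n — so the parse is unique and
  reproducible. Defaults: m ∈ [4, 8], n ∈ [20, 40], window 150 residues.
  These cover every row of the family table except the single printed
  `C-X5-C-X88` arrangement, which the original study itself could not
  confirm as real rather than a mis-annotation; an opt-in *extended* mode
  (`scan_config(extended = TRUE)`: n ≤ 120, window 250) detects it, and the
  scanner takes no position on which reading is right.
* **Completeness and terminal labels.** A domain is *complete* iff a zinc
  finger was found. Domains may not overlap (greedy left-to-right selection);
  with two or more domains the first is labelled N and later ones C, a single
  domain is labelled "only".

Physicochemical properties (`compute_physchem`) use average residue masses
plus one water for molecular weight, and bisection on the
Henderson–Hasselbalch net-charge function (EMBOSS pKa set, free termini
included) to |charge| < 1e-4 for pI. Both are composition-only.

## Classification rules

`assign_group` applies, in priority order: (1) ≥ 2 heptapeptides with ≥ 1
complete domain → group 1 — this deliberately overrides the zinc-finger type,
so a two-domain protein with C2HC fingers is still group 1 (flagged
`two_domain_c2hc_override`), mirroring how the bamboo family's one such
member was classified; (2) single complete C2HC domain → group 3; (3) single
complete C2H2 domain → group 2, subgroup from a hint or nearest labelled
reference; (4) otherwise unclassified. The m spacer is *not* used for
grouping: group 2 members carry both 4- and 5-residue spacers, so m carries
no group signal.

Two classification paths exist because two rows of the printed family table
conflict with these rules (group-3 labels over C2H2 fingers). The *label*
path takes the printed labels at face value; the *rule* path recomputes from
the domain descriptors. The fixture preserves the printed values verbatim
(including the conflicting rows and the `PheWRK109` id typo); the package
reports its own tallies and flags the conflicts rather than "correcting" the
source.

**Subgroup assignment** is operationalized as nearest labelled reference by
global alignment score, with score ties broken by placement in a joint
neighbour-joining tree (patristic distance to the tied references), then
lexicographically. Real subgroups are defined phylogenetically; nearest
reference against user-supplied exemplars is a transparent, testable stand-in
and is recorded as a design decision, not a claim about the published
criteria.

## Alignment, distances, trees, homology

Pairwise alignment is affine-gap Gotoh dynamic programming (Rcpp): global
(Needleman–Wunsch) for identities/distances, local (Smith–Waterman) for BBH
scores. A gap of length L costs `gap_open + L * gap_extend`, defaults 10 and
0.5 (ClustalX-like), substitution matrix BLOSUM62. Distances are
1 − fractional identity over aligned residue columns (gap columns excluded);
this is a premetric (symmetric, zero diagonal) and the triangle inequality is
not asserted. The original study aligned with ClustalX and built trees in
MEGA; wrkykit implements the distance + NJ route itself so the artifact is
self-contained — a methodological substitution, checked in the tests against
an independent NJ implementation (ape) and against brute-force alignment
enumeration on small cases.

`nj_tree` is Saitou–Nei agglomeration with fixed tie-breaking (minimum Q,
ties to the smallest index pair) and negative branch lengths clamped to 0.
Trees are reported unrooted (the published rooted figure never states its
root criterion); midpoint rooting is available behind a flag.

`bbh` reports a pair iff each sequence is the *unique* best-scoring hit of
the other; score ties mean no pair. This is the conservative reading of a
method "restricted to a 1:1 ratio" — the source never states its scoring or
tie policy, so uniqueness-on-ties is our decision. Calling it with one set
finds within-species paralogue pairs (self-hits excluded, canonical id
order).

## Ka/Ks and duplication dating

`nei_gojobori` implements the classical 1986 estimator: per-codon synonymous
site fractions from the standard code (mutations to stop codons count as
nonsynonymous, so S + N = 3 × codons exactly), differences for multi-hit
codons averaged with equal weight over all orderings of the differing
positions (pathways crossing a stop are excluded; if every pathway is
blocked, all are used), proportions pS = sd/S and pN = nd/N, and the
Jukes–Cantor correction `JC(p) = −(3/4)ln(1 − 4p/3)`. Saturation (p ≥ 3/4)
yields `NA` plus a `flagged` field rather than a number. The original study
names only the program it used; Nei–Gojobori with equal-weight pathways is
the classical estimator that program reports, and results are labelled with
the estimator name. In-frame stop codons are an error, never silently
skipped.

Duplication dates use `T = Ks / (2λ)` in million years. λ defaults to the
grass synonymous clock 6.5e−9 substitutions/synonymous site/year
(appropriate for bamboo, rice, *Brachypodium*); 1.5e−8 is the documented
value for *Arabidopsis*. Both are overridable per run.

## Expression analyses

* `relative_expression`: ΔCt = Ct(target) − Ct(reference) per reaction;
  ΔΔCt = mean treated ΔCt − mean untreated ΔCt; relative expression 2^−ΔΔCt.
  Per-replicate values against the mean untreated ΔCt give the replicate
  mean and SD.
* `call_upregulated`: the published filter verbatim — BH FDR ≤ 0.05 **and**
  |log2FC| ≥ 2, both inclusive. The source does not state which test
  produced its FDRs (the expression data came from prior studies), so the
  default is a transparent two-sided exact Poisson rate test on group-summed
  counts (the conditional-binomial construction, cross-checked against
  `stats::poisson.test`), exposed as a plug-in `test` argument. log2FC uses
  pseudocount 1 to guard zeros. Note the rule uses the *absolute* fold
  change, as printed.
* `hier_cluster`: complete-linkage agglomeration on Euclidean distances of
  `log2(x + 1)`-transformed rows, via `stats::hclust` (the canonical
  implementation; merge heights are non-decreasing by construction).
* `coexpression_network`: plain Pearson correlation over samples with an
  inclusive r² ≥ 0.95 edge rule and hubs at degree ≥ 9, both printed
  thresholds. The source is ambiguous about whether a WGCNA adjacency or the
  plain Pearson rule produced its network; the stated Pearson rule is what is
  implemented. Zero-variance genes are excluded with a warning; fewer than 3
  samples is an error.

## Synthetic data: the stated world

The generators exist so every stage is testable offline with known truth.

* `make_family` plants domains into random flanks. The default group mix is
  the family table's own composition (20:5:11:28:7:12:27:11 over 121);
  `variant_rate` defaults to 0.1 (the observed 15 variant domains among
  roughly 150 heptapeptide slots); a quarter of group-1 genes get an
  incomplete C-terminal domain (5 of 20 as tabulated). Spacer lengths follow
  the table (group 2: m 4–5, n 23; group 3: m 6–7, n 23–24; group 1: m 4,
  n 22–23). Flanks are rejection-sampled to contain no 7-mer within Hamming 2
  of WRKYGQK, and spacers/linkers exclude the coordinating residues (C, and H
  inside the finger), so the planted truth is unambiguous and 100% recovery
  is a meaningful requirement rather than a statistical accident. Group-2
  subgroups additionally carry a fixed signature 7-mer after the
  heptapeptide (`WRKY2_SUBGROUP_TAGS`) standing in for subgroup-specific
  conserved motifs, which is what makes reference-based subgroup recovery
  learnable. These are generator artifacts: real families have intron
  structure, codon-usage bias, paralogue-correlated flanks and softer motif
  boundaries, so a green recovery test establishes the scanner/classifier
  logic, not field performance on real proteomes.
* `evolve_pair` diverges a CDS by synonymous-only substitutions: the number
  of events is Poisson with mean `pS* × S`, where `pS* = (3/4)(1 − e^(−4Ks*/3))`
  inverts the Jukes–Cantor correction and S is the Nei–Gojobori synonymous
  site count; proposals are rejection-sampled (must be synonymous, one change
  per codon at most), and every accepted change is logged. Protein identity
  of the pair is an invariant. Targets that round to zero expected events are
  an error ("unreachable"), per the contract.
* `make_expression` draws negative-binomial background counts (dispersion
  0.1, log-normal baselines around `base_mean`), multiplies treated-group
  means of planted DE genes by `fc`, and builds co-expression modules on the
  log2 scale with a shared per-sample latent factor whose loading is chosen
  so within-module pairwise correlation equals `module_r` exactly
  (`module_r = 1` removes idiosyncratic noise entirely, making profiles
  proportional). Module genes are therefore continuous (log-normal) while
  background genes are counts — acceptable for a matrix documented as "RPKM
  or counts", and stated here so nobody mistakes the mixture for a full
  RNA-seq simulator.

All generators are pure functions of (parameters, seed).

## Numerical choices and degenerate inputs

* Alignment arithmetic is exact in doubles (integer matrix entries, 0.5 gap
  steps), so traceback equality tests are safe.
* NJ tie-breaks and the zinc-finger parse order are fixed as above; rerunning
  any stage with the same config and seed is byte-identical.
* `jc_correct` returns NA at p ≥ 3/4 (saturation) — flagged, never clamped.
* Empty FASTA files, duplicate ids, non-modulo-3 CDS, in-frame stops,
  asymmetric or NaN distance matrices, missing qPCR conditions, and
  sub-3-sample networks are all hard errors with named locations; a constant
  expression matrix clusters validly at height 0.
* The family-table fixture was transcribed programmatically from the printed
  table with a full-coverage parse (121 rows, no residual characters) and
  carries a `verbatim` column per row.

## Known limitations

* Subgroup assignment needs labelled references; none are bundled for real
  species (users may supply published exemplars from *Arabidopsis* or rice).
* BBH uses raw Smith–Waterman scores, not E-values; no significance model.
* The Poisson DE test is a deliberate simple default, not a dispersion-aware
  DGE method — the contract is the published filter rule, not a DESeq2
  replacement.
* De-novo motif discovery (MEME-style) and profile-HMM domain search are out
  of scope; the scanner is pattern-based by design.
* `evolve_pair`'s one-change-per-codon simplification slightly lowers
  realized divergence at high targets; the Ks-recovery test quantifies this
  at the targets it uses.
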