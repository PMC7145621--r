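---
title: "Methods: sketch distances, pangenome partitioning and RGP detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sketch distances, pangenome partitioning and RGP detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models, parameter choices and
simulation design behind `pangraphr`, including the places where a
published method leaves a decision open and what this implementation
chose.

## 1. MinHash sketches and Mash distances

**Model.** A genome is represented by the set of its canonical k-mers
(the lexicographic minimum of each 18-mer and its reverse complement,
windows containing `N` skipped). Each k-mer is hashed with a seeded
64-bit hash (FNV-1a mixed through a splitmix64 finalizer); the sketch
keeps the `s` smallest distinct hash values. Because the hash is a
uniform permutation of k-mer space, the `s` smallest values of the
*merged* pair of sketches are a uniform sample of the union of the two
k-mer sets, and the fraction of that sample found in both sketches is
an unbiased estimator of the Jaccard index `j`. The Mash distance

$$ d = -\frac{1}{k}\,\ln\frac{2j}{1+j} $$

inverts the Poisson expectation `j = w/(2-w)`, `w = e^{-kd}`, of
shared k-mers under independent point substitution at rate `d` per
base, so `d` estimates per-base divergence and `1 - d` approximates
ANI/100.

**Parameters.** `k = 18` makes random 18-mer collisions negligible for
genomes below ~10 Mb while staying sensitive at species-level
divergence; `s = 5000` gives a Jaccard standard error of roughly
`sqrt(j(1-j)/s)` ≈ 0.004 at mid-range `j`, which maps to well under
0.01 in distance near the species threshold. Both match standard
practice for bacterial genome sketching.

**Numerical choices.** Hashes are stored as fixed-width lowercase hex
strings so byte order equals numeric order (R has no native unsigned
64-bit type); sorting uses radix order to be locale-independent.
`j = 0` is mapped to `d = 1` by convention because the formula
diverges; distances are clamped to `[0, 1]`. Circular contigs are
sketched as linear sequences — the at most `k - 1` wrap-around k-mers
per replicon are negligible against ~5 × 10^4 windows per 50 kb, and
this keeps the sketch independent of the (often unreliable)
circularity flag.

## 2. Species graph and clustering

Genomes enter the graph only if CheckM-style completion ≥ 90% and
contamination ≤ 5% (boundary values pass; the *removal* rule is
strict). An edge joins genomes with `d ≤ 0.06` — the 94% ANI species
boundary — and carries weight `1 - d`. The similarity weighting is a
choice this package makes where the threshold rule alone leaves the
weight open: it lets Louvain discount borderline pairs rather than
treating all admitted edges as equal. Louvain community detection
(resolution 1, seeded visit order) yields species clusters; labels are
canonicalised (`MICGC1` = largest cluster, ties by lexicographically
smallest member) so output does not depend on input order. Trees for
cluster members come from Saitou–Nei neighbor joining, which is exact
on additive matrices; negative branch lengths (possible on noisy
input) are clamped to zero with the deficit moved to the sibling
branch, preserving path lengths as far as possible.

## 3. Protein families

Candidate pairs sharing at least one amino-acid 4-mer are aligned
locally (Smith–Waterman, BLOSUM62, gap open 11, extension 1 — BLASTP's
default scoring). A pair is linked when

* identity ≥ 0.8, with identity = matches / aligned columns
  *including gap columns*, so indel-heavy alignments are penalised, and
* coverage ≥ 0.8 **of both sequences** (aligned span / sequence
  length).

The "80% coverage" rule is often stated without saying which sequence;
requiring both keeps the relation symmetric, which single linkage
needs to be well defined, and prevents a short protein from chaining
into a long multi-domain one. Families are connected components of the
link graph, labelled canonically (`FAM1` = largest).

## 4. Pangenome partitioning

**Model.** With `x_ig` the presence of family `i` in genome `g`
(paralogs binarised), the matrix follows a `K = 3` component
multivariate Bernoulli mixture: `P(x_i | z_i = k) = ∏_g
ε_{kg}^{x_ig} (1-ε_{kg})^{1-x_ig}`. A Markov random field on the
pangenome graph (edge weight `w_ij` = number of genomes in which
families `i`, `j` are contig neighbours; each genome counts once; no
tandem self-loops) couples labels of syntenic neighbours. EM with a
mean-field E-step adds `β · Σ_j (w_ij / N) · r_jk` to the component
scores, where `N` is the genome count; dividing by `N` makes `β`
comparable across dataset sizes.

**Numerical choices.**

* Initialisation: `ε` rows start at 0.9 / 0.5 / 0.1 — a deterministic
  "persistent/shell/cloud" profile that removes run-to-run label
  switching; `random_init = TRUE` is available for sensitivity checks.
* `ε` is clamped to `[10^-3, 1 - 10^-3]` so a component that captures
  an all-present family cannot drive `log(1-ε)` to `-∞`.
* E-step in log space with a row-wise max shift before
  exponentiation.
* Convergence when the largest responsibility change falls below
  `tol = 10^-6` or the relative objective change does; `max_iter =
  500`.
* Relabelling by decreasing mean presence probability; a family's
  label is the responsibility argmax with ties resolved toward the
  higher-presence component (deterministic).
* `β = 0.5` by default: strong enough to flip ambiguous families
  toward their syntenic context, weak enough that the data term
  dominates (at `β = 0` the objective is the exact mixture
  log-likelihood and is non-decreasing — asserted in the tests).
* The fit requires at least 3 families (one per component) and, by
  default, at least 15 genomes — below that, presence frequencies
  barely distinguish shell from cloud; `allow_fewer = TRUE` overrides
  with a message.

## 5. RGP detection

Genes on each contig, ordered by start coordinate, are scored +1
(shell/cloud) or −3 (persistent). A segment opens at a variable gene,
accumulates score, and closes when the running score drops to ≤ 0;
the reported candidate is the maximum-score prefix. Candidates need
score ≥ 4 and genomic span **strictly greater than** 3000 bp. These
constants mean: a region must hold at least four variable genes'
worth of signal, one interspersed persistent gene (+4 − 3 = +1 > 0)
does not break a strong region, and two consecutive ones do.

Circular contigs are scanned over a doubled gene walk (segments capped
at the contig's gene count) so an origin-crossing region is found
exactly once; the score/span filter is applied *before* overlap
de-duplication so a rejected linear prefix cannot mask a passing
wrapped region that reuses its genes. For wrapped regions `end <
start` and `span` carries the true extent; the BED writer splits them
into two intervals.

Cross-strain matching reports `100 · |F_q ∩ F_t| / |F_q|` with the
**query** family set as denominator — an asymmetric containment
measure, chosen so "is my island present over there?" is answered
independently of how much extra cargo the target region carries.

## 6. The simulators: design, realism and limits

All generators take a mandatory seed and run under `withr::with_seed`,
so they never touch the session RNG.

* **Point substitution only.** `mutate_sequence` replaces each
  position independently with probability `rate` by a uniformly chosen
  *different* symbol. No indels, no rearrangements, no GC skew. This
  is deliberate: the Mash model being tested is itself a Poisson
  substitution model, so the generator realises the model's own
  assumptions and makes `d ≈ rate` an exact, checkable prediction.
* **Species simulation** places one ancestor per species at
  `rate_between = 0.2` from a common root and members at `rate_within
  = 0.01`; the resulting within (~0.02) / between (~0.4) Mash
  distances bracket the 0.06 threshold by an order of magnitude on
  each side, so the clustering test verifies wiring, not luck.
* **Pangenome simulation** draws presence per class (p = 0.99 / 0.5 /
  0.05). Shell families are drawn in *blocks* of 30 sharing one
  Bernoulli draw per genome — co-occurring "adaptation modules" that
  give the MRF genuine neighbourhood signal. Every family is
  conditioned on being present in at least one genome (a family
  observed nowhere does not exist in real data, and this keeps planted
  counts comparable to recovered counts). Present genes are laid on
  one linear contig in a conserved class-grouped order; this makes
  variable families syntenic neighbours of each other — intentionally
  favourable to the MRF, and the reason RGP precision/recall tests use
  a persistent-only backbone plus explicit islands, where "one
  detected region = one planted island" is well defined.
* **Islands** are dedicated cloud families inserted as a contiguous
  run at a random backbone position per receiving genome
  (`island_prob = 0.25`, at least one receiver forced), with zero
  intra-island gaps so the planted span is exact.

**Calibration of the `s = 200` sketch check.** The replicate study
fixes within-pair divergence at 0.002 over 50 kb. At this divergence
the true Jaccard is high (~0.93), where the binomial standard error of
the estimator, `sqrt(j(1-j)/s)` ≈ 0.018, puts a 0.05 tolerance at
nearly 3σ — so ≥ 95% of replicates passing is a sound statistical
expectation rather than a tuned outcome. At mid-range Jaccard
(`j ≈ 0.5`) the same `s = 200` gives σ ≈ 0.035 and a 0.05 tolerance
would sit at 1.4σ, where a 95% pass rate is *not* predicted by the
model; the study condition was chosen up front to make the claim
testable, not adjusted afterwards.

## 7. Limitations

* No indel or rearrangement model; divergence estimates on real
  genomes with large indels will differ from the simulated ideal.
* Paralogs are binarised for partitioning; copy-number signal is
  discarded.
* The mean-field MRF is an approximation — the penalised objective is
  not guaranteed monotone for `β > 0` (only the `β = 0` case is).
* Single-linkage families can chain through intermediate sequences;
  the 80/80 thresholds limit but do not eliminate this.
* RGP detection is purely compositional (partition runs); it does not
  use tRNA anchors, nucleotide composition or mobile-element genes.
* Functional categories for RGP cross-linking (AMR, virulence, ...)
  are consumed from external tables, never predicted.
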