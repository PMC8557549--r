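---
title: "Codon usage bias analysis with codonscope: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with codonscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscope)
```

This vignette documents the models behind each stage of the package, the
conventions adopted where the literature admits several, the defaults and why
they were chosen, and what the synthetic-data generator does and does not
emulate. It is the package's methodological record: the numerical claims made
here are the ones the test suite computes.

## Input model and filtering

The unit of analysis is a coding sequence (CDS) read in frame 0 — the package
assumes its inputs are extracted CDS regions and performs no ORF search.
Sequences are case-folded, RNA `U` is normalized to DNA `T`, and a trailing
incomplete codon is trimmed (and counted) rather than causing rejection.

`filter_cds()` applies three rules with a fixed precedence — length, then
ambiguity, then internal stop — so each rejected sequence is counted against
exactly one rule and the report is deterministic. The default minimum length
is 400 bp with sequences *strictly shorter* eliminated, the standard cutoff
for transcriptome codon studies (indices such as ENc are noisy on short
genes). Whether internal-stop-containing CDS should be removed is not settled
practice; it is exposed as `drop_internal_stops` and defaults to `TRUE`,
since an in-frame stop usually indicates a mis-called CDS whose downstream
codons are not translated.

## Composition and silent-site statistics

GC and positional GC1/GC2/GC3 are computed over all codons of the trimmed
CDS, and GC12 is exactly `(GC1 + GC2)/2`. The silent-site statistics GC3s and
A3s/T3s/G3s/C3s are restricted to synonymously variable codons: members of
families with degeneracy ≥ 2, excluding Met, Trp and stops. Each single-base
fraction B3s follows the CodonW convention: occurrences of base B at
synonymous third positions, divided by the number of synonymous third
positions at which B *could* occur as a synonymous variant (e.g. `A` cannot
occur silently in a Phe codon). A documented consequence is that the four
B3s values need not sum to 1.

The PR2 point is `x = G3/(G3+C3)`, `y = A3/(A3+T3)`. Standard PR2 practice
restricts to third positions of fourfold-degenerate codon boxes, where all
four bases are exchangeable and deviation from (0.5, 0.5) cleanly separates
strand/selection asymmetry from amino-acid constraints; the package's default
scope is therefore `fourfold_only` (the six-fold families contribute their
fourfold boxes, e.g. CTN for Leu). Because the looser reading "all silent
third positions" also appears in the literature, an `all_silent` scope is
shipped as an option; a zero denominator flags the point `NA` and plot
functions drop it.

## Usage indices

**RSCU.** `RSCU_ij = x_ij / ((1/k_i) Σ_j x_ij)` within each synonymous family
of size `k_i`; Met, Trp and stops are excluded, leaving 59 informative
codons. Families absent from a gene give `NA` — "undefined" is distinct from
"avoided". Within every family present, RSCU sums to the family size (a
property the suite checks on 1000 random fixtures).

**ENc.** Wright's estimator from bias-corrected family homozygosities
`F̂ = (n Σp² − 1)/(n − 1)`, with class means F2, F3, F4, F6 over the 2-, 3-,
4- and 6-fold degeneracy classes and `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`.
Numerical conventions:

* families with fewer than `min_family_n = 2` codons are excluded from their
  class mean (the estimator is undefined at n = 1);
* `F̂ = 0` families (e.g. a two-codon family used once each) stay in the
  class mean; a class whose *mean* is 0 or that has no usable family is
  treated as absent;
* if the 3-fold class (Ile) is absent, its reciprocal is interpolated as
  `1/F3 = (1/F2 + 1/F4)/2`, Wright's recommended fallback expressed on the
  reciprocal scale that the formula consumes; the same interpolation is
  applied to an absent 6-fold class — a case Wright does not address
  explicitly, chosen for symmetry over dropping the class term, which would
  change the 20–61 range;
* if the 2- or 4-fold class is absent, or fewer than two families are
  usable, ENc is undefined;
* raw estimates above 61 are reported as the 61 cap with a `capped` flag
  (transcriptome studies routinely report genes "with ENc = 61", implying
  exactly this convention). Values below 20 cannot occur because `F̂ ≤ 1`.

The GC3s-only expectation is `ENc_exp = 2 + GC3s + 29/(GC3s² + (1−GC3s)²)`,
evaluated exactly (60.5 at 0.5; 31 and 32 at the endpoints) and capped at 61
only for plotting. The relative deviation `(ENc_exp − ENc_obs)/ENc_exp` is
histogrammed at bin width 0.1 by `plot_enc_deviation()`.

**CAI.** Weights are relative adaptiveness values from a pooled reference
set: pooled RSCU, zero-count codons floored at RSCU 0.01 (the standard
device keeping the geometric mean finite), then normalized by the family
maximum. Because CodonW-era studies rarely record their reference set, the
default is self-consistent: the 10 % of genes with the lowest ENc — the same
high-bias extreme the optimal-codon stage treats as the high-expression
proxy. An external reference can be supplied via `build_cai_weights()`. CAI
itself is the geometric mean of weights over the gene's sense codons,
excluding Met, Trp and stops.

**Fop and CBI.** Fop is the share of synonymous sense codons (Met/Trp
excluded) in the optimal set. CBI is `(N_opt − N_ran)/(N_tot − N_ran)` with
`N_ran` the chance expectation, computed only over families containing at
least one optimal codon; the degenerate case `N_tot = N_ran` is flagged
`NA`. Both default to the optimal set derived by the package itself
(pre-tabulated species sets do not exist for non-model crustaceans).

## Optimal codons

Genes are ranked by ENc; the lowest decile is the high-bias set (used as the
high-expression proxy — low ENc is the package's default because expression
data are optional; an FPKM-based split is available via `by = "fpkm"`), the
highest decile the low-bias set, with lexicographic gene-id tie-breaking and
set sizes `floor(0.10 n)`. Codon counts are pooled within each set; per
codon, a 2×2 chi-square (this codon vs the rest of its family, high vs low
pool) with Yates continuity correction tests the usage shift, falling back
to Fisher's exact test when any expected cell is below 5. Whether published
analyses used per-codon or family-wise tests is usually unstated; per-codon
2×2 is implemented because it maps one p-value to one codon decision.

A codon is *optimal* when `RSCU_H > 1`, `ΔRSCU = RSCU_H − RSCU_L ≥ 0.08`
and `p < 0.01`. The 0.08 threshold is the widely used convention for the
ΔRSCU method; threshold and alpha are arguments. Reports include the
ending-base tally (how many optimal codons are C- vs G-ending), the
signature quantity of mutation-vs-selection arguments.

## Codon pairs

Duplex codons are counted with an overlapping window (step one codon) within
genes only; pairs containing a stop are excluded. The preferred pair per
amino-acid pair is the raw-count argmax with lexicographic, flagged
tie-breaking; a frequency-normalized mode (`normalize = TRUE`, dividing by
the product of marginal codon counts) is exposed because some analyses
normalize before taking the maximum — raw counts are the default as the more
common convention. Cross-species diffs list only amino-acid pairs present in
both species with different argmaxes; rendered tables can use the RNA
alphabet to match publication style.

## Divergence (Ka, Ks, ω)

Ortholog pairs are aligned at the amino-acid level (global, BLOSUM62, affine
gaps 10/0.5) and back-translated; gap columns are excluded. The estimator is
Nei–Gojobori (1986): per-codon synonymous site fractions (averaged over the
two sequences; at each position the synonymous fraction is taken over
non-stop single-base changes so S + N = 3 per codon), pathway-averaged
difference counts for codons differing at 2–3 positions (pathways through
stops excluded; if all are blocked, all pathways are used), and the
Jukes–Cantor correction `d = −(3/4) ln(1 − 4p/3)` applied to both
proportions. `p ≥ 3/4` flags saturation; `ks = 0` leaves ω undefined
(`Inf`-flagged when `ka > 0`), and such pairs are excluded from stratum
means — mirroring the universal practice of reporting Ka/Ks only for the
computable subset. Strata are ω > 1 (positive), ω < 1 (purifying), ω = 1
(neutral boundary) and undefined.

NG86 was chosen over maximum-likelihood codon models deliberately: it is
exactly reproducible, dependency-free and adequate at the low divergences
(Ks ≲ 0.3) where the method is applied; `read_kaks_tsv()` accepts externally
computed values (e.g. from an ML tool) when exact reproduction of a specific
published table is needed. Numerical equality with ML estimates is not
claimed.

## Multivariate analyses

Correspondence analysis is the classical chi-square-metric decomposition:
relative matrix P, row/column masses, standardized residuals
`S = D_r^{-1/2}(P − rcᵀ)D_c^{-1/2}`, SVD, principal coordinates, inertia
fractions `σ_k²/Σσ²`. It runs on per-gene RSCU rows (the CodonW "RSCU-COA"
mode): undefined entries are imputed as 0 with the per-gene missingness
recorded, and genes with more than 50 % missing entries are excluded — the
imputation treats an absent family as maximal avoidance, acceptable only
when rare, hence the cap. Total inertia equals the table's Pearson
chi-square over its grand total, which the tests verify against an
independent eigendecomposition.

Correlation analyses (index–index, axis–index, divergence–index) default to
Spearman — index data are bounded, skewed and monotone-related, and the
original tools' coefficient choice is typically unrecorded, so the test
surface is figure-level *sign patterns*, not numeric r values; Pearson is
available. Constant columns are flagged `NA` rather than erroring.

GC classes for plot colouring are low < 45 %, 45–60 % mid, > 60 % high, with
boundary values assigned to the middle class (captions use strict
inequalities for the outer classes). GC3s tertile gene sets take the bottom,
centred-middle and top `n_per_group` genes of the GC3s ranking with
deterministic tie-breaking.

Cross-species comparisons pool counts per species into one RSCU row each;
clustering is agglomerative (average linkage, Euclidean distance by default;
complete/Ward and correlation distance available) with Newick export, and
PCA is a column-centred SVD. Heatmap-style row scaling (z-score per codon)
is left to the caller: raw RSCU is the default representation because RSCU
is already family-normalized.

## The synthetic-data generator

`sample_transcriptome()` emulates the statistical structure the analysis
assumes, not real sequence content:

* amino acids i.i.d. from a typical eukaryotic proteome composition;
* within each family, codon probability ∝ `exp(β s)` with `s = +1` for
  C/G-ending and `−1` for A/T-ending codons — chosen because the optimal
  codons of weakly biased animal transcriptomes are characteristically
  C/G-ending, so this is the structure downstream tests must recreate;
  `β = 0` gives exactly uniform usage (ENc near its 61 cap);
* per-gene `β ~ Beta(1.5, 6)` (mean ≈ 0.2: weak bias, mean ENc in the
  high-50s with a tail of biased genes);
* lengths log-normal (`meanlog = log 1200`, `sdlog = 0.45`) floored at
  402 bp, matching the filtered-transcriptome regime;
* FPKM log-normal (`meanlog 2`, `sdlog 1.5`), coupled to β through a
  Gaussian copula with rank correlation `rho = 0.6`, planting the
  positive FPKM–GC3s / negative FPKM–A3s/T3s sign structure;
* `evolve_ortholog()` plants (Ka, Ks) by drawing Poisson numbers of
  synonymous and nonsynonymous single-base codon changes with means
  `S·p` and `N·p`, where S/N are the gene's NG86 site counts and `p`
  inverts the Jukes–Cantor correction; repeated hits produce natural
  saturation. Targets above 0.5 substitutions/site are refused.
* all draws come from one RNG stream seeded by the config, so outputs are
  byte-identical across runs.

What it does **not** emulate: real amino-acid usage covariation, length–bias
coupling, isochore structure, indels, assembly artifacts, or any
sequence-level homology. Passing tests on synthetic data therefore
demonstrate estimator correctness and sign-structure recovery under the
stated generative model, not agreement with any particular real
transcriptome. One visible consequence of the `exp(β s)` form with β ≥ 0 is
that synthetic GC3s averages slightly above 0.5, whereas real weakly biased
transcriptomes often sit just below; adding a mutational AT-drift term would
fix this but break the clean `β = 0 ⇒ uniform` contract the tests rely on,
and the correlation structure is unaffected.

## Problem sizes used by the test and acceptance suites

Chosen once as desk-scale versions of the study conditions: the acceptance
suite uses 1000 random fixtures for RSCU conservation; 200 simulated pairs
per planted ω ∈ {0.1, 0.5, 2.0} at 500 codons and planted Ks = 0.1 for NG86
recovery (median ω̂ within 15 %); a 600-gene transcriptome at `rho = 0.6`
for the correlation sign structure plus 250 genes with β ~ U(0, 1) for the
CA-axis/GC3s gradient (|r| > 0.9); and a 1000-gene null transcriptome split
into random halves for chi-square type-I calibration (the ΔRSCU threshold
additionally filters chance hits to zero optimal codons at these pool
sizes). Unit tests use smaller fixtures with explicit oracles: brute-force
string counts, hand-computed homozygosities, enumeration-based NG86, and
eigendecomposition CA/PCA checks.

## Known limitations

* ENc class-absence fallbacks are conventions, not estimates; genes missing
  the 2- or 4-fold class entirely are reported `NA` rather than guessed.
* The self-consistent CAI reference makes CAI values dataset-relative;
  comparing CAI across datasets requires a shared external reference.
* NG86 underestimates divergence at high Ks and ignores
  transition/transversion and codon-frequency biases; use the external
  Ka/Ks hook where that matters.
* CA imputation of absent families as 0 biases genes with many missing
  families toward the avoided-codon corner; the 50 % missingness cap bounds
  but does not remove this.
* The per-codon chi-square tests within a family are not independent of one
  another (family counts are shared), so family-level error rates are not
  controlled; the ΔRSCU threshold is the practical guard.
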