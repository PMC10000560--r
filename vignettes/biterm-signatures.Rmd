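---
title: "Biterm topic models for sparse mutation catalogs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biterm topic models for sparse mutation catalogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btmsig)
```

## The problem

Targeted sequencing panels cover a few hundred genes, so a typical sample
carries fewer than ten somatic mutations — roughly 0.1% of what a whole
genome would show. Mutational-signature models built for rich catalogs
(NMF and per-sample topic models) have one exposure vector per sample to
estimate from those few mutations and generalize poorly. `btmsig` takes
the route developed for very short text documents: model co-occurrence.
Two mutations observed in the same patient carry a weak but usable hint
that they came from the same mutational process, and the number of pairs
grows quadratically with the number of mutations per patient.

## The Btm model

Mutations fall into the `M = 96` SBS categories (6 pyrimidine-centered
substitution types × 16 flanking-base contexts; canonical COSMIC order is
substitution-major). A *biterm* is an ordered pair of distinct mutation
instances in one patient. From a patient's count vector `V` the package
builds `B = VᵀV − diag(V)` (`patient_biterms()`), so the diagonal entry
`B[i,i] = V_i (V_i − 1)` counts same-category pairs and a patient with `S`
mutations contributes `S(S−1)` biterms; `cohort_biterms()` sums over
patients, choosing automatically between one dense cross-product
(`O(N·M²)`) and per-patient accumulation over nonzero categories
(`O(total biterms)`), whichever is cheaper.

Btm is a mixture over pairs: signature `k` is drawn from a single,
cohort-level exposure vector `π`, then both endpoints independently from
signature `e_k`. The log-likelihood of a biterm matrix is
`Σ_ij B_ij log Σ_k π_k e_k(i) e_k(j)`. EM responsibilities are symmetric
in `(i, j)`, so the expected endpoint counts reduce to
`E_k(i) = π_k e_k(i) Σ_j G_ij e_k(j)` with `G = (B + Bᵀ) / P` and
`P_ij = Σ_k π_k e_k(i) e_k(j)`; the M-step renormalizes `E` and its row
sums. Every quantity lives on the `M × M` matrix, so one iteration costs
`O(K·M²)` regardless of cohort size. Each biterm has two endpoints, which
gives the conservation law `Σ_k A_k = 2 Σ_ij B_ij` used as an internal
test invariant.

**Where the co-occurrence signal comes from.** If every sample shared the
same exposures, the two members of a pair would be independent draws from
the pooled category distribution and the expected biterm matrix would be
exactly rank one — held-out likelihood then correctly prefers `K = 1`
no matter how many signatures generated the pooled distribution. The
model detects multiple signatures only through *exposure heterogeneity
across samples*: patients dominated by different processes make the pair
distribution a mixture of distinct rank-one blocks. The synthetic designs
in the tests and the acceptance script therefore generate heterogeneity
explicitly (signature-dominant clusters); this is also why the method is
a natural companion to Mix, which models that heterogeneity directly.

## Training protocol

`train_btm()` runs 10 independent random initializations for 100 EM
iterations each, keeps the one with the best training log-likelihood
(first encountered wins ties), and trains it for 500 further iterations.
Initial `π` and signature rows are symmetric Dirichlet(1) draws —
unbiased over the simplex. Iteration counts are fixed rather than
tolerance-stopped to keep runs comparable; an optional relative-change
stop (`tol`) exists but is off by default. A master seed spawns one child
seed per initialization, so the whole multi-seed run is bit-reproducible.

Numerical choices: after every M-step, signature entries are clamped to
`≥ 1e-12` and renormalized. This guarantees held-out biterm matrices
never score exactly `−∞` (a held-out fold can contain category pairs the
training fold lacked) while perturbing the likelihood by far less than
the `1e-9` relative monotonicity tolerance asserted in the tests. A
signature whose expected mass hits zero is reset to uniform with epsilon
exposure rather than propagating `0/0`.

## Choosing the number of signatures: Btm2K

`btm2k()` repeats `T` times (default 30): split the samples into two
random halves (odd sample out goes to the first half), train Btm at each
candidate `K` on the biterms of each half, score the summed held-out
log-likelihood of the opposite half's biterm matrix, and add the two
directions. The candidate with the best median score is then *rolled
back*: `rollback()` returns the smallest `K ≤ K*` whose score sample is
not significantly different from `K*`'s by a two-sided Wilcoxon rank-sum
test (normal approximation, mid-ranks; level `alpha = 0.05`). Smaller
`alpha` rolls back more aggressively (at `alpha = 0` every candidate is
indistinguishable and the smallest is returned); `alpha` near 1 keeps
`K*` unless score vectors are essentially identical. The rollback is a
single pass from the smallest candidate upward — re-testing iteratively
against each new winner would terminate after one round anyway, since the
first accepted `K` is already minimal.

Because a patient with `S` mutations holds `S(S−1)` biterms, burden
outliers dominate the pair counts: in heavy-tailed cohorts a few percent
of samples hold most of the biterms, and which fold they land in moves
the score more than the choice of `K` does. Samples holding more than
`big_factor = 5` times the average biterm count are therefore *big
patients*: they join the training side of both folds and are never
scored. The selection result records fold memberships and big-patient ids
so leakage is auditable after the fact, and the score table (`K` ×
repetition) is kept for plotting (`autoplot()`) and re-testing.

"Number of biterms" per patient means the ordered count `S(S−1)`
throughout — the total of the patient's biterm matrix, diagonal included.
The ordered/unordered choice cancels from the 5× threshold; it only has
to be consistent with the matrix the likelihood consumes, and it is.

## The Mix model and BIC

`train_mix()` fits the companion clustering model: sample `n` belongs to
a latent cluster `c_n ∈ {1..L}` with prior `w`; its mutations are i.i.d.
draws from the cluster's mixture `Σ_i π_{ℓi} e_i(·)` over `K` signatures
shared by all clusters. The log-likelihood (multinomial coefficient
omitted — constant in the parameters) is evaluated in log space with a
log-sum-exp over clusters. EM has two latent levels: cluster
responsibilities per sample, then signature responsibilities per mutation
within each cluster; one iteration costs `O(N·L·K·M)`. The same
10-seed/100+500 protocol, floors, and seed discipline apply; an empty
cluster is floored at `1e-12` and renormalized. With `fixed_signatures`,
`e` is held at a supplied signature set and only `w`, `π` update (refit
mode for scoring reference signatures on new cohorts).

`mix_bic()` scores `p·ln(N) − 2·LL` with
`p = (L−1) + L(K−1) + K(M−1)` free parameters. The observation count is
the number of samples `N` by default, because the likelihood is a product
over samples; whether total mutation count is the better `n` is genuinely
arguable for multinomial data, so it is exposed as
`observations = "mutations"` rather than decided silently.
`bic_grid_select()` trains every `(K, L)` pair and returns the minimizer
with the full table.

**An identifiability caveat** that shapes the recovery tests: the Mix
likelihood depends on the data only through the `L` cluster-level
category mixtures `π_ℓ · e`. With fewer clusters than signatures
(`L < K`) the individual signatures are not identifiable — any `(π, e)`
reproducing the same cluster mixtures is equivalent — even when cluster
assignments are recovered perfectly. The test suite therefore checks
cluster accuracy and weights in an `L = 2, K = 3` regime, but checks
signature recovery (total variation < 0.1) in an `L = K = 3` design where
each cluster is dominated by one signature and the mixtures pin the
signatures down.

## Evaluation utilities

`match_signatures()` mirrors how de novo signatures are conventionally
reported: each learned signature maps to its most-similar reference
signature by cosine; pairs under the threshold (0.7 or 0.8 are the usual
cutoffs; 0.8 default) are dropped; when several learned signatures hit
the same reference, all but the highest-cosine one are flagged duplicates
and excluded from the summed similarity. Matching is greedy per learned
signature, not an optimal assignment — duplicates are information, not an
artifact to optimize away. An exhaustive optimal-assignment mode
(`method = "optimal"`, permutation search, fine for K ≤ 8) exists for the
parameter-recovery harness, where the question is "how close is each true
signature to its best counterpart", not "how would a practitioner report
this".

`effective_k()` answers a question specific to down-sampled simulations:
after thinning, how many of the generating signatures are still visibly
present? Each remaining mutation of category `j` in sample `n` is
attributed to `argmax_k exposure[n,k] · e_k(j)` (ties to the lowest
index, deterministically), attributions are summed over the catalog, and
signatures holding more than 5% of the total count toward the effective
number.

## The synthetic-data generator

The generator produces data with exactly the structure the models assume,
plus the two features of real panel cohorts that stress them:

- `sample_catalog()` draws, per sample, a cluster from the truth's
  weights, a total burden, and categories i.i.d. from the cluster
  mixture.
- Burdens are log-normal by default. The shape `sigma = 1.4` (with the
  arithmetic mean fixed at the nominal burden) was chosen so that a
  panel-like cohort shows 1–3% big patients holding roughly 75–85% of all
  biterms — the regime the big-patient mechanism exists for.
  `burden_fixed()` gives clean multinomial draws for closed-form checks.
- `downsample_catalog()` models panel capture as per-cell binomial
  thinning (optionally category-specific to mimic panel composition
  bias). Real capture is region-based and genome-aware; thinning
  preserves the sparsity statistics that matter to these models but none
  of the genomic locality, so tests passing on thinned data say nothing
  about region-capture bias.
- `sample_biterms()` draws directly from the Btm generative story
  (signature, then two endpoints), incrementing both orientations so the
  matrix convention matches the ordered-pair count.
- Presets: `"panel-like"` (5000 samples, mean burden 7 — the scale of a
  large clinical panel cohort) and `"wgs-like"` (300 samples, burdens in
  the thousands).

What the generator does *not* emulate: sequencing noise and artifact
signatures, correlated signature activities (e.g. clock-like processes
scaling with age), per-sample exposures drawn from continuous simplex
distributions rather than a small number of cluster profiles, and
region-based capture. Recovery results here are therefore best-case
evidence of correct inference, not of robustness to real-data violations.

## Problem sizes and defaults used in validation

The shipped tests and `scripts/acceptance.R` exercise: biterm algebra on
200 random catalogs; brute-force oracle equivalence on instances up to
`M = 6, K = 3` (Btm) and `N = 3, M = 4, L = K = 2` (Mix) at `1e-10`;
600-iteration monotonicity runs; Btm recovery from 10⁶ biterms of three
well-separated signatures (pairwise cosine < 0.3, total-variation
tolerance 0.05); Btm2K on 500-sample, mean-burden-30 cohorts with three
signature-dominant clusters (`T = 10`, candidates 1..6); and Mix
clustering at 200 samples × 50 mutations. These sizes give stable
recovery while keeping a full validation run in minutes on one core;
scaling any of them up is a matter of the corresponding arguments, not of
code changes.

## Known limitations

- Btm has one global exposure vector by design; it does not produce
  per-sample exposures (use Mix, or refit with `fixed_signatures`).
- Gibbs-sampling inference for biterm models is not implemented — EM
  only.
- The likelihood treats biterm counts as independent observations; they
  are not (all pairs of one patient share its mutations), so Btm
  likelihoods are useful for relative comparison, not calibrated
  probabilities.
- MAF/VCF ingestion and genome-aware context extraction are out of
  scope; inputs are pre-tabulated SBS-96 counts.
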