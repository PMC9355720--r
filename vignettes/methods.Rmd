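---
title: "Methods: network propagation with Laplacian-regularized smoothing for lncRNA-disease ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation with Laplacian-regularized smoothing for lncRNA-disease ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birwrls)
```

This vignette documents the model implemented by `birwrls`, the choices
made where the design was genuinely open, and what the synthetic benchmark
does and does not establish.

## The prediction problem

The input is a binary lncRNA × disease matrix `Y` of curated associations
together with a disease ontology (MeSH-style tree numbers). Absent entries
are *unknown*, not verified negatives: curation is sparse, so evaluation is
ranking-based throughout — the question is whether held-out true
associations outrank unobserved pairs, never whether a pair is "truly
negative".

A single orientation is enforced at the type level: lncRNAs are rows,
diseases are columns, in every matrix the package produces or consumes.
Propagation on the lncRNA network therefore always multiplies on the left,
propagation on the disease network on the right.

## Disease semantic similarity

Each disease's tree numbers are closed under dot-prefix truncation to give
its ancestor DAG. Two reconstruction details matter:

* **Term identity.** A code owned by a dataset disease is identified with
  that disease, so all tree numbers of one disease collapse into a single
  node (a descriptor can occupy several positions in the hierarchy; a
  disease reached by two paths has two parents). Codes owned by no dataset
  disease participate as anonymous terms — they still count in ancestor
  intersections and in corpus frequencies.
* **Corpus scope.** The corpus for the information-content statistics
  (`Dags(t)`, and `D` in the denominators) is the loaded dataset, not the
  full MeSH release: the dataset is all the implementation can see. With a
  different corpus the `SV3` contributions change smoothly through
  `beta(t) = (max_k Dags(k) − Dags(t)) / D`.

The default contribution variant is `SV3` (decay `alpha` plus `beta`),
which is the variant the final similarity composes; `SV1` (decay only) and
`SV2` (information content only) are kept as ablation switches. `beta` is
evaluated at the term being scored; evaluating it at the child instead is
exposed as `beta_at_child` but off by default. Contributions are
deliberately *not* clamped when `alpha + beta(t) >= 1` — the recursion is
applied exactly as defined, and the similarity ratio stays in [0, 1]
regardless because shared terms are a subset of each DAG.

When both diseases have semantic value zero (possible only in degenerate
single-disease corpora under `SV2`), the off-diagonal similarity is defined
as 0 and the diagonal forced to 1.

## lncRNA functional similarity

Best-match averaging over associated disease groups. Two decisions:

* An lncRNA whose disease group is empty — which happens routinely after
  cross-validation masking — gets similarity 0 to everything except itself
  (diagonal 1). A message flags the case.
* Inside cross-validation, `Sl` is recomputed from the *masked* training
  matrix. The alternative (computing it once from the full matrix) leaks
  each held-out positive into the training features; the package keeps
  that as an explicit `leak_similarity` switch purely so the inflation is
  demonstrable, and the test suite checks the leaky variant scores higher
  on planted data.

Lookups go directly into the full disease similarity matrix; no
renormalization of the pairwise sub-matrix is applied.

## Unbalanced bi-random walk

Both walks start from `P0 = Y` and iterate a fixed number of steps:
`gamma * S %*% P + (1 - gamma) * Y` on the lncRNA side (right
multiplication by `Sd` on the disease side). Design choices:

* **Similarities are used raw.** Many random-walk-with-restart variants
  row-normalize the transition matrix; these recursions do not, and the
  package follows them literally. Downstream AUC is invariant to the
  resulting overall scale.
* **Fixed step counts, no early stopping.** The step counts are integer
  tuning parameters (`n_l = 31`, `n_d = 1` by default), not convergence
  thresholds. The closed-form fixed point
  `(1 - gamma) (I - gamma S)^{-1} Y` is provided as a convergence oracle
  for testing, valid when `gamma * rho(S) < 1`.
* The default `gamma = 0.001` makes the propagation term small relative to
  the `(1 - gamma) Y` restart. That is the published operating point and
  the implementation does not "correct" it; most of the ranking signal for
  unseen pairs then comes from the smoothing kernels, which is visible in
  the reduction identities (with identity kernels and `gamma -> 0` the
  scores collapse to `Y`).

## Laplacian-regularized least-squares smoothing

With `M = diag(rowSums(S))`, the symmetric normalized Laplacian is
`L = M^{-1/2} (M - S) M^{-1/2}` (positive semidefinite; zero when `S = I`).
The smoothing kernel `K = S (S + eta L S)^{-1}` is the closed-form
minimizer of the regularized objective
`||Y - S a||_F^2 + eta * tr(a' S L S a)` at `F = S a`; the test suite
verifies this against a generic numerical minimizer on small fixtures. The
motivating objectives are realized only through this closed form — there is
no iterative optimization path.

Numerical choices:

* Kernels are computed by linear solves, never explicit inverses, and every
  construction is validated by the residual
  `||K (S + eta L S) - S||_F <= 1e-8 ||S||_F`.
* A singular system (possible for degenerate synthetic similarity
  matrices) is retried once with a ridge `1e-10 * trace(S) / n` and a
  warning; silent failure is never an option.
* Ranking exports break score ties by ascending lncRNA name, so all
  outputs are deterministic.

**Operand pairing.** The defining recursions of the two walks and the two
kernels, combined under a single orientation, admit two dimensionally
consistent pairings. The package's default is *cross-space* pairing — the
disease kernel smooths the lncRNA-walk scores along the disease axis
(`P_l %*% t(K_d)`) and the lncRNA kernel smooths the disease-walk scores
(`K_l %*% P_d`) — which preserves the cross-pairing of the method as
described while keeping every product well-defined. `cross_pairing = FALSE`
switches to same-space pairing for sensitivity analysis.

**When to smooth.** Smoothing after every walk step (`per_step`, the
default, reading "at the t-th walking" literally) and smoothing once after
the final step (`final`) are both implemented; with a single step on a
network they coincide on that side, so with the default `n_d = 1` the
choice only affects the lncRNA side.

The fused score is the entrywise mean of the two smoothed walk results.

## Evaluation protocol

5-fold cross-validation at pair granularity: the known positives are
partitioned uniformly at random (fold sizes differ by at most one),
deterministically per seed. Negatives for AUC are all pairs that are zero
in the *full* matrix — the standard choice in this literature, which does
not define a verified negative set. AUC is the normalized Mann–Whitney
statistic computed from midranks (ties count half), which matches
brute-force pair counting exactly. The headline number is the mean of the
per-fold AUCs; the pooled-score AUC is also reported.

## The synthetic benchmark

`default_paperlike_spec()` emulates the *shape* of the curated snapshot
this method family is usually evaluated on: 80 lncRNAs × 150 diseases in 5
planted blocks, with within-block density 0.25 and background 0.01 so the
expected positive count is about 700 (matching the ~5% density of the real
82 × 157 × 701 snapshot). Block members share an ontology ancestor prefix,
so disease semantic similarity genuinely correlates with co-association —
the property the predictor exploits. One integer seed drives the ontology
and the associations through independent derived streams, so changing
association densities never changes the ontology.

The acceptance checks run the benchmark at within-block density 0.5 and
background 0.02, a stronger planted signal appropriate for a pass/fail
recovery criterion, and average cross-validated AUC over several generator
seeds; the test suite additionally uses 30 × 40 instances for the
leakage and determinism properties. These sizes keep the full suite to a
couple of minutes while leaving the planted-signal estimates stable to a
few hundredths of AUC.

What the benchmark does *not* emulate: the real MeSH topology (depth,
branching, and cross-hierarchy descriptors), the long-tailed degree
distribution of curated association databases, and any biological
correlation structure beyond block membership. Passing the planted-signal
criterion therefore shows the pipeline is wired correctly end to end and
recovers block-structured signal; it does not certify the AUC the method
would attain on a particular curated snapshot.

## Known limitations

* Diseases absent from the ontology table cannot be scored; the pipeline
  errors rather than imputing a similarity.
* lncRNA similarity is derived entirely from shared disease associations —
  no sequence or expression features — so lncRNAs with no training
  associations receive uninformative rows and are ranked by the disease
  walk alone.
* Dense matrix algebra throughout: appropriate at the 10^2-scale this
  problem lives at, not for transcriptome-wide matrices.
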