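---
title: "Joint instance and feature selection for multiple-instance learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint instance and feature selection for multiple-instance learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miljifs)
```

## The problem

In drug-activity modelling, the measured activity label belongs to a
*molecule*, but the physical event that produces it involves one (or a few)
of the molecule's many 3D *conformers*. Represented as pharmacophore
fingerprints — fixed-length binary strings whose bits flag matches to
pharmacophore models — a molecule becomes a **bag** of binary **instances**
with a single ±1 label, a classical multiple-instance learning (MIL)
setting. Two questions matter beyond plain bag classification: *which
instances* carry the label (the putative bioactive conformers), and *which
fingerprint bits* discriminate (the putative pharmacophoric features).
`miljifs` answers both jointly by iterating instance-embedded
classification with 1-norm-driven elimination.

## The model

**Instance-embedded mapping.** Every training instance $x^k$
($k = 1,\dots,n$, all bags lined up and re-indexed) is treated as a
candidate *concept target*. A bag $B_i$ is mapped to the vector of its
similarities to all concepts,
$m(B_i) = [\, s(x^1, B_i), \dots, s(x^n, B_i)\,]^T$. Two mappings are
implemented:

* `min_distance` (default): $s(x^k, B_i) = \min_j d(x_{ij}, x^k)$ with $d$
  the Hamming distance. Note this is a **dissimilarity** — small means
  similar — and it is deliberately *not* negated or inverted: the signed
  weights of the linear classifier absorb the orientation.
* `gaussian_max`: $s(x^k, B_i) = \max_j \exp(-\lVert x_{ij} - x^k
  \rVert^2/\sigma^2)$, a genuine similarity in $(0, 1]$; on binary data the
  squared norm equals the Hamming count. `sigma` is a configuration
  constant here, not optimized.

**Sparse linear classification.** In the embedded space a 1-norm
regularized linear classifier (1-norm SVM) is trained by solving the
linear program
$$\min_{w, b, \xi}\ \lambda \sum_k |w_k| + \sum_i \xi_i
  \quad \text{s.t.} \quad y_i\,(w \cdot m(B_i) + b) \ge 1 - \xi_i,\
  \xi_i \ge 0 .$$
The 1-norm penalty drives weights exactly to zero, so the support
$I = \{k : |w^*_k| > \delta\}$ *is* the selected concept set; a bag is
classified by $\hat y = \operatorname{sign}(\sum_{k \in I} w^*_k s(x^k,
B_i) + b^*)$, using the prototypes alone (zero-weight — *void* — concepts
cannot contribute). $\lambda$ is chosen by stratified, seeded
cross-validation at the bag level; ties in mean CV error break toward the
larger (sparser) $\lambda$.

**Instance classification.** Within a bag, the *responsible set* $U$
collects the instances that are nearest neighbors (all argmin ties
retained) of at least one support concept; the rest are *void*. Each
responsible instance receives the contribution
$$g(x_{ij^*}) = \sum_{k \in I_{j^*}} \frac{w^*_k\, s(x^k,
x_{ij^*})}{m^k},$$
where $I_{j^*}$ are the support concepts whose nearest neighbor it is and
$m^k$ counts the bag's instances tied as nearest neighbors of concept $k$.
Dividing by $m^k$ shares each concept's cell among its ties, which yields
the exact conservation identity $\sum_{j^* \in U} g(x_{ij^*}) =
\sum_{k \in I} w^*_k\, s(x^k, B_i)$ — the package's master correctness
oracle, tested to $10^{-9}$. The divisor can be switched off
(`use_mk_factor = FALSE`), in which case conservation fails whenever ties
exist. Instances with $g$ above the threshold $\delta = -b^*/|U|$ are
classified positive, the others negative.

**The selection loop** (`run_jifs`) alternates the two spaces:

1. embed all bags against the current concepts on the current bits;
2. fit the 1-norm classifier at a CV-chosen $\lambda$, record the CV error
   $\mathrm{Err}_n$;
3. shrink the concept set to the support;
4. rank instances within each bag and take the top `k_per_bag` (default 2)
   from each bag with the bag's label;
5. re-fit the 1-norm classifier on those instances in the *original*
   (current) fingerprint space;
6. drop zero-weight bits; repeat until an iteration eliminates no bit.

Iteration 0 is therefore a plain instance-embedded (MILES-style) fit with
no elimination. Finalization either returns the last iteration
(`natural_stop`, the default — backward elimination is the method's
*optional* extra) or the iteration with minimum $\mathrm{Err}_n$
(`backward_elimination` — on ties, the earliest). The two finalizations
trade differently: the minimum-CV iteration usually keeps more features
with better bag-level error estimates, while the natural stop yields the
smallest, purest feature sets. Held-out
bags are evaluated by restricting them to the finalized bits and embedding
them against the finalized concepts from the training data; a bag is never
dropped, even if all its instances are far from every prototype (it then
falls to the intercept).

## Orientation of the ranking — a design decision

The instance-ranking direction in step 4 is the one place where the two
similarity mappings genuinely diverge, and the package makes the choice
explicit. Under a true similarity (`gaussian_max`), concepts
characteristic of positive bags earn *positive* weights, so the instances
with the largest $g$ are the positive evidence: positive bags contribute
their largest-$g$ instances (gated by $g > \delta$), negative bags their
smallest-$g$ ones. Under `min_distance` the feature values are distances,
the weight signs reverse (a concept close to positive bags discriminates
with a *negative* weight), and the same semantic rule maps to the opposite
ordering: ascending $g$ with gate $g < \delta$ for positive bags,
descending for negative ones. Applying the similarity-oriented ordering to
the distance mapping selects, measurably and systematically, the instances
that argue *against* their bag's label: on the default synthetic family
the planted instances all but vanish from the selection (about one
seventh of the base rate), and the second-stage fit then sees no signal.
With the orientation-aware rule the selected positive instances are
strongly enriched for planted ones instead. A literal
`selection_rule = "ascending"` (sort the gated $g$ ascending in every bag
and take the first $k$) is retained for auditability.

## The synthetic study family

No public fingerprint/conformer sets accompany the method, so the package
ships a planted-concept generator (`generate_planted`) emulating the data
regime at desk scale. Defaults, fixed once:

| parameter | default | rationale |
|---|---|---|
| bags | 100 positive + 100 negative | a few hundred molecules, near balanced |
| instances per bag | 4–6 | conformers per molecule, scaled down |
| fingerprint bits | 500 | $10^3$–$10^4$ bits in real exports, scaled down |
| planted patterns | 2 | a couple of binding modes |
| discriminative bits | 20 | a small pharmacophore signature |
| planted instances per positive bag | 1–2 | a minority of conformers are bioactive |
| bit-flip noise on signatures | 0.05 | conformational/fingerprint noise |

Background bits are i.i.d. Bernoulli(0.5) everywhere; positive bags carry
one or two instances whose signature bits follow one of the planted
patterns (each bit flipped with probability 0.05); negative bags are pure
background; planted instances sit at random positions within their bag.
What this family does *not* emulate: the sparsity and heavy bit-bit
correlation of real pharmacophore fingerprints, conformer geometry, or
class imbalance. Passing tests on it show the machinery recovers planted
structure under honest noise; they do not certify performance on real
chemistry. Two consequences of the design are worth knowing when reading
results: (i) with two planted patterns, signature bits on which the
patterns disagree carry no *marginal* signal for a linear model, so only
roughly half the planted bits are linearly recoverable in principle;
(ii) with 480 of 500 bits pure noise, pairwise Hamming distances
concentrate around 250 and the planted signal shifts them by only a few
bits, so iteration 0 (the plain embedded fit) is deliberately
hard — the interesting behavior is the gain across iterations as
elimination concentrates the distances on the signature.

## Numerical choices

* **LP solver.** The hinge-loss 1-norm program is solved exactly by a
  dense primal simplex written for this package (Rcpp/RcppArmadillo): the
  slack columns give a feasible identity starting basis (no Phase I),
  twin columns ($v = -u$, surplus $= -\xi$, $b^- = -b^+$) are stored once,
  pricing is Devex with a Bland anti-cycling fallback, a tiny
  deterministic RHS perturbation breaks the massive ratio-test degeneracy
  of binary designs, and the final basis is re-solved exactly against the
  unperturbed right-hand side, so the reported optimum carries no
  perturbation error. Agreement with an independently coded LP oracle is
  tested to $10^{-6}$ (observed $\sim 10^{-13}$).
* **Support tolerance.** LP vertices carry exact zeros in theory but tiny
  nonzeros in floating point; the support threshold defaults to
  $10^{-8} \max(1, \max_k |w^*_k|)$.
* **Ties.** `sign(0)` resolves to $+1$; ties in instance ranking break
  toward the lower instance index; ties in CV toward the larger
  $\lambda$; ties in backward elimination toward the earlier iteration.
* **Degenerate collapses.** An empty support, an empty selection, or a
  selection too small to cross-validate terminates the loop with a
  recorded `degenerate` stop rather than an error; a `max_iterations`
  safety cap (default 20, absent from the original procedure) guards
  pathological oscillation and is reported when hit.
* **Seeds.** All randomness (fold assignment, generation, splits) is
  seeded; per-iteration fold seeds derive from the configuration seed, so
  a run is bit-reproducible end to end.

## Problem sizes used in the shipped studies

The packaged simulation studies run the full loop on the default family
(200 bags, ~1000 instances, 500 bits) over 10 seeds, and on stratified
3:1 train/test splits over 20 seeds; the worked toy example and all
oracle comparisons are instantaneous. These sizes exercise every stage —
iteration-0 embedded fits with ~1000 concepts, second-stage fits with
~400 selected instances — while keeping a complete run in tens of seconds.

## Known limitations

* On the noise-heavy default family the elimination rarely reaches an
  exact fixed point: a cross-validated 1-norm fit on a few hundred noisy
  instances almost always zeroes *something*, so after the large early
  drops the loop sheds a handful of bits per iteration until the
  second-stage selection becomes too small to cross-validate (a recorded
  `degenerate` stop). The bulk of the elimination is always front-loaded
  in the first iteration; total iteration counts on the default family
  range from about 3 to 10 across seeds rather than staying uniformly
  below six.
* The two-pattern default caps linear feature recovery at the bits the
  patterns agree on (see above); single-pattern families recover nearly
  the full signature.
* `gaussian_max` with a poorly scaled `sigma` compresses all similarities
  toward 0 or 1; choose `sigma` on the scale of typical within-data
  Hamming distances.
* No class-imbalance slack weights in this version; near-balanced designs
  are assumed.
* The LP solver is dense; it is sized for thousands of columns and
  hundreds of rows, not for orders of magnitude beyond.
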