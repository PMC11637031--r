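---
title: "Texture-based MS detection with hybrid SHO/SCA wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based MS detection with hybrid SHO/SCA wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `msfs` implements, the
parameters that matter, the synthetic benchmarks the tests rely on, and the
design decisions taken where the method left room for interpretation.

## The problem

Multiple-sclerosis lesions are hyperintense on T2-weighted and FLAIR MRI,
and their presence changes the texture statistics of a brain slice: the
intensity histogram widens and skews, co-occurrence structure becomes less
homogeneous, and local binary patterns shift. `msfs` turns each slice into a
fixed 286-dimensional texture descriptor, then searches for the small subset
of descriptors that best separates MS from healthy slices with a KNN
classifier — a *wrapper* feature selection driven by a swarm metaheuristic.

## Preprocessing

Images are read from PNG/JPEG, converted to a single channel by the
unweighted channel mean if necessary, resized with bilinear interpolation
(align-corners convention, so identity resizes are exact) and rounded to the
0..255 integer grid. Inter-scan normalization is histogram stretching

$$O(x,y) = \frac{N(x,y) - N_{\min}}{N_{\max} - N_{\min}},$$

after which values are re-quantized to $L$ levels by
$\lfloor v\,(L-1) + 0.5\rfloor$ (round half up, keeping both endpoints
exact). Stretching a constant image is an error rather than silently mapped
to zero: a zero dynamic range would corrupt the entropy and GLCM statistics
downstream. Normalization is a pipeline switch (`feature_config(normalize =)`),
default on; when sources share a scanner it can be disabled to keep raw
intensities. Stretch-then-quantize is idempotent and order-preserving, which
the tests check as invariants.

## The texture descriptor

* **First-order statistics** (6): mean, variance, standard deviation
  (population form, divisor $N$), skewness and kurtosis (standardized third
  and fourth central moments), and Shannon entropy in nats over the $L$-bin
  histogram with $0\ln 0 = 0$, so $0 \le H \le \ln L$. Variance is defined
  as the square of the standard deviation, which keeps the moment set
  mutually consistent; on a constant image the standardized moments are
  0/0 and are returned as 0 so degenerate fixtures remain usable.
* **GLCM features** (6 × 4 = 24): the co-occurrence matrix $G(i,j)$ counts
  ordered (reference, neighbor) intensity pairs at distance $d = 1$ and
  orientation $\theta \in \{0°, 45°, 90°, 135°\}$, normalized to sum to one.
  Contrast $\sum |i-j|^2 G$, dissimilarity $\sum |i-j| G$, homogeneity
  $\sum G/(1+|i-j|^2)$, ASM $\sum G^2$, energy $\sqrt{\mathrm{ASM}}$, and
  correlation from the marginal means and deviations of $G$. Features are
  computed per orientation and concatenated (a flag enables
  angle-averaging); the matrix is asymmetric by default (symmetric
  accumulation behind a flag). When a marginal deviation is zero (constant
  image) correlation is returned as 1 — a constant field is perfectly
  predictable — and flagged.
* **LBP histogram** (256): for each interior pixel, $P = 8$ neighbors on
  the circle of radius $R = 1$ are sampled by bilinear interpolation and the
  sign bits of neighbor-minus-center differences are packed into a code,
  $S(x) = 1$ iff $x \ge 0$; the 256-bin code histogram (normalized) is the
  descriptor. The sign test tolerates interpolation round-off of about
  $10^{-14}$ (threshold $-10^{-6}$, far below the one-level intensity grid),
  so constant regions produce code 255 exactly. The basic 256-bin variant is
  used (not uniform/rotation-invariant codes); a 3×3 Moore-neighborhood mode
  is available behind a flag.

Total: $6 + 24 + 256 = 286$ named features, fixed order
(`fo_* | glcm_<angle>deg_* | lbp_000..lbp_255`).

## The optimizers

All optimizers act on a population of $P$ agents in $[0,1]^{D}$, minimize a
black-box objective, clip every proposal to the bounds, and track the
best-ever agent (the *elite*). Defaults follow the study protocol:
$P = 10$, $T = 50$ iterations, 25 repeated runs.

**Sea-horse optimizer (SHO).** Three phases per iteration:

* *Movement*: with probability ½ (a standard-normal draw $r_1 > 0$) the
  agent spirals around the elite with a Lévy-flight step,
  $x' = x + \mathrm{Levy}(\lambda)\,((x^* - x)\,xyz + x^*)$ where
  $x = \rho\cos\theta$, $y = \rho\sin\theta$, $z = \rho\theta$,
  $\rho = u e^{\theta v}$, $\theta \sim U[0, 2\pi]$ drawn once per agent,
  $u = v = 0.05$; otherwise it drifts by Brownian motion
  $x' = x + \mathrm{rand}\cdot l\,\beta\,(x - \beta x^*)$ with $l = 0.05$
  and $\beta$ the standard-normal density evaluated at a fresh draw per
  coordinate. The Lévy step is $s\,w\sigma/|K|^{1/\lambda}$ with $s = 0.01$,
  $\lambda = 1.5$, $w, K \sim N(0,1)$ and the Mantegna $\sigma$ (outer
  exponent $1/\lambda$; $\sigma(1.5) \approx 0.6966$). A `levy_literal` flag
  switches to the plain un-exponentiated $\sigma \approx 0.5813$ with
  uniform draws.
* *Predation*: $\alpha = (1 - t/T)^{2t/T}$ decays from 1 to 0; a uniform
  draw $r_2 > 0.1$ is a successful hunt,
  $x'' = \alpha((x^* - \mathrm{rand}\,x') + (1-\alpha)x^*)$, otherwise
  $x'' = (1-\alpha)((x' - \mathrm{rand}\,x^*) + \alpha x')$. The threshold
  0.1 (success rate 90%) is used for the branch; a literal reading of the
  branch condition as $r_2 > 0$ would make the failure branch unreachable.
* *Breeding*: agents sorted ascending by fitness; the best
  $\lceil P/2\rceil$ are fathers, the rest mothers; each mother pairs with a
  distinct random father and produces one offspring
  $r_3 f + (1 - r_3) m$, scalar $r_3 \sim U[0,1]$ per pair.

**Sine-cosine algorithm (SCA).** Per coordinate,
$x' = x + b_1 \sin(b_2) |b_3 x^* - x|$ (sine when $b_4 < 0.5$, cosine
otherwise) with the linearly decaying amplitude $b_1 = a - t a/T$, $a = 2$.
The draw ranges are the canonical $b_2 \in [0, 2\pi]$, $b_3 \in [0, 2]$;
with both restricted to $[0,1]$ (a `literal_ranges` flag) the cosine branch
is nearly constant and exploration collapses — benchmark runs with the
literal ranges were uniformly worse, confirming the canonical default.

**SHOSCA hybrids.** `shosca` (full): movement → SCA update (replacing
predation) → breeding. `shosca-motor`: SCA update replaces movement;
predation and breeding retained. `shosca-breeding`: movement → predation,
then the SCA update applied to every agent in place of mating (a
`worst_half_only` flag restricts it to the worse half).

**Selection.** The next generation is the elitist truncation of the pool
*current agents ∪ updated agents ∪ offspring* back to $P$. Retaining the
current agents matters: if only the freshly perturbed agents survive, the
whole population is re-randomized at the current step scale every iteration
and can never settle near the optimum — on the 10-d sphere benchmark the
full hybrid stalls around fitness 0.09 without retention versus about 0.01
with it. Plain SCA instead keeps its canonical unconditional replacement,
with the elite tracked separately. Fitness is evaluated once per iteration
after all position updates; no agent is re-evaluated.

Convergence traces record the best-ever fitness after initialization and
after each iteration (length $T + 1$), so they are non-increasing by
construction and well-defined even for $T = 0$.

### What the sphere benchmark shows — and a known limit

On $f(x) = \sum_d (x_d - 0.5)^2$, $D = 10$, the full hybrid improves the
initial best by one to two orders of magnitude within 50 iterations and
dominates plain SHO, SCA and the other hybrids. Its final precision is,
however, bounded by the SCA perturbation geometry: even with the population
collapsed onto the elite, the update magnitude per coordinate is
$b_1 \sin(b_2) |b_3 x^* - x^*| \approx 0.25\,b_1$ — it does not shrink with
the distance to the optimum — so sub-$10^{-2}$ proposals only appear in the
last few iterations, and final fitness values straddle $10^{-2}$
(roughly half the seeds land below it). This is intrinsic to the update
equations at $a = 2$, $T = 50$; it is irrelevant for binary feature
selection, where positions only matter through the 0.5 threshold.

## Wrapper feature selection

A position binarizes to a mask by strict `> 0.5`. The fitness of a mask is
$\alpha E + (1-\alpha) S/D$ with $\alpha = 0.99$: classification error
dominates, with a small parsimony pressure. $E$ is the error of KNN
(k = 5, Euclidean) trained on the 80% partition and evaluated on the run's
20% held-out partition. The weighting uses the standard complementary form;
a `literal_weights` flag reproduces the alternative reading in which both
terms carry weight $\alpha$, which abandons the error/size balance. An
empty mask scores fitness 1.0 (maximal) without fitting, so empty
selections are always rejected. One agent of the initial population is
seeded at 0.75 in every coordinate, making the full-feature baseline always
reachable and the "selected is no worse than full" property assertable at
the cost of one evaluation.

Each repeated run draws a fresh stratified 80/20 split (seeded
`base_seed + r`); when several algorithms are compared, run $r$ shares its
split seed across algorithms so per-run metrics are paired for the Friedman
test. The reporting classifier (KNN k = 5 by default, or random forest with
100 trees) is configured independently of the fitness classifier, which
stays KNN.

## Evaluation

Accuracy, precision, recall and F1 treat MS (label 1) as the positive
class; denominator-zero cases return flagged zeros, and macro-averaging is
available. Aggregates over runs: pooled mean accuracy (weighted by test-set
size), mean/best/worst fitness, standard deviation with divisor $R-1$, mean
selected size both as a raw count (the headline) and as a fraction of $D$,
and mean wall-clock time (reported, never asserted — hardware-dependent).
The Friedman test ranks algorithms within each run, ties sharing mean
ranks, and uses the tie-corrected chi-square statistic
$12\sum_j (S_j - R(k+1)/2)^2 / (Rk(k+1) - \sum(t^3-t)/(k-1))$ with $k-1$
degrees of freedom; it agrees with `stats::friedman.test`, which the test
suite uses as an independent cross-check. Post-hoc pairwise tests are out
of scope.

## Synthetic benchmarks

**Images.** Each pair shares one background (Gaussian-blurred uniform
field, σ = 3 px, scaled to mid-gray 30–130) and one pixel-noise draw
(σ = 10 levels); the lesioned image adds 2–5 bright elliptical blobs
(semi-axes 4–10 px, +80 levels — kept above twice the noise σ so classes
remain separable by construction). Pairing isolates the lesion signal: with
one blob the images differ only inside it, and the lesioned raw mean is
strictly greater. Default size 128×128 keeps test runtimes modest; 512×512
works unchanged. The generator emulates lesion-like hyperintensities only —
no bias fields, partial-volume effects or sequence-contrast differences —
so green tests demonstrate pipeline mechanics and optimizer behavior, not
clinical performance.

**Tables.** $k$ informative columns are $N(0,1)$ for class 0 and
$N(\delta,1)$ for class 1 ($\delta = 1.5$ by default), the other $D - k$
columns pure noise; column order is shuffled with the informative positions
recorded. At $\delta = 1.5$, $D = 50$, $k = 5$, 150 samples per class, KNN
on the informative columns alone is nearly perfect while the full table is
degraded by noise — the regime where feature selection demonstrably helps.
A deterministic surrogate objective (Hamming distance to a planted mask
plus the size penalty) has the planted mask as unique binary minimizer,
verified exhaustively at $D = 8$.

**Problem sizes in the tests.** Feature oracles run on twenty 8×8 images;
optimizer invariants on the 10-d sphere at the full protocol
($P = 10$, $T = 50$, 10 seeds); recovery on the $D = 50$ table with 10
selection runs; the ordering check with 25 paired runs; the end-to-end
pipeline on forty 128×128 images with $R = 2$, $T = 5$. These sizes keep
the whole suite under a minute while exercising every code path at the
protocol's parameter values.

## Numerical conventions and degenerate inputs

* Quantization: round half up, $\lfloor v(L-1) + 0.5\rfloor$; endpoints exact.
* Constant image: histogram stretch errors; skewness/kurtosis 0; GLCM
  correlation 1 (flagged); LBP code 255 everywhere.
* Lévy step: $|K|$ floored at $10^{-12}$ against underflow.
* Predation at $t = T$: $\alpha = 0$ exactly; the success branch proposes
  the zero vector (clipped), per the published equations.
* Position legality is enforced by clipping to $[0,1]$ after every operator.
* All generators and optimizers are pure functions of their seed; identical
  seeds give bitwise-identical traces, masks and reports.

## Known limitations

* The SCA exploitation floor described above limits continuous-benchmark
  precision at the protocol's iteration budget.
* Wrapper fitness is measured on the same held-out split later used for
  reporting; an optional internal cross-validation mode on the training
  partition avoids the selection bias at extra cost but is off by default
  for protocol fidelity.
* Whale-optimization and Harris-hawk comparators are not implemented; the
  optimizer interface accepts user-supplied drivers with the same signature
  instead.
* DICOM ingestion, skull stripping and slice curation are out of scope; the
  pipeline starts from exported PNG/JPEG slices.
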