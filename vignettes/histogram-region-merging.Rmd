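---
title: "Multilevel thresholding by histogram region merging: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel thresholding by histogram region merging: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histmerge)
```

## The problem

Intensity thresholding splits an 8-bit grayscale image into T + 1 classes by
T gray-level cut points. For MR brain images the intensity distribution is
multimodal — background, cerebrospinal fluid, gray matter, white matter each
contribute a mode — and multilevel thresholding is a cheap first-pass tissue
segmentation. The classical route, maximizing Otsu's between-class variance,
is exhaustive over all C(255, T) threshold tuples and becomes impractical as
T grows. Histogram region merging replaces the global search with a greedy
coarsening of the histogram whose cost is linear in the number of gray levels
and independent of T.

## The model

All quantities live on the 256-bin gray histogram with probabilities
$P_i = n_i / N$ ($n_i$ pixels of gray $i$, $N$ pixels total). A *region* is a
contiguous inclusive gray interval $[lo, hi]$ with

$$\omega = \sum_{i=lo}^{hi} P_i, \qquad
  \mu = \frac{1}{\omega}\sum i P_i, \qquad
  \sigma^2 = \frac{1}{\omega}\sum (i-\mu)^2 P_i, \qquad
  D = \omega\,\sigma^2 .$$

The energy $D$ couples the two things that make a gray range *worth being a
class*: how many pixels it holds ($\omega$) and how much its intensity varies
($\sigma^2$). A region with tiny $D$ is either nearly empty or nearly flat;
either way it carries little segmentation information and should be absorbed.

The algorithm initializes 256 singleton regions (255 thresholds) and
iterates:

1. select the region with minimum $D$;
2. merge it into its lower-energy adjacent region;
3. recompute the merged region's statistics (one energy evaluation — no other
   region's statistics can change).

Each iteration removes exactly one threshold, so a run to T thresholds is
exactly $255 - T$ iterations, at most 255, with at most $256 + 255 = 511$
energy evaluations in total. The package asserts both counts in its test
suite rather than timing hardware.

## Conventions the source description leaves open

Several details are under-determined by a prose description of the scheme;
the package fixes them explicitly, and the no-cache brute-force oracle in the
test suite pins the whole merge sequence down bit-for-bit:

* **Minimum-energy ties** go to the region with the smallest starting gray.
  Ties are common (all singletons start at $D = 0$), and a fixed rule makes
  runs reproducible.
* **Neighbour choice.** "Merge with the adjacent region whose D is smaller"
  is read as *the smaller of the two neighbours*: the selected region is the
  global minimum, so a neighbour with strictly smaller energy cannot exist.
  Equal neighbour energies merge left; regions containing gray 0 or 255 have
  a single neighbour and take it unconditionally.
* **Empty regions** ($\omega = 0$) get $\mu = (lo + hi)/2$, $\sigma^2 = 0$,
  $D = 0$: every statistic stays finite and zero-information regions are
  maximally mergeable, which is the intent of the energy.
* **Singleton regions** are assigned $\sigma^2 = 0$ and $D = 0$ exactly,
  bypassing the $\sum(i-\mu)^2P_i/\omega$ arithmetic. Mathematically that sum
  is zero for one support point, but in floating point $\mu = (i\,P_i)/P_i$
  can differ from $i$ by an ulp, leaving a residue of order $10^{-30}$ —
  harmless as a value, but enough to reorder ties among zero-energy regions
  and destroy determinism across reimplementations.
* **Probabilities, not counts.** Statistics are computed in double precision
  from $P_i$; region energy is invariant under uniform count scaling (a
  tested property).

The same class convention is used everywhere: class $k$ covers grays
$t_{k-1}+1 \dots t_k$, i.e. a pixel of gray $g$ is in class $j$ when
$t_j < g \le t_{j+1}$. The exhaustive Otsu comparator uses it too, so
threshold lists from both methods are directly comparable.

## The exhaustive Otsu comparator

`otsu_exhaustive()` maximizes $\sum_k \omega_k(\mu_k - \mu_G)^2$ over all
strictly increasing tuples in $[0, 254]$, with empty classes permitted
(contributing zero) so the search space is the full combinatorial set. The
search is compiled (Rcpp) because T = 4 already means
$\binom{255}{4} \approx 1.7\times 10^8$ candidates; prefix statistics come
from cumulative sums so each candidate costs O(1). Enumeration is ascending
lexicographic and only a strictly larger objective replaces the incumbent,
so ties resolve to the lexicographically smallest tuple — which matters on
degenerate inputs (a point-mass histogram has a totally flat objective) and
on plateaus across empty bins. The default cap of 4 thresholds is a cost
guard, raisable per call. Correctness is cross-checked two ways: an
independent pure-R 255-scan must reproduce the T = 1 result, and for every
candidate tuple the decomposition
*between-class variance + Σ ω_kσ²_k = global variance* must hold to 1e-9.

## The uniformity score

$$U = 1 - c(P)\,\frac{\sum_j \sum_{i \in R_j} (f_i - \mu_j)^2}
                     {N\,(f_{max} - f_{min})^2}$$

with $P$ thresholds, $f_i$ the gray of pixel $i$ and $\mu_j$ the mean gray of
class $j$ *computed over pixels, not histogram bins*. $U \le 1$, and $U = 1$
exactly when every class is internally constant. The prefactor $c(P)$ is
typeset ambiguously in parts of the literature; the package defaults to
$2(P-1)$ — the most literal grouping — and exposes `prefactor = "2sqrtP"`
(the classical uniformity measure's $2\sqrt{P}$) and `"2P-1"` as documented
variants, since published U values cannot always be attributed to one
reading. Note the degenerate consequence of the default: at $P = 1$ the
prefactor is zero and $U \equiv 1$; comparisons at a fixed $P \ge 2$ are
unaffected because all variants scale the same within-class sum.

## The synthetic generator

`synth_image()` / `synth_histogram()` draw i.i.d. pixels from a 2–5 mode
Gaussian mixture on $[0, 255]$ (rounded, clipped), emulating the multimodal
intensity profile of MR brain slices. Ground truth is the set of *density
valleys* — the integer gray minimizing the analytic mixture density between
consecutive mode means — because valleys, not Bayes boundaries, are what a
histogram-shape method can possibly see (for equal-sd modes the two
coincide). Seeded draws are bit-reproducible and leave the global RNG stream
untouched.

What the generator does **not** emulate: spatial structure of any kind — no
bias field, no partial-volume voxels, no anatomy, no spatial noise
correlation. Passing tests on these fixtures therefore validates the
*histogram-domain* behaviour of the methods; they say nothing about
robustness to intensity inhomogeneity in real scanners.

The canonical benchmark fixtures (`fixture_modes()`) place consecutive modes
exactly 6 sd apart — two modes at 80/170 with sd 15, three at 50/125/200 with
sd 12.5, weights 0.4/0.3/0.3 — at 65,536 pixels. Six sd is the tightest
separation at which the valley is unambiguous, and it was chosen over wider
spacing deliberately: once the inter-mode gap contains zero counts, *any*
threshold inside the gap yields the identical segmentation, the Otsu
objective is flat across the gap, and "distance from the valley" stops being
a meaningful score for either method.

## Known limitation: where the greedy merge puts its thresholds

On these fixtures the exhaustive comparator recovers every valley within a
gray level or two. The merge loop does not, and the mechanism is structural,
not statistical. Mid-run, the loop forms a low-energy region that *straddles*
the valley (sparse pixels from both flanking tails). Near the end that
straddling region is the energy minimum and must merge wholesale into one
neighbouring mode — the algorithm has no way to split it — so the final
threshold lands at the straddler's far *edge*, displaced from the valley
bottom by roughly one mode-sd (~10–20 gray levels on the canonical
fixtures, as the package's reproduction script measures). The resulting
*segmentations* are still good — mean uniformity on four-mode synthetic
images is ≈ 0.98 for the merge method vs ≈ 0.99 for exhaustive Otsu at
T = 3, at a tiny fraction of the search cost — but valley-position recovery
within a ±5 gray-level band is a property this algorithm does not have on
6-sd Gaussian fixtures, and the corresponding recovery check in the
acceptance tests records exactly that. On histograms with sharp, deep
valleys (small within-mode sd), the displacement shrinks with the sd and the
two methods' thresholds approach each other.

## Numerical and testing choices

* Statistics are recomputed *fresh over the union interval* at each merge
  rather than combined incrementally from the two parents; with L = 256 the
  cost is negligible and it keeps one code path for initialization, merging
  and auditing. `audit = TRUE` re-verifies every cached statistic against
  recomputation (tolerance 1e-9) after every step.
* Min-selection is a linear scan over the current regions. A heap would save
  nothing at L = 256 and would obscure the tie-break order; the costed
  operation — energy evaluations — stays ≤ 2·L regardless.
* The test suite's independent oracle re-derives *all* region energies from
  the raw histogram at every iteration (no caching, no incremental state)
  and must reproduce the implementation's full merge trace and its
  thresholds for T ∈ {1,…,5} identically on 200 random histograms; random
  histograms mix sparse (many empty bins) and dense regimes.
* Problem sizes in the routine test run: 200 histograms for oracle
  equivalence, 50 for the cached-statistics audit, 100 seeded replicates per
  fixture family for recovery rates, 65,536-pixel histograms and 128×128
  images — small enough for a laptop run in a few minutes, large enough that
  binomial noise in valley counts is well below the ±5 recovery band.
* Degenerate inputs: empty images, non-8-bit values, all-zero histograms,
  constant images (undefined U), single-region partitions and out-of-range T
  all raise immediate errors with specific messages; multi-channel images
  are rejected rather than silently converted to gray.

## Scope

No >8-bit images (the method is defined on 256 gray levels), no 2-D/spatial
histograms, no alternative energy functionals (entropy, minimum error), no
accelerated or stochastic Otsu variants (recursive lookup tables, particle
swarm) — the exhaustive search is the comparator — and no claim of global
optimality for the greedy merge: its value is the O(L) iteration bound.
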