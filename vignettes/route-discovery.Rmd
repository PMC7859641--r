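---
title: "From paths to routes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paths to routes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routeclust)
```

## The problem

Animals commuting between locations often follow *routes*: common spatial
corridors around which individual *paths* meander. Given a collection of
recorded trajectories — time-ordered planar positions, one sequence per
traversal — we want to know (i) whether the collection splits into distinct
routes at all, (ii) how many, and (iii) which path belongs to which route,
without an experimenter drawing the groups by eye.

`routeclust` answers this with a four-step procedure:

1. **Describe** each trajectory, either by seven *flight characteristics*
   or by its *path similarity* to every other trajectory.
2. **Cluster** the descriptions with Monte Carlo reference-based consensus
   clustering (M3C), which returns a stability score (PAC) and a p-value
   for every candidate number of routes $K$.
3. **Validate** visually with a t-SNE projection of the description space.
4. **Quantify robustness** of the resulting partition to the one free
   preprocessing parameter, the resampling coefficient, with a pairwise
   precision score judged against a random-clustering null.

## Descriptions of a path

### Flight characteristics (7-D)

For a trajectory with positions $(x_t, y_t)$ in mm ($x$ along the tunnel,
$y$ lateral) recorded at `frame_rate` frames/s, `flight_characteristics()`
returns

| quantity | definition | unit |
|---|---|---|
| `mean_speed` | mean per-step displacement × frame rate | mm/s |
| `mean_lateral`, `sd_lateral` | mean / population sd of $y$ | mm |
| `mean_gaze`, `sd_gaze` | circular mean / circular sd of step headings $\alpha_t = \operatorname{atan2}(\Delta y, \Delta x)$ | rad |
| `max_lateral` | maximum signed $y$ | mm |
| `sinuosity` | path length / start-to-end distance | — |

Design notes, where the design was genuinely open:

* **Gaze is a proxy.** Only positions are tracked, so "gaze direction" is
  the instantaneous direction of motion. Insects saccade and sideslip, so
  this under-represents true gaze variability; the column is still a useful
  route discriminator and is labelled as a motion direction throughout.
* **Circular statistics.** Headings live on the circle; the mean is the
  resultant direction and the spread is $\sqrt{-2\ln\bar R}$. A path
  heading alternately $+179°$ and $-179°$ correctly averages to $\pm180°$,
  not $0°$.
* **Population sd (divide by $N$)** everywhere, so small-sample tests are
  exact and the two-trajectory z-score is exactly $\pm 1$.
* **Signed `max_lateral`**, not $\max |y|$: the lateral axis of a tunnel is
  one-sided ($[0, W]$ mm), so the signed maximum is the meaningful extreme.
* Characteristics are computed on the **original** trajectories; the
  equal-arc-length resampling below deliberately destroys speed
  information and is applied only for similarity measures.

`characteristics_matrix()` z-scores each column across trajectories
(zero-variance columns become zeros, with a warning) giving an $N \times 7$
description.

### Path similarity (2N-D)

Trajectories are first resampled to equal arc-length spacing $s$
(`resample_equal_arclength()`): points at arc positions $0, s, 2s, \dots$
along the linearly interpolated polyline, plus the original endpoint. The
default $s = 6$ mm/step matches the pooled median per-frame displacement of
the recorded data this method was developed on; `median_speed()` recomputes
it for any dataset (`resample_set(set, step_mm = NULL)`).

Numerical choices: interpolation is piecewise linear (no overshoot);
repeated positions are collapsed before parameterization; the final
endpoint is always retained even when the last spacing is shorter than $s$,
because both similarity measures anchor the endpoints and start/end define
the route. The alternative — truncating at the last full step — is covered
by the robustness sweep, which shows the partition is insensitive to
spacing details.

Two complementary measures compare resampled paths $A, B$:

* **Dynamic time warping** (`dtw_distance()`): the minimum, over monotone
  alignments pairing both endpoint pairs, of the **summed** Euclidean
  point-pair distances — a *global* measure; every part of both paths
  contributes. The exact $O(|A||B|)$ dynamic program is implemented in
  C++ and is fast enough for all-pairs use at this problem scale;
  `fastdtw_distance()` provides the classic multilevel
  coarsen–project–refine approximation (default radius 10) whose cost is
  that of a feasible warping path and therefore never below the exact
  value.
* **Discrete Fréchet distance** (`frechet_distance()`): the minimax
  coupling cost — the shortest sufficient "leash" — a *local* measure
  dominated by the single worst point of divergence. On equal-arc-length
  resampled paths the discrete value approximates the continuous one to
  within a step.

The point-to-point metric inside both is planar Euclidean distance. DTW
totals are not divided by path length; constant-step resampling keeps
lengths commensurate.

`similarity_description()` min–max normalizes each $N \times N$ distance
matrix to $[0,1]$ **per measure** (a sum and a maximum have incommensurate
scales; whether the original analysis normalized per matrix or globally is
not stated, per-matrix is this package's documented choice) and
concatenates rows: with both measures each trajectory becomes a $2N$-vector.

## Choosing the number of routes (M3C)

For each $K$ in `K_range` (default $2\ldots10$):

1. **Consensus.** `n_consensus_iters` times (default 100): draw
   $\lceil 0.8N \rceil$ trajectories without replacement, partition them
   with PAM (k-medoids, Euclidean in description space; the deterministic
   BUILD initialization plus FastPAM1 swap, so a run is reproducible given
   the subsample), and record co-clustering. The consensus index of a pair
   is (#times co-clustered)/(#times co-subsampled).
2. **PAC.** The proportion of ambiguous clustering is the fraction of pairs
   with consensus in $(U_1, U_2]$, defaults $(0.1, 0.9]$ — the middle
   segment of the consensus CDF. Lower PAC = more stable clustering.
3. **Null.** `simulate_reference()` draws `n_reference_sims` (default 100)
   single-Gaussian datasets whose principal-component variances match the
   observed description matrix; each is consensus-clustered at the same
   $K$, yielding a null PAC distribution under H0 "one cluster".
4. **Test.** One-sided empirical p-value with a pseudocount,
   $p_K = (1 + \#\{\text{null PAC} \le \text{PAC}_K\})/(1 + n_{\rm sims})$,
   so $p$ is never exactly 0 and the smallest attainable value is
   $1/(n_{\rm sims}+1)$ — with the default 100 sims, $1/101 < 0.05$.

Candidate route numbers are Ks whose PAC is a **strict local minimum**
(boundary Ks qualify when lower than their single neighbor) **and**
$p_K < \alpha$ (default 0.05). When several Ks qualify the package reports
*all* of them — disambiguation is intentionally visual (t-SNE +
silhouette), never silent.

Final labels at a given $K$ cut an average-linkage dendrogram of
$1 - \text{consensus}$, so the reported partition reflects exactly the
consensus structure that PAC scored, not one additional PAM run.

The iteration counts (100/0.8/100) are not stated by the original analysis;
they follow the M3C convention and are exposed in `m3c_config()`. The
package's own calibration test verifies that on single-Gaussian data the
per-K rejection rate at $\alpha = 0.05$ stays at or below ~10%.

## Visual validation and the route model

`embed_tsne()` projects the description space to 2D with exact
($\theta = 0$) t-SNE, PCA initialization, perplexity
$\min(30, (N-1)/3)$ and a fixed seed: the embedding arbitrates between
candidate Ks, so run-to-run stability matters more than speed.

`build_route_model()` freezes everything assignment needs: labels, one
medoid per cluster (minimum summed description-space distance), per-cluster
average routes, and the training normalization constants.
`average_route()` resamples each member to exactly $M = 100$ points at
*fractional* arc-length positions $j/(M-1)$ — members differ in length, so
constant-step resampling would not align them — and takes the pointwise
mean. `assign_novel()` describes a new trajectory with the frozen
constants (no re-fit, no leakage) and assigns the cluster of the nearest
medoid, ties deterministically to the lowest cluster index. Inbound and
outbound journeys can be made comparable beforehand with `mirror_path()`.

## Robustness to the resampling coefficient

`resampling_sweep()` reruns resampling → distances → consensus labels for
every $s$ in a range (default $2\ldots11$ mm/step) and compares each
partition, per $K$, with the reference run ($s = 6$) over all unordered
pairs: co-clustered in both = TP, only in the alternative = FP, etc. The
**precision** TP/(TP+FP) is 1 when the alternative never invents a pair the
reference separates. Each precision is judged against
`random_precision_null()`: 100 random clusterings (per draw, $K$ uniform on
$2\ldots10$, trajectories assigned independently and uniformly — empty
clusters allowed, the simplest faithful reading of "randomly assigned"),
with the 95th-percentile critical value and the same pseudocount tail
probability. One seed is shared across $s$ values so differences reflect
$s$, not Monte Carlo noise.

## The synthetic world

`generate_dataset()` plants routes in a $1400 \times 300$ mm tunnel:
per path, waypoints are jittered (sd 10 mm), a smooth centerline is drawn
through them ($x$ linear in the waypoint parameter so monotone corridors
stay monotone; $y$ a cubic spline), and the path walks along it with
per-frame speeds $\mathcal N(6, 1.5^2)$ mm/frame (truncated at 0.5) plus an
AR(1) lateral meander (stationary sd 8 mm, coefficient 0.95). All four
default corridors share the entrance and exit, and their interiors are
separated by ~180 mm — an order of magnitude above the meander sd, i.e.
clearly distinct routes. `default_benchmark()` fixes 4 routes × 20 paths
(seed 2021), matching the scale of the 83-flight dataset the method was
developed on.

What the generator does **not** emulate: tracking noise and dropouts,
collision-shaped detours around individual obstacles, individual identity
effects (synthetic "individuals" are bookkeeping only), altitude, and
inter-route similarity structure subtler than corridor geometry. A green
recovery test therefore establishes that the pipeline finds well-separated
planted structure at realistic scale and noise — not that it resolves
arbitrarily entangled routes in real recordings.

## Degenerate inputs and tie rules

* Sinuosity is undefined for a path that starts and ends at the same point
  (explicit error), and heading statistics need ≥ 3 points.
* A constant distance matrix cannot be min–max normalized (error).
* A pair never co-subsampled across consensus iterations is an error
  advising more iterations, not a silent NA.
* PAC's interval is half-open, $(U_1, U_2]$; values exactly $U_1$ do not
  count as ambiguous, values exactly $U_2$ do.
* PAC ties across neighboring Ks break *against* candidacy (strict minima
  only); assignment ties break to the lowest cluster index; `which.min`
  order makes both deterministic.
* Trajectory files are sorted by frame within id on read; duplicated frame
  indices are a validation error, ids with fewer than 2 rows are skipped
  with a warning. In YAML dialect files the `"y"` key must be quoted
  (YAML 1.1 reads bare `y`/`n` as booleans).

## Known limitations

* DTW and Fréchet compare positions, not movement directions; behaviors
  where the turn sequence matters more than location (escape, search)
  need direction-based measures outside this package's scope, as are
  partial-match measures (LCSS) that tolerate large single deviations.
* The Gaussian reference preserves second-order structure only; heavily
  non-Gaussian single-route data could inflate or deflate the null.
* Consensus clustering at the default Monte Carlo level is the dominant
  cost, $O(|K| \cdot \text{iters} \cdot \text{sims})$ PAM runs; the
  package's tests run at a documented reduced level (50/50, and 25/25 for
  the null-calibration study) to fit a single-CPU budget. All levels are
  configuration, not constants.
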