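---
title: "Edge-modelling CRF segmentation of the left ventricle: model and methods"
author: "lvcrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-modelling CRF segmentation of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short-axis cine MRI shows the left ventricle as a bright blood pool
(endocardium, the *inner contour*) inside a darker myocardial wall whose
outer border — together with the septal border against the right ventricle
— forms the *outer contour*. Both contours must be delineated in every
frame of a cardiac cycle to derive volumes, ejection fraction and mass.
Two features make this hard for purely edge-driven methods: papillary
muscles inside the blood pool share the wall's intensity and obscure the
endocardial border (convention includes them in the inner contour), and
the contrast between wall and surrounding tissue is weak in places. The
approach implemented here treats segmentation as joint inference over the
whole cycle, so that spatial continuity, temporal coherence and the
anatomy of the wall can compensate where the local edge evidence fails.

## Contour representation

Each contour in frame $t$ is a vector of $N$ radii at uniformly spaced
angles around a per-frame centre point $c(t)$, stored as discretised
log-radii
$$\rho_n(t) = \left\lfloor \tfrac{M}{2}\,\log r_n(t) / \log r_\mathrm{init}
\right\rfloor \in \{0,\dots,M-1\},$$
so that a contour at the reference radius $r_\mathrm{init}$ sits at bin
$M/2$ and small radii receive finer resolution. Defaults are $N = 128$
angular directions and $M = 256$ bins with $r_\mathrm{init}$ chosen near
the end-diastolic endocardial radius (50 px for clinical acquisitions).
The log-polar transform $D(t)$ of each frame, sampled bilinearly around
$c(t)$, is the observation the model works on; row $d_n(t)$ is the
intensity profile along angle $2\pi n/N$.

A note on the discretisation constant: the formula above is a
reconstruction. We adopted the normalisation $\tfrac{M}{2\log
r_\mathrm{init}}$ because it is the unique affine-in-$\log r$ map that
satisfies both stated design constraints (bins span $\{0,\dots,M-1\}$ and
the end-diastolic contour sits near $M/2$); alternative constants would
rescale the beam bounds and the wall prior but leave the method unchanged.

## Centre tracking

The user supplies the centre of frame 0, where the blood pool is largest
and least obstructed. Remaining centres minimise a Gaussian-weighted
between-frame alignment error: for consecutive frames, patches around the
two centres are compared pixelwise, weighted by
$\exp(-\lVert c-p\rVert^2/\sigma^2)$ truncated at $2\sigma$. The track is
constrained to integer pixels, steps of at most 2 px per coordinate
(cardiac centre translation between frames is below 3 px), and periodicity
$c(T-1) = c(0)$; dynamic programming over the feasible offset grid finds
the global minimum, with ties broken toward the lexicographically smallest
displacement. We make the endpoint constraint hard (non-$c(0)$ endpoint
states are infeasible) rather than adding a constant penalty, which is
equivalent but independent of the image's cost scale. $\sigma$ defaults to
half the end-diastolic inner radius.

## The CRF

Segmentation is the MAP configuration of a conditional random field over
all $2NT$ radial variables, with energy
$E(\rho) = \sum_q \theta_q f_q(\rho_q, D)$, all features non-negative
(small = good) and all cliques pairwise. The ~14 weight families are, per
contour kind: the edge-classifier unary, spatial and temporal continuity
$((\Delta\rho)/M)^2$, the binary systolic-motion penalty (growth before
end-systole $t_{ES}$, shrinkage after), and two wall-intensity coherence
terms that compare the intensity sampled $\epsilon_\rho$ bins inside the
outer contour (or outside the inner contour) across time and across
adjacent angles; plus two cross families linking the contours at each
angle: the negative log of an empirical wall-thickness prior
$P(\rho^{out}-\rho^{in})$, and the intensity variance of the wall between
the contours.

Numerical conventions worth recording:

* The continuity features are scaled by $1/M^2$ to sit at the same order
  of magnitude as the normalised edge costs; the weights absorb residual
  scale during training.
* The wall-variance feature divides by the wall width $W$ as printed,
  although the sum has $W+1$ terms; the conventional-variance variant
  (divide by $W+1$) is available as `wallVariant = "count"`. The literal
  form is the default and is not shift-invariant in intensity; on
  normalised images the difference is absorbed by its weight.
* The wall-intensity features compare the sample at frame $t$ with the
  sample at frame $t-1$ (taken from the previous frame's row); offsets
  falling outside the bin range are clamped.
* The wall prior is floored at $10^{-6}$ and renormalised so unseen
  thicknesses keep finite cost.
* The systolic feature is defined for $t \ge 1$ only (frame 0 has no
  predecessor), with $t_{ES} = 8$ by default, matching a 20-frame
  clinical cycle; phantom runs set it to the phantom's own end-systole.

## Inference

MAP inference uses min-sum (max-product) loopy belief propagation with a
sequential schedule: per iteration the inner contour's messages sweep the
angular ring forward and back within each frame, then the temporal chain
forward and back for each angle; the outer contour follows, incorporating
inner-to-outer cross messages; outer-to-inner messages flow at the start
of the next iteration (and are refreshed once after the last iteration so
the decode sees the final outer state). Messages are normalised by
subtracting their minimum — without this, costs grow without bound after a
few iterations. Three iterations are the default; we have not observed
oscillation on phantom data. Beam constraints restrict
$|\rho_n(t)-\rho_n(t-1)| \le 25$, $|\rho_n(t)-\rho_{n-1}(t)| \le 2$ and
$\rho^{out}-\rho^{in} \ge$ `minWall` (10 for normal walls; 2, with
$\epsilon_\rho = 1$, for thin-wall cohorts); infeasible transitions carry
a large finite cost rather than being removed, which keeps normalisation
trivial.

Decoding is where loopy BP leaves freedom, and results are sensitive to
it. We recover each frame's contour as an *exact ring optimization*: node
scores combine the unary, the cross term, the actual pairwise cost to the
already-decoded previous frame and the backward temporal message; the
ring is solved exactly by conditioning on the $n=0$ bin (ties to the
smallest bin). Frames are decoded in temporal order; the second contour
is decoded against the first through the actual cross factor, so every
output satisfies the wall constraint exactly — this is the one place we
deviate from fully independent per-contour backtracking, trading a little
independence for a hard guarantee. Both contour orders (inner-first and
outer-first) are decoded and the lower-energy configuration kept.

Because the decoded configuration can still sit in the wrong basin on
graphs with many tight loops, a refinement pass follows: block coordinate
descent in the true energy, where each block is re-solved exactly — one
frame's contour ring, one frame's inner+outer pair moved rigidly (gap
preserved, which escapes traps where the wall prior forbids moving either
contour alone), and a global rigid shift of the entire configuration.
Every accepted move strictly lowers the true energy, so the pass
terminates and never degrades the BP decode. On tiny instances with
model-realistic structure this pipeline matches an exhaustive-enumeration
oracle essentially always; on adversarial uniform-noise instances with
random weights (structure the model was never meant for) it remains a
~75% heuristic, which is the documented price of loopy inference.

## Edge classifiers

Edge evidence comes from 2 kinds × 8 angular groups of deliberately small
classifiers (one hidden layer of two logistic units — the scale is the
point: they are feature detectors, not segmenters). A window of width
$w = M/4$ around bin $\rho$ is reduced to the feature vector
$\kappa(v) = (g, |g|, \operatorname{sign} g, |g|>\epsilon)$ built from
forward differences $g$; $\epsilon$ defaults to 2 intensity units on a
0–255 scale (0.008 for 0–1 images). Windows centred within 2 bins of the
annotated contour are positives; negatives are drawn uniformly beyond 8
bins, one per positive. Direction-dependent groups (16 consecutive angles
each) let the classifiers exploit the sign structure that differs between
the septal and free walls without hand-coding it. Network responses
become costs via $1 - $ response, per-row minimum subtraction and sum
normalisation, then a circular minimum filter of width 3 in the angular
direction erodes isolated false penalties. Training runs 500 optimiser
iterations per network; fewer (~100) leave the weaker outer-contour
classifiers visibly underfitted on phantoms.

## Weight training

The weights $\theta$ are fitted by minimising the symmetric landmark
error (the mean of the two one-sided mean point-to-boundary distances, in
mm) of inferred against annotated contours, summed over training
sequences, plus a weakly weighted regulariser $\lambda \sum_d \log
\theta_d$ ($\lambda = 10^{-3}$). The one-sided error alone rewards jagged
contours, hence the symmetrised form. Inference is a black box inside the
objective — only its output contours are consulted — which sidesteps the
intractable partition function and trains through the *approximate*
inference actually used at test time. Powell's direction-set method (no
gradients; cyclic bidirectional line searches, direction list updated
with each cycle's net displacement) runs in $\log \theta$ so positivity
is structural; evaluations are cached by parameter hash. Full-scale fits
take on the order of 300 evaluations; phantom fits use 100. Note the
regulariser decreases as $\theta_d \to 0$: with small $\lambda$ it acts
as the intended specialisation penalty, gently shrinking weights that
carry no error signal.

The starting point matters more than one might expect. Because each edge
cost row is normalised to sum to one, edge evidence sits at scale $1/M$
per node, while the wall-prior term contributes order-1 values; with
all-ones weights the MAP is a degenerate far-field configuration that
pays only the modal wall thickness and ignores the image. The default
start (`initialTheta`) therefore scale-matches the families — edge
weights at $M/4$, the wall-prior weight at $0.1$, everything else at 1 —
and Powell refines the balance from a model that already segments.

One convention deserves a flag: the systolic-motion feature switches to
penalising shrinkage at $t \ge t_{ES}$, so the contraction *into* the
end-systolic frame itself would be penalised if $t_{ES}$ named the
minimum-radius frame. The CRF's $t_{ES}$ is therefore the first frame
treated as diastolic — one past the frame of maximum contraction.

## The phantom

The synthetic cine phantom provides exact ground truth for every stage: a
bright blood disc whose radius contracts strictly to end-systole
($t_{ES} \approx T/2$) and re-expands, a darker wall annulus whose outer
border contracts about a third as much (so the wall thickens at
end-systole), an intermediate background, papillary-muscle blobs placed
on one side of the blood pool against the endocardial border (one-sided
so direction-dependent classifiers face asymmetry), a smooth periodic
centre drift of at most 2 px/frame, and additive Gaussian noise. Discs
are rasterized with a 1 px linear boundary ramp so gradients are finite
and classifier windows see realistic edge profiles. Defaults: 96 px
images, $T = 12$ frames, end-diastolic inner radius 24 px, wall 8 px,
contraction 35%, two blobs of radius 3.5 px at −40° and 25°, noise 0.035
(5% of the blood–wall contrast), intensities blood 0.9 / wall 0.2 /
background 0.55. A `"hypertrophy"` preset (14 px pool, 18 px wall, 72%
contraction) reproduces the known failure mode where the blood pool all
but vanishes at end-systole.

What the phantom does *not* emulate: MRI bias fields, through-plane
motion, partial-volume effects at the apex, intensity inhomogeneity
between acquisitions, or annotation inconsistency. Passing the phantom
study therefore demonstrates that the machinery — features, propagation,
decoding, training — is implemented coherently, not that clinical
accuracy figures transfer.

## Problem sizes and study design

The self-contained phantom study (`runPhantomStudy`) trains the
classifier bank and wall prior on 3 phantom sequences, fits $\theta$ with
a 100-evaluation Powell budget, and evaluates on 3 held-out phantoms
through the full pipeline (centre tracking from the rounded true frame-0
centre, log-polar transform, BP). It runs at $N = 64$, $M = 128$,
$r_\mathrm{init} = 24$ — half the clinical angular resolution and bin
count, matched to the phantom's 24 px radius so truth sits at bin $M/2$
at end-diastole, with `minWall = 4` bins (the phantom wall spans ~6–13
bins over the cycle). Where short sequences are used (e.g. $T = 6$ for
centre-tracking studies), the per-frame contraction is kept at the pace
of a full-length cycle, because compressing a whole systolic excursion
into three frame intervals produces frame-to-frame boundary motion that
no clinical acquisition exhibits and that biases patch-based alignment.

## Known limitations

* Loopy BP carries no optimality guarantee; the refinement pass bounds
  the damage but adversarially frustrated instances can still decode
  above the global minimum.
* The centre tracker assumes the structure around the centre translates;
  strong contraction with one-sided structure induces a small systematic
  pull (about a pixel on phantoms at clinical motion rates).
* $t_{ES}$ is fixed per sequence, not inferred; pathologies that shift
  end-systole degrade the systolic-motion feature.
* A disappearing blood pool (severe hypertrophy) violates the assumption
  that the inner contour exists in every frame; the hypertrophy preset
  exists to exercise exactly this mode.
* The wall prior is a global histogram; per-patient priors would adapt
  poorly to cohorts mixing normal and heart-failure anatomy unless
  refitted.
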