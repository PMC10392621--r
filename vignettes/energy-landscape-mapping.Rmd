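---
title: "Mapping folding energy landscapes with foldscape"
author: "foldscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping folding energy landscapes with foldscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
set.seed(1)
```

foldscape analyses the folding of repeat proteins — chains built from
tandem copies of a structural unit — through three connected lenses:

1. **Structural metrics** that score how native-like a conformation is,
   globally and per repeat.
2. **A low-dimensional visualisation** of conformational ensembles that
   preserves pairwise structural dissimilarity, so that parallel folding
   routes appear as separate branches.
3. **Thermodynamics and kinetics**: free-energy profiles along a folding
   coordinate from umbrella sampling via WHAM, melting curves, and
   commitment (folding-probability) estimates.

Because real simulation data is bulky, the package ships a fully
deterministic synthetic generator — a three-repeat toy solenoid with a
coarse-grained structure-based energy function and Langevin dynamics — so
every method can be exercised, and tested against ground truth, in
seconds.

```{r load}
library(foldscape)
```

## The structural metrics

All metrics operate on Cα coordinate matrices (`Conformation` objects,
Ångström units).

**Pair similarity `q`.** For two conformations $a$ and $b$,

$$q(a,b) = \frac{1}{N_p}\sum_{(i,j)} \exp\!\left[
  -\frac{(r^a_{ij}-r^b_{ij})^2}{2\sigma_{ij}^2}\right],
  \qquad \sigma_{ij} = \sigma_0\,|i-j|^{0.15},$$

summed over residue pairs with $|i-j| \ge 3$. The sequence-dependent
width $\sigma_{ij}$ loosens the comparison for long-range pairs. `qw`
is this similarity against the native structure; `localQ` restricts the
sum to pairs touching a chosen residue window (for per-repeat order
parameters), and `dissimilarityMatrix` computes $\delta = 1 - q$ for all
frame pairs of an ensemble.

**Fraction of native contacts `Q_o`.** Native contacts are residue
pairs with $|i-j| > 3$ closer than 12 Å in the native structure
(`buildContactSet`). Each contact contributes a smoothed step

$$\frac{1}{1+\exp[\beta_0 (r_{ij} - \lambda r^0_{ij})]},$$

with $\beta_0 = 5\,\text{Å}^{-1}$ and $\lambda = 1.2$, so a contact at
exactly $1.2\,r^0$ scores one half. `localFractionNativeContacts`
returns the per-residue profile.

```{r metrics}
nat <- buildToyNative(3L, 15L)
X <- coords(nat) + matrix(rnorm(135, sd = 0.4), ncol = 3)
c(qw = qw(conformation(X), nat),
  qo = fractionNativeContacts(conformation(X), nat))
```

A practical subtlety: the per-repeat `localQ` of a *perfectly folded*
repeat whose neighbours are disordered is far below 1, because the
window's pair list includes interface pairs with the disordered
neighbour. Per-repeat values are therefore best read comparatively
(repeat 1 versus repeat 3), not against an absolute scale.

## Ensemble visualisation

`elvim()` composes two steps:

* **Leader clustering** (`reduceRepresentatives`): frames within a
  dissimilarity `cutoff` of an existing representative are absorbed by
  it; otherwise they found a new cluster. This is a single-pass, order-
  dependent but deterministic reduction that caps the problem size.
* **Stress majorisation** (`embedDissimilarity`): representatives are
  embedded in the plane by SMACOF/Guttman iterations (in C++),
  minimising the normalised squared stress
  $\sum (\delta_{kl} - d_{kl})^2 / \sum \delta_{kl}^2$.
  Majorisation guarantees a monotonically non-increasing stress trace;
  multiple seeded restarts (`nStarts`) guard against local minima.

```{r embed}
eN <- routeEnsemble(nat, routeSpec(1:3), 60, seed = 11L, stages = 1:2)
eC <- routeEnsemble(nat, routeSpec(3:1), 60, seed = 12L, stages = 1:2)
proj <- elvim(ensemble(c(frames(eN), frames(eC))), seed = 3L)
plot(coords(proj), col = rep(c("#1b6ca8", "#c0392b"), each = 60),
     pch = 19, cex = 0.7, xlab = "dim 1", ylab = "dim 2",
     main = "Two folding routes separate in the embedding")
```

`augmentReactionAxis` attaches a reaction coordinate (for example `qw`)
to each embedded point so branches can be read as progress along
folding; `selectRegion` picks frames inside a polygon drawn on the map
and `regionContactMap` summarises their contacts.

## Free energies

`wham()` implements single-temperature binned WHAM for umbrella-sampled
windows: the self-consistent equations for the window free energies are
iterated to convergence (first window pinned to zero as the gauge), and
a warning is raised when windows do not overlap enough to tie the
profile together. `histogramFreeEnergy` is the unbiased special case.
Choose the number of bins so each occupied bin holds on the order of 30
samples or more; finer binning trades statistical noise for resolution.

`umbrellaScan` runs the toy model with a harmonic bias on `qw` at a
ladder of centres; `meltScan` plus `meltingCurve` estimate the folding
temperature from the midpoint of mean `qw` versus temperature, using a
bounded logistic fit cross-checked against (and, if implausible,
replaced by) a monotone-interpolation midpoint.

## The synthetic generator

`buildToyNative` constructs a three-repeat solenoid of β-hairpin-like
units (15 residues per repeat). The strand-to-strand spacing *tapers*
from the first repeat to the third, so repeat 3 is more tightly packed
and carries more intra-repeat contacts than repeat 1 (16/21/25 with the
defaults). This deliberate asymmetry gives the two folding directions
distinguishable contact signatures.

`routeEnsemble` generates frames along a folding *route* (an ordering
of the repeats): at stage $k$, the first $k$ repeats of the route are
native-like and the rest are self-avoiding stiffened coil. Fractional
stages interpolate by zipping the next repeat partway. `mixtureEnsemble`
mixes routes with given weights — the setting where *apparent
backtracking* arises: averaging two routes makes some residues' contact
probability non-monotonic in the global folding coordinate even though
each route is monotonic. `detectBacktracking` flags exactly this
signature on a `foldingHeatmap`, and should stay silent on either pure
route. `frayedEnsemble` plants terminal-repeat fraying at a known rate
for testing `frayingProfile`.

The energy function (`goEnergy`, `langevinRun`) is an additive
structure-based model: harmonic backbone bonds, Gaussian wells on
native contacts, and soft excluded volume, integrated by overdamped
Euler–Maruyama dynamics at reduced temperature $kT = T/300$.

Two caveats worth knowing:

* The additive model has **no explicit cooperativity**, so its melting
  transition is broader than a real repeat protein's.
* The smoothed $Q_o$ credits contacts at $r < 1.2 r^0$ during
  collapse, so on short timescales a compact disordered chain can gain
  $Q_o$ quickly without being committed. Commitment analyses should
  use low temperatures and budgets long enough to distinguish downhill
  completion from diffusive search (see `commitment`).

## Commitment

`commitment` launches seeded, unbiased trajectories from given starting
conformations and reports the fraction that reach a `threshold` in
$Q_o$ within a step `budget`, with Clopper–Pearson confidence
intervals. On the toy model, native seeds commit with probability one,
high-temperature coil seeds essentially never do, and seeds further
along a route commit more often than seeds earlier on the same route —
the classic ordering test for a putative transition-state region.

## Session info

```{r session}
sessionInfo()
```
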