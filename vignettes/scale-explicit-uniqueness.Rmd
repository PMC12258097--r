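---
title: "Scale-explicit phylogenetic uniqueness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-explicit phylogenetic uniqueness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(evoscape)
```

## The problem

A site's conservation value depends not only on how many species it holds,
but on how irreplaceable its community is: could the same set of lineages be
conserved somewhere else? Phylogenetic endemism (PE) captures part of this —
branch length weighted by the inverse of its geographic range — but it is a
single number per site that ignores *where* the alternatives are. Two sites
can have identical average uniqueness for entirely different reasons: one is
surrounded by similar communities and only becomes distinct at continental
distances, the other has no similar community even next door. `evoscape`
separates these cases by modelling, for every focal site, how its
phylogenetic dissimilarity to other sites grows with geographic distance.

## The dissimilarity index

The building block is an asymmetric, branch-length-based dissimilarity: the
proportion of the focal community's branch length not shared with a
comparison community,

d(focal, other) = PD_unique / PD_total,

where PD_total is the total branch length of the focal community's branch
set and PD_unique the part of it absent from the other community's branch
set. A community's branch set is *root-inclusive*: every edge on the path
from each present tip to the root of the full tree. This convention makes
deep branches count as shared when two communities both contain descendants
of them, reduces the index to the classical taxonomic Ruggiero proportion
|focal \\ other| / |focal| on equal-branch star trees, and makes the PE sum
identity exact (see below). The index is deliberately asymmetric — the
question is what fraction of the *focal* site's evolutionary history is
unprotected elsewhere — so pairwise values live in a square matrix with
focal sites as rows, not a triangular distance matrix. The row mean
(excluding the diagonal) is the site's average phylogenetic uniqueness.

```{r}
tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
rug_pair_phylo(tr, c("A", "B"), c("A", "C"))  # 1/3
rug_pair_phylo(tr, c("A", "C"), c("A", "B"))  # 0.5: not symmetric
```

All n^2 pairs are computed from a single sites-by-edges incidence matrix
(an edge is in a site's branch set iff the site holds a descendant tip), so
the shared branch length of every pair is one matrix product; `rug_row()`
provides a streaming per-focal-row mode when the full n^2 matrix does not
fit in memory.

## Phylogenetic endemism

PE follows the Rosauer definition: for each site, the sum over its branch
set of branch length divided by the branch's range size, where range size
counts the sites whose branch set contains the branch. Because every
branch's contributions across sites sum to its full length, total PE over
all sites equals the PD of the union of the occupied sites — an identity the
test suite asserts to 1e-9 relative tolerance and that the root-inclusive
convention makes exact.

To compare PE with average uniqueness on a common scale, both are min-max
standardised to [0, 1] over the analysed sites and their difference is
regressed on log species richness (natural log; the base only rescales the
slope, not r²). Min-max over observed sites (rather than division by the
maximum) was chosen because the two quantities have unrelated units and
offsets; the degenerate constant-vector case standardises to zeros with a
warning rather than an error.

## Distance-increase models

For each focal site the dissimilarities d of its matrix row are modelled
against geodesic distance s (km) as a negative exponential,

d = 1 − a·exp(b·s),

fitted as a Gaussian GLM with log link on the similarities y = 1 − d, i.e.
E[y] = exp(log a + b·s), by iteratively reweighted least squares. Starting
values come from ordinary least squares of log(y) on s, with y clipped to
[1e-10, 1] for the initialisation only (pairs with d = 1 would otherwise
destroy the log); the IRLS itself uses the unclipped similarities, and with
a Gaussian error family it minimises the same squared-error objective as a
nonlinear least-squares fit of y = a·exp(b·s), with which it agrees to
1e-4 on well-conditioned inputs in the test suite. Convergence is declared
at a relative deviance change below 1e-8 within 100 iterations;
non-convergence is reported as a flag, never an exception, so one
pathological site cannot abort a landscape-wide analysis.

Two derived metrics drive the classification:

* **dissimilarity intercept** = 1 − a: the dissimilarity extrapolated to
  zero distance — high values mean the site is unique even to its nearest
  neighbours;
* **slope metric** = −b: the initial relative rate at which similarity
  decays (equivalently, how fast dissimilarity accrues with distance).

The model's `a` is a similarity-scale multiplier; because usage of
"intercept" and "slope" differs between the similarity and dissimilarity
parameterisations, both (a, b) and (1 − a, −b) are reported in the fit
table, and the classification uses the dissimilarity-scale pair. `b` is not
constrained to be negative: a positive fitted `b` (dissimilarity decreasing
with distance) is legitimate output and simply flags an unusual site.
Distances default to haversine great circles on the mean-radius sphere
(R = 6371.0088 km), with WGS84 ellipsoidal geodesics behind a flag; the two
differ by under 0.6% and the slope b is per km.

## Hills and islands

Among the sites in the top quartile of PE, those in the top quartile of the
slope metric are **evolutionary hills** (distinct only at large distances —
gradual, distance-dependent differentiation) and those in the top quartile
of the dissimilarity intercept are **evolutionary islands** (distinct even
at the shortest distances — long-term isolation); sites top-quartile in
both are labelled `both`, and everything else `neither`. Quartile
thresholds use linear-interpolation percentiles (R's default type 7), with
ties at the threshold included, and are computed over *all* analysed sites
by default; a documented switch (`reference = "top_pe"`) restricts the
reference population to the top-PE sites, since either reading of the
procedure is defensible. Unconverged fits are excluded from the quartile
computation and labelled `neither` with a warning.

Group contrasts between hills and islands (species richness, PE per
species, EDGE score per species) use two-sided Wilcoxon rank-sum tests in
the normal approximation with tie and continuity correction — group sizes
in realistic landscapes are far beyond the exact-enumeration regime. Sites
labelled `both` are excluded from the two contrast groups by default
(`include_both = TRUE` pools them into each), since the groups are meant to
contrast the two mechanisms.

## Prioritisation curves

`accumulation_curve()` orders sites by a per-site criterion (descending;
ties broken by ascending site id for determinism) and grows the union
branch set incrementally, reporting the fraction of total PD covered at
each prefix. The denominator is the PD of the union of all *analysed* sites
(after the richness filter), so every curve ends at exactly 1. One point is
emitted per site — no binning. The six standard criteria are richness, PD,
PE, uniqueness, EDGE-score sum and EDGE richness; EDGE scores and flags are
caller-supplied inputs. These curves rank fixed orderings; they are not
complementarity-based reserve-selection algorithms and should not be read
as such.

## Synthetic landscapes

`generate_landscape()` produces the structures the analysis assumes, with
known ground truth:

* a pure-birth (Yule) tree over the species pool;
* a square lattice of site centroids in degree space (default 10 × 10 over
  30°, chosen so inter-site distances span roughly 300-4000 km, the range
  over which a per-km slope of order 1e-3 is identifiable);
* circular species ranges with uniform radii (default 5-15°, giving a
  median richness of ~25-30 species per site and leaving at most a few
  edge sites below the 5-species filter), whose overlap creates
  distance decay of similarity;
* a latitudinal shrinkage of range radii (to 40% at the far edge) — a
  spatial turnover gradient whose small-range band behaves like
  evolutionary hills and is labelled `hill` ground truth;
* planted island sites (default 3, mutually separated by at least a third
  of the extent) holding a private endemic clade. Each clade tip becomes
  exclusive to its island with probability equal to the isolation strength
  (default 0.9), and widespread species are thinned from the island with
  the same probability.

The endemic clade is chosen deterministically as the free clade of 8-24
tips with the greatest *private* branch length (crown plus stem). An early
variant picked the smallest clade of sufficient size, but in a Yule tree
that is almost always a shallow recent radiation whose private branch
length is negligible next to the deep root paths shared by the island's
remaining widespread species — the planted sites then carried no
zero-distance uniqueness signature at all. Long-term isolation means an old
lineage, and the generator now plants one; with full isolation the island's
dissimilarity to every other site is bounded below by the private clade's
share of the island's PD, a bound the tests assert by construction.

What the generator does *not* emulate: real range shapes and
irregular occupancy, latitudinal richness gradients beyond the turnover
gradient, tree shape beyond the Yule model, abundance, or detection error.
Passing tests therefore demonstrate correctness of the computations and
recoverability of planted structure under idealised geometry, not that any
particular empirical landscape contains hills or islands.

Species scores are terminal branch length with multiplicative lognormal
noise (sd 0.4 on the log scale), top decile flagged — a stand-in with the
correlation structure of evolutionary-distinctiveness-based scores.

All generators are deterministic given the recipe seed; the tree uses the
seed itself, the landscape draws use seed + 1 and the default score seed is
seed + 2, so the components are independently reproducible.

## Numerical choices and degenerate inputs

* Branch lengths of exactly 0 are allowed; they stay in branch sets and
  contribute nothing. A focal community whose branch set has zero total
  length has no defined dissimilarity and is an error.
* An unrooted newick (basal multifurcation) is accepted with a warning; the
  basal node is treated as the root. Polytomies are never binarised.
* A fit with all d = 1 (no similarity anywhere) is degenerate and raises an
  error in the single-site function; the per-landscape driver records it as
  a failed row instead of aborting.
* Pairs at zero geographic distance (duplicate coordinates) are dropped
  from fits with a warning — they are uninformative for a log-link model.
* Matrix CSVs are written with 15 significant digits so write/read round
  trips preserve values to full double precision.
* Tie-breaks: accumulation ordering is descending score then ascending site
  id; quartile flags include ties at the threshold.

## Problem sizes in the test suite

The suite validates against brute-force oracles on trees of up to 12 tips
(where exhaustive path-union arithmetic is feasible) and runs the
end-to-end planted-structure analysis on 20 landscapes of 100 sites x 200
species, the size at which the default recipe's spatial structure is
well-resolved while the full suite stays fast; parameter-recovery
simulations use 200 replicates of 500 pairs.
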