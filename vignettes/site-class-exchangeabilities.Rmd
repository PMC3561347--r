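---
title: "Site classes and class-specific amino-acid exchangeabilities"
author: "aaSiteClass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site classes and class-specific amino-acid exchangeabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaSiteClass)
```

## The problem

A single empirical exchangeability matrix (mtMam, mtREV24, WAG, ...)
applied to every column of a protein alignment asserts that all sites
face the same evolutionary constraints.  Folded proteins contradict this:
buried hydrophobic cores, surface loops and helix caps tolerate different
sets of residues, so the pattern of acceptable replacements - not just
the overall rate - varies along the sequence.  This package implements a
pipeline for discovering such site classes in an amino-acid alignment and
quantifying how strongly their substitution processes differ:

1. every alignment column is summarized by the mean of nine
   physiochemical property scales over its residues;
2. sites are grouped by K-means on these 9-dimensional profiles, with the
   number of groups chosen by the gap statistic's 1-standard-error rule;
3. a full 20x20 reversible exchangeability matrix is estimated for each
   group by maximum likelihood on a fixed tree topology;
4. the class structure is validated by a random-partition noise analysis
   and by 50% likelihood cross-validation.

## Site profiles

The nine property scales (`kideraTable()`) are near-orthogonal factors
distilled from 188 published amino-acid property measures: P1 bulk,
P2-P4 hydrophobicity, P5-P6 beta-structure preference, P7 alpha-helix
preference, P8-P9 bend preference.  Each scale is centered across the 20
residues, so a column of "average" composition sits near the origin.

A site's profile is the plain mean of the property rows of its observed
residues.  Gaps (`-`, `.`, `?`) and ambiguity codes (X, B, Z, J, U, O)
are excluded from both numerator and denominator: curated alignments
carry them as "no information", and expanding an ambiguity code into its
possible residues would give invented observations the same weight as
real ones.  A stop codon symbol is treated as a format error rather than
data.  Columns with no canonical residue at all are rejected with their
indices listed, since a mean over nothing is undefined.

```{r}
siteProfile(c("A", "V", "-"))
```

## Choosing the number of classes

Sites are clustered with Hartigan-Wong K-means on the n x 9 profile
matrix.  K-means only finds a local optimum, so every fit is the best of
many random initializations (default 1000 for the observed data); ties
break toward the earlier restart, which makes runs reproducible from one
seed.  Classes are always relabelled by decreasing size, so class 1 is
the largest.

The number of classes is selected by the gap statistic: the pooled
within-class dispersion $W_k$ of the data is compared with its
expectation under a reference null that is uniform over the data's
bounding box *in the right-singular-vector basis* - a shape-aware null
that follows the orientation and extent of the observed cloud:

$$\mathrm{Gap}(k) = \tfrac{1}{B}\sum_b \log W^{*}_{kb} - \log W_k,
\qquad s_k = \mathrm{sd}_b\!\left(\log W^{*}_{kb}\right)\sqrt{1 + 1/B},$$

with $B = 100$ reference draws by default.  The selected $k$ is the
smallest one with $\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$
(the 1-standard-error rule).  $k = 1$ is always evaluated so "no
structure" is an expressible outcome; when no $k$ satisfies the rule the
largest evaluated $k$ is returned with `ruleSatisfied = FALSE` and a
warning.  Reference fits use fewer restarts (default 25) than the
observed data: the reference curve is an average over $B$ draws, so
per-draw optimization error largely cancels, while the observed $W_k$
enters alone.

```{r}
selectK(list(k = 2:4, gap = c(0.5980, 0.6371, 0.6209),
             sk = c(0.0087, 0.0073, 0.0066)))
```

## The substitution model and its likelihood

Each class's process is a reversible 20-state Markov model
$Q = R\,\mathrm{diag}(\pi)$: $R$ is the symmetric matrix of
exchangeabilities $\rho_{ij}$ (190 pairs, zero diagonal) and $\pi$ the
equilibrium frequencies, always estimated empirically from the data
subset (with a $10^{-6}$ pseudocount per residue, because some classes
are dominated by a handful of amino acids and the remaining frequencies
would otherwise be exactly zero).  $Q$ is rescaled to mean rate one, so
branch lengths are expected substitutions per site; as a consequence the
likelihood is invariant to the overall scale of $R$, and fitted matrices
are emitted on the mean-rate-one scale.

The log-likelihood on a fixed topology is computed by Felsenstein
pruning over compressed site patterns, with per-node rescaling against
underflow; transition matrices come from the symmetric eigendecomposition
of $\mathrm{diag}(\sqrt{\pi})\,Q\,\mathrm{diag}(1/\sqrt{\pi})$.  By
reversibility the value does not depend on root placement, which the
tests exercise directly, along with a brute-force oracle that enumerates
all internal-state combinations on trees of up to five taxa.

### Optimization

All 189 free exchangeabilities (one pair is fixed at 1; see below) are
optimized on the log scale by bounded quasi-Newton (L-BFGS-B), either

* jointly with all log branch lengths (`method = "joint"`), or
* cyclically, alternating branch-length and exchangeability phases until
  the cycle-to-cycle gain drops below 0.01 log units
  (`method = "cyclic"`),

and every supplied starting matrix is run with every requested method,
the best final likelihood winning.  Both phases use the analytic
gradient of the pruning likelihood: the derivative of each transition
matrix follows from the eigendecomposition
($\partial P/\partial\theta = V (H \circ \Phi) V^{-1}$ with
$\Phi_{kl} = (e^{\lambda_k t} - e^{\lambda_l t})/(\lambda_k - \lambda_l)$),
and per-edge "flow" matrices collected in one upward pass turn the whole
189 + branches gradient into a handful of 20x20 matrix products per
edge.  A gradient evaluation therefore costs about as much as two
likelihood evaluations, which is what makes 189-parameter fits routine
on a desk machine; the test suite checks the analytic gradient against
central finite differences.

Branch lengths are optimized by the same bounded quasi-Newton scheme
over log branch lengths, iterated until the per-pass improvement falls
below the tolerance.  This replaces literal one-branch-at-a-time line
searches: with an analytic gradient the joint update converges in far
fewer likelihood evaluations and satisfies the same contract (monotone
log-likelihood, same tolerance).  Branch lengths are bounded below by
$10^{-8}$ to keep $P(t)$ well conditioned.

Numerical safeguards worth knowing about:

* **Identifiability anchor.**  Exchangeabilities are only defined up to
  a common factor, so one reference pair is held at 1 during
  optimization.  The anchor defaults to the pair of the two most
  abundant residues in the subset.  A fixed conventional anchor such as
  Trp-Val fails on sparse subsets: when the anchor residue is absent
  its exchangeability is uninformed, and fixing an uninformed value at 1
  puts the whole matrix on an arbitrary scale that the box bounds
  ($[10^{-6}, 10^3]$ by default) then clip.
* **Uninformed pairs.**  Pairs involving a residue with zero
  observations in the subset are pinned at their starting values during
  optimization and reported at the starting matrix's normalized values,
  flagged in the `nonIdentifiable` slot.  The likelihood is flat along
  these directions, and quasi-Newton line searches would otherwise park
  them anywhere between the bounds - pure noise that would contaminate
  matrix distances.
* **Underflow.**  Where a proposed parameter vector drives some site
  likelihood to zero, the objective returns a large finite penalty so
  the line search backtracks instead of aborting.

### Branch-length scale factors

As the constrained alternative to free per-class branch lengths,
`fitBranchScale()` fits a single multiplier $s$ stretching every branch
of a reference tree for one site class, by golden-section search on
$\log s$ over $[10^{-3}, 100]$, flagging boundary solutions.

## Noise analysis

Could the apparent class structure be produced by randomly splitting a
homogeneous alignment?  The noise analysis fits a matrix to every class
of the observed partition and to every class of $S$ random partitions
with the same class sizes (default $S = 50$; at least 2), measures each
matrix's Euclidean distance over the 190 pairs to the complete-data
reference matrix (all matrices on the mean-rate-one scale), and runs a
one-sided one-sample t-test per class of whether the mean random
distance falls below the observed one, with Bonferroni correction over
classes.  Failed replicate fits are dropped with a warning rather than
aborting a long campaign.

Two caveats are documented deliberately.  First, the distance is the
unweighted Euclidean norm over all 190 pairs; distances therefore carry
a floor of estimation noise that grows as subsets shrink, which is why
the observed/random *contrast* - not the absolute distance - is the
meaningful quantity.  Second, the one-sample t-test treats the observed
distance as a constant.  Under true homogeneity the observed partition
is exchangeable with the random ones, so the test's real false-positive
rate is well above its nominal level (with $S = 10$ the rejection
threshold sits only $0.7\,s$ above the random mean, which a
same-distribution draw exceeds about a quarter of the time).  The test
is reported in its classical form because that is the form in which
such noise analyses are conventionally reported; a calibrated variant
would divide by $s\sqrt{1 + 1/S}$ instead of $s/\sqrt{S}$.  The package
reports exact p-values at $S - 1$ degrees of freedom.

## Cross-validation

The 50% likelihood cross-validation splits every class uniformly at
random into equal training and validation halves (odd counts favor
training), fits a matrix to each training half, and scores every
validation half under every training matrix and under the supplied
complete-data matrix.  By default each (validation set, matrix)
evaluation re-optimizes branch lengths and uses the validation set's own
empirical frequencies: the exchangeabilities are the object under
validation, and forcing a competitor to also carry mismatched branch
lengths or frequencies would overstate its deficit.  Reusing the
supplied tree instead is available via `reoptimizeBranches = FALSE`.
Note the design is deliberately not a standard k-fold CV: the class
memberships are fixed before training, because the quantity being
validated is the usefulness of the complete-data class matrices for
future data.  `cvSummary()` reports the mean and standard deviation over
replicates (default 10) of the winner's log-likelihood advantage per
cell.

## The synthetic data generators

Nothing external is needed to exercise the pipeline: two generator
flavors produce group-structured alignments with known truth.

**Frequency-class fixtures** (`fixtureSpec()`) emulate what the
clustering stage is meant to detect: three classes with concentrated,
disjoint dominant-residue profiles - a large hydrophobic class (L I V F
M), a hydrophilic helix-amenable class (A T K E Q), and a small
bend-preferring class (G P S N) - evolving on one shared deep unrooted
tree (branches uniform on 0.5-1.2 substitutions per site, 75 taxa by
default, class sizes 100/60/40).  Trees are unrooted because under a
reversible model only the sum of the two branches at a degree-two root
is identifiable.  Several generator choices came out of explicit failure
analysis and are worth recording:

* *Per-site profile heterogeneity.*  Each site draws its own equilibrium
  frequencies from a Dirichlet (precision 50) over its class's dominant
  residues.  If all sites of a class share one equilibrium profile, the
  within-class profile cloud collapses onto a few discrete modes indexed
  by the site's root state, and the gap statistic - correctly - reports
  more than three clusters.  Real alignments show exactly this kind of
  residual site-to-site heterogeneity within a class.
* *Dominant-set-restricted heterogeneity.*  The Dirichlet varies only
  the dominant residues (weight >= 0.05); rare residues keep fixed small
  weights.  Letting every coordinate vary occasionally produces a site
  dominated by one atypical residue, and a handful of such outliers is
  enough for K-means to carve them into their own cluster.
* *Fast escape from rare states.*  Baseline frequencies are 0.001 with
  baseline exchangeability 4 against 12 within the dominant set.  With a
  slow baseline a site whose root draws a rare residue stays frozen
  there across the whole tree (at baseline exchangeability 2 the
  normalized escape rate is about 0.23 per unit length, so nearly half
  of such sites never relax over a depth-3 tree), again creating
  carveable outliers.  At the chosen defaults fewer than one frozen site
  is expected per 200-site fixture, and the gap curve rises to $k = 3$
  and declines beyond it, the qualitative shape reported for real
  mitochondrial data.

**Shared-support fixtures** (`sharedSupportSpec()`) serve the
matrix-level analyses.  All classes share one equal-frequency profile
over eight residues, but each class exchanges fast along its own
disjoint perfect matching of those residues.  This matters because with
disjoint dominant sets each class informs only its own block of the
matrix, so a class-specific fit and the joint fit coincide on that block
and neither the noise analysis nor cross-validation has anything to
detect; with shared support a matrix trained on one class is genuinely
wrong for another.

What passing tests on these fixtures do *not* show: robustness to
alignment error, to non-reversible or time-heterogeneous evolution, to
among-site rate variation (deliberately out of scope - the model is
homogeneous within a class), or that real mitochondrial data contain
exactly three classes.

## Problem sizes used in the checks

The automated checks run at desk scale, with sizes chosen as the
smallest that leave comfortable statistical margins: the pruning oracle
on 50 trees of 3-5 taxa; parameter recovery on 20 taxa x 3000 sites
(cyclic optimization from two starting matrices, Pearson r ~ 0.997
against the planted sparse process); class recovery on the default
75-taxon, 200-site fixture over ten seeds; the noise analysis on an
8-taxon, 400-site two-class fixture with S = 10; cross-validation on a
12-taxon 120/80/60 fixture with 10 replicates.  Noise and CV fits use
the joint method with exchangeability bounds $[10^{-2}, 10^2]$ - a
deliberately tighter box than the package default, applied identically
to observed and random/CV fits so comparisons are like-for-like; on
subsets this small the extreme tails of the default box are only ever
reached by weakly informed pairs.

## Known limitations

* Among-site rate variation (gamma categories), matrix mixtures and
  topology search are out of scope; the topology is always fixed.
* The distance between matrices is unweighted over the 190 pairs;
  weakly informed pairs contribute noise, mitigated but not eliminated
  by the pinning rule above.
* The noise-analysis t-test is anti-conservative under true homogeneity
  (see above); treat borderline p-values with suspicion and rely on the
  observed-vs-random contrast.
* The gap statistic inherits K-means' preference for spherical classes
  in profile space; strongly elongated or nested class geometries can
  legitimately select a different k.
* A physicochemical distance matrix supplied as an optimizer start is
  used as-is (any symmetric non-negative 20x20 matrix is a legal start);
  no conversion to exchangeabilities is attempted.
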