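---
title: "Modeling RNA-binding protein binding preferences with graph kernels"
author: "graphrbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling RNA-binding protein binding preferences with graph kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphrbp)
```

## The problem

CLIP-seq experiments yield intervals on transcripts where an RNA-binding
protein (RBP) was cross-linked; in-vitro assays such as pull-down
competitions yield graded relative affinities for designed RNA pools. Both
kinds of data ask the same question: what sequence *and structure* features
make an RNA region a good binding site? Many RBPs recognize their motif
only in a particular structural context — a hairpin loop, an accessible
single strand, a paired stem — so a model restricted to sequence k-mers
misses part of the signal, while a model committed to one predicted
minimum-free-energy structure inherits the (large) errors of single
structure prediction.

`graphrbp` takes the middle road. Each candidate site is extended by
folding context, a *population* of plausible secondary structures is
sampled via shape abstraction, sequence and structure are encoded together
as a directed annotated hypergraph, and an explicit graph-kernel feature
map turns each site into a sparse vector on which ordinary linear models
(margin classifier or support vector regression) are trained. Everything
downstream of the feature map is linear, so per-nucleotide contributions,
binding profiles and motif logos come out of the model by bookkeeping, not
approximation.

## From interval to graph

**Context and viewpoint.** A binding site is extended on both sides by 150
nt (or to the transcript end). The extension exists so that the site can
fold in a realistic context; it is *not* part of the site. The original
interval is marked as the *viewpoint*: kernel features must root at least
one of their two neighborhoods inside it. Training sites longer than 75 nt
are discarded, and iCLIP cross-link positions are widened by 15 nt per
side before any other processing. Unbound (negative) training sites are
drawn by shuffling the coordinates of bound sites uniformly within the
occupied genes, rejecting placements that overlap any bound site (up to
1,000 attempts; the spec of the assay does not constrain this, but
overlapping "unbound" sites would be label noise).

**Folding.** Contexts are folded in sliding 150-nt windows with step 37,
plus a final window flush with the 3' end so trailing positions are always
covered. Per window, up to three *shreps* are kept: the minimum-free-energy
(MFE) structure plus the lowest-energy representative of each distinct
abstract *shape* within 10% of the window MFE (for negative MFE, energy
$E \le 0.9\,\mathrm{MFE}$; for non-negative MFE only the MFE structure).
Shapes ignore stem lengths always; level 5 keeps only the helix
arrangement (`[]`), level 3 keeps helix breaks caused by internal loops
and bulges, level 1 keeps all loop detail including unpaired runs (`_`).
The default abstraction is level 3; it is a tunable worth including in a
line search.

Two folding backends satisfy one contract (sequence in; structures,
shapes, energies out). The default is a built-in deterministic folder: a
Nussinov-style dynamic program whose score charges every pair a helix
opening penalty (+1.5) and credits every directly stacked pair the mean
strength of the two pairs (GC 4.5, AU 3.5, GU 2.5), followed by an exact
best-first enumeration of all suboptimal structures within the energy
band (an unambiguous grammar, so each structure appears exactly once, in
energy order). With these constants an isolated pair is never favorable —
the "no lonely pairs" behavior of thermodynamic folders — which matters in
practice: with naive per-pair scores, spurious single pairs litter loops
and corrupt the structure-element assignment. Energies are in arbitrary
units; the 10% band applies to whichever backend is active. The second
backend shells out to ViennaRNA's `RNAsubopt` and computes shapes
in-package; it gives kcal/mol energies but adds an external dependency,
so tests and defaults use the built-in folder.

**Graph encoding.** Each shrep of each window becomes one connected
component of the site's graph, so one site yields one feature vector
accumulated over its whole structure ensemble. Within a component:
nucleotide vertices labeled by base, backbone edges 5'→3', base-pair
edges from the 5' to the 3' partner. On top sits the abstract layer: one
vertex per structure element — stem (S, one vertex per helix covering both
strands), and one vertex per contiguous run of hairpin (H), internal loop
(I), bulge (B), multiloop (M) or external (E) positions — with adjacency
edges directed from outer elements toward more deeply nested ones
(external → stems → loops → inner stems → hairpins). Each abstract element
is tied to its nucleotides through a *relation* vertex whose edges are
non-traversable, so paths can never short-circuit through the hyperedge.
Finally the whole graph is duplicated with all edges inverted and labels
prefixed `r`: a directed kernel on one copy alone would see only the
downstream side of every root, and an undirected kernel could not tell a
sequence from its reverse at all. The mirrored copy restores the upstream
view while preserving direction sensitivity.

## The feature map

The kernel features are pairs of same-radius neighborhood subgraphs. For
every ordered pair of roots $(u, v)$ of the same feature set (nucleotide
roots pair with nucleotide roots through backbone/base-pair edges;
abstract roots pair with abstract roots through abstract adjacency) at
directed shortest-path distance $d \le D$, and every radius $r \le R$, a
feature is keyed by $(r, d, \mathrm{set}, L_r(u), L_r(v))$, where $L_r$
is a canonical label of the radius-$r$ neighborhood: the sorted multiset
of per-vertex signatures (distance from root, vertex label, sorted
incident-edge descriptors within the subgraph). *Hybrid* features
additionally pair the abstract endpoint of every relation vertex with each
of its nucleotides, which is what lets two identical subsequences generate
distinct features when one sits in a hairpin and the other in an internal
loop. A pair is counted only if a root (for hybrid features, the
nucleotide endpoint) lies in the viewpoint; abstract vertices inherit the
viewpoint flag from their members.

Counts are normalized to unit Euclidean norm within each
$(r, d, \mathrm{set})$ block and the concatenation is rescaled to unit
norm, preventing feature-rich blocks (large radii) from dominating the
kernel. Keys are hashed (64-bit FNV-1a folded to $2^{\mathrm{bits}}$,
default $2^{20}$) and colliding keys are summed — the kernel is
deliberately approximate; an `exact_mode` keyed by canonical strings
exists for oracle tests, which verify on random small graphs that
exact-mode dot products equal a brute-force paired-neighborhood
isomorphism count (VF2). The canonical label is a graph invariant, not a
complete canonical form; non-isomorphic neighborhoods could in principle
collide, and the oracle test is exactly the place where such a defect
would surface.

## Learning and prediction

**Classification.** A linear model on the hashed features is trained by
stochastic gradient descent on the $\lambda$-regularized hinge loss with
a Pegasos-style schedule $\eta_t = 1/(\lambda(t + t_0))$, per-epoch seeded
shuffling and an unregularized bias. Defaults $\lambda = 10^{-3}$, 20
epochs, $R = 2$, $D = 5$, $2^{20}$ hashed dimensions were fixed once by a
small round-robin sweep on simulated motif-implant data of the kind the
package targets; for real datasets the intended protocol is the built-in
line search (below), which tunes each dataset separately.

**Regression.** For graded affinities the package solves
$\varepsilon$-insensitive support vector regression in the dual on the
Gram matrix of the explicit features (kernlab), then reconstructs the
sparse primal weight vector from the support-vector coefficients, so a
regression model predicts by the same inner product as a classifier and
serializes to the same text archive. When the $\varepsilon$ tube swallows
the entire target range the optimal model is flat; the package returns a
zero-weight model centered in the range rather than failing.

**Evaluation.** Tenfold cross-validation with stratified seeded folds
(stratification is a choice; it stabilizes AUROC on unbalanced data);
AUROC via the Mann–Whitney statistic with ties at ½; average precision as
the mean of precision at each positive's rank with stable tie order; and
relative error reduction $(x' - x)/(1 - x)$ for comparisons. The line
search tunes one hyperparameter at a time over its grid, round-robin until
a full cycle changes nothing, scoring by cross-validated AUROC on a
held-aside stratified subset of $\min(1000, \lfloor 0.1 n \rfloor)$
examples that is excluded from the final assessment (the tuning CV uses
5 folds by default, a cost choice; the assessment CV stays tenfold).

**Profiles, site calls, logos.** Because the model is linear, the margin
decomposes exactly over feature occurrences. Each occurrence's
weight×value contribution is split half-and-half between its two root
vertices (fully to the root for self-pairs); mass on mirrored vertices
maps back to the original position, and mass on abstract vertices is
divided equally among the element's nucleotides — with that convention
the per-nucleotide profile sums to margin − bias exactly (tested at
1e−9). Binding scores are profile means over sliding 12-mers; calling
high-affinity sites keeps the top 1% of windows across the whole
collection (ties broken by sequence id then position, stable) and merges
overlapping *and* abutting windows, scoring each merged site by its best
window. Motif logos take, per folding hypothesis of up to 2,000 bound
sites, the best-scoring viewpoint 12-mer with its structure-element
string, pool the top 1,000, and emit column-normalized 4×k and 6×k
frequency matrices plus the raw k-mer list for WebLogo-style rendering.

## The synthetic generator

All tests and the acceptance script run on synthetic data with known
ground truth. The generator emulates:

* **Classification sets** — uniform-random background sequences (60 nt by
  default; an optional first-order Markov background exists) with an 8-mer
  motif implanted at a random position, each motif position mutated with
  probability `mutation_rate` (default 0.1). For `hairpin_loop` contexts
  the motif is framed by an 8-bp GC stem (homopolymer runs capped at 2 —
  repetitive stems fold in slipped registers that swallow loop edges);
  under the built-in folder ≥ 90% of motif positions then sit in H
  elements. For `stem_flanked` contexts the motif is paired against its
  own reverse complement. The off-by-default `decoy_motif` flag gives
  negatives the same motif flanked by composition-matched but
  *independent* GC arms: sequence composition then carries no class
  signal and only the pairing relation separates the classes, which is
  the clean way to measure the structure model's added value.
* **Affinity sets** — motif copies degraded by 0 to 4 substitutions give
  a graded range of site qualities; the ground-truth signal is an
  occupancy-style match score
  $\log \sum_w \exp(\beta(q_w - 1))$ over all motif-length windows
  ($\beta = 8$, about one unit per mismatch), i.e. the equilibrium
  log-occupancy a bulk binding assay measures — a sum over partial sites
  rather than a best-match maximum, which no linear model over
  substructure counts could express. Measured affinity adds Gaussian
  noise (default sd 0.25, replicate-level scatter relative to the ≈0.5-sd
  signal).

What the generator does **not** emulate: cross-link-induced mutations and
PCR duplicates in reads, transcript-abundance confounding, protein
concentration effects, cooperative binding between nearby sites, and the
coordinate-shuffling negatives of real CLIP pipelines (the prep module
implements that separately). Passing the recovery experiments therefore
shows the machinery is correct and sensitive at realistic noise levels,
not that any particular biological accuracy will be reached on real CLIP
data.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed throughout the R API (GRanges/IRanges
  convention); BED input/output converts at the boundary via rtracklayer.
* The suboptimal enumeration breaks energy ties by insertion order of the
  search states, making the structure list deterministic; shrep selection
  uses a 1e−9 tolerance on the band edge.
* Sequences containing `N` never pair; an all-N or unpairable window
  yields a single zero-pair hypothesis with shape `_` (one external run).
* Empty viewpoints are rejected at construction; viewpoints shorter than
  the motif width are skipped (with a warning) during logo extraction.
* Hash collisions in the default mode are accepted and summed; all
  collision-sensitive tests run in exact mode.
* Top-k selections (sites, k-mers) use stable sort with explicit
  tie-breaks (score desc, then id, then position) for reproducibility.
* One global seed fans out additively to stage seeds (folds, SGD
  shuffling, negative placement), all below 2^31.

## Problem sizes

The test suite and acceptance script run: motif recovery at 500+500
sequences with tenfold CV; the structure-benefit comparison at 150+150
over several seeds (both modes, tenfold CV each); affinity recovery at
300 training / 100 held-out sequences; kernel-oracle checks on 200 random
graphs of up to 10 vertices. These sizes give stable estimates (CV AUROC
seed-to-seed spread ≈ 0.01) while keeping a full run in minutes on one
core.

## Known limitations

* The built-in folder's energies are not kcal/mol; absolute energies are
  meaningful only within a backend. Shape *sets* (not energies) are the
  quantity the pipeline consumes.
* Pseudoknots are outside the structure model, and base-pair probabilities
  are not used — structure enters only through the shrep ensemble.
* The canonical neighborhood label is an invariant, not a complete
  canonical form (see above).
* Cooperative binding between nearby sites is not modeled; margins of
  overlapping sites are simply what the linear model assigns.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(n_pos = 100, n_neg = 100, seq_len = 60, seed = 42)
sites <- generate_classification_set(spec)
fit <- graphrbp(sites, mode = "sequence")
summary(fit)
cv <- crossvalidate(sites, k = 10, seed = 42, mode = "sequence")
cv
mot <- extract_motif(fit, sites[sites$label == "bound", ], top_n = 100)
mot
```
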