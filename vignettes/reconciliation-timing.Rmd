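---
title: "Dating gene events by dated DTL reconciliation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating gene events by dated DTL reconciliation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chronodtl` answers a question that comes up whenever a gene family is
mapped onto a time-calibrated tree of life: *when* did the family's
duplications, horizontal transfers, losses and speciations happen?  The
package reconciles rooted gene trees with a dated species chronogram
under a parsimony duplication–transfer–loss (DTL) model, converts the
inferred events into calendar time ranges, and summarises the result as
per-gene timelines, earliest-event records, count tables and binned
trends.  This vignette explains the models, the defaults and the design
decisions; the README shows a worked run.

## Temporal conventions

All times are in Ga (billions of years) before present: the present is
0 and time increases into the past.  A chronogram is a rooted, binary,
ultrametric tree; leaves sit at 0 and every internal node has an age.
Node ages may carry 95% confidence intervals, written in newick as
bracketed node comments `[&ci={low,high}]`.  When a CI is present the
*working date* of that node is the CI midpoint; otherwise the point age
is used.  This midpoint convention propagates into every event date the
package reports.

Input newick is accepted if it is ultrametric to within a relative
tolerance of `1e-6` of the root age (round-off in published files is
common); ages are then re-projected to exact ultrametricity by setting
each node's age to its mean distance to its descendant leaves.  Larger
deviations are rejected with the name of the offending leaf.  Polytomies
and duplicate leaf labels are rejected outright.

## Time slices and the position graph

The chronogram is cut into horizontal *time slices* at the distinct
internal-node ages.  Exactly equal node ages are merged into a single
boundary rather than perturbed, which preserves published ages at the
cost of disallowing transfers between two branches that meet only at the
merged instant (they share no open time interval).  Within a slice the
set of living species branches is constant, and a horizontal transfer is
permitted only between two branches alive in the *same* slice.  Because
the species tree contains no extinct or unsampled lineages, no transfer
can involve a dead lineage — the restriction the reconciliation model
assumes throughout.

On top of the slices the package builds a *position graph*: one position
per (branch, slice) pair, plus a degenerate *stem* position above the
root.  The stem exists so that a gene divergence can coincide with the
root speciation (a congruent family must be explainable by speciations
alone) and so that a family may originate, and even duplicate, before
the root.  Single-lineage movement between positions is priced by three
arc types — free same-branch descent, speciation-loss into one child
(cost λ), and within-slice transfer-loss (cost τ + λ) — and an
all-pairs shortest-path matrix over these arcs.  Chained within-slice
jumps are never cheaper than a single jump, since every contemporaneous
branch is one jump away.

## The parsimony model

Events are priced δ for a duplication, τ for a transfer and λ for a
loss; speciations and the matching of gene leaves to extant species are
free.  The defaults δ = 2, τ = 3, λ = 1 are the conventional defaults of
standard DTL reconciliation software and are fully configurable
(`cost_scheme()`).  For a gene node placed at a position, the dynamic
program considers: a speciation (only where the branch ends in a
speciation node at the slice bottom, children descending into the two
child branches, both pairings), a duplication (both children continue in
place), or a transfer (one child continues, the other restarts on any
other branch alive in the same slice).  Each "child starts here" term is
minimised over the child's eventual event position via the movement
matrix.  Origination is free anywhere on the tree — including the stem —
so the earliest inferred event *bounds* the family's birth rather than
dating it.

Backtracking is deterministic: ties are broken by event priority
speciation > duplication > transfer, then by older slice, then by the
lexicographically smallest branch identifier (branches are named by the
smallest leaf of their clade plus the clade size, which is unique and
stable).  Movement paths are decomposed into explicit events, a
speciation-loss counting as one speciation plus one loss and a
transfer-loss as one transfer plus one loss, so the identity
*total cost = δ·#D + τ·#T + λ·#L* holds exactly over the emitted event
list and is asserted after every reconciliation.

Gene trees are taken as rooted and binary with their given root; no root
search is attempted.  Leaf labels map to species either exactly or by
the prefix before `|`, so multi-copy families use labels like
`s07|copy2`.  A single-leaf family is free (origination on the terminal
branch); an empty family yields an empty reconciliation of cost 0.

## The independent oracle

`brute_force_reconcile()` is a deliberately separate code path used only
for validation: a depth-first branch-and-bound over *atomic* moves
(descend, speciate, speciation-loss, transfer-loss jump, duplicate,
transfer) with the accumulated cost pruned against a cap.  It shares no
movement matrix or precomputed structure with the dynamic program and is
restricted to instances with at most 5 species and 5 gene leaves.  The
test suite requires exact cost agreement between the two engines on 100
random simulated instances, alongside hand-checkable fixtures.

## The simulator

`simulate_species_chronogram()` draws a pure-birth (Yule) tree
conditioned on the number of leaves and on the crown age, using the
exact conditioned construction: the non-root node ages are i.i.d.
truncated-exponential on (0, root age) and the topology is built by
splitting a uniformly chosen lineage at each successive speciation time.
The closed-form age CDF (`yule_age_cdf()`) doubles as the
Kolmogorov–Smirnov oracle in the tests.  The default root age is 4.05
Ga, a commonly inferred age for the last universal common ancestor
under an autocorrelated relaxed clock, and the default Yule rate of 0.5
per lineage per Ga makes a 20-species tree at that depth typical rather
than star-like or ladder-like.

`simulate_gene_family()` runs a forward Gillespie simulation from a
single ancestral copy at the species root.  Between species divergences
each copy duplicates, transfers or dies at the configured per-copy
rates; at each divergence every copy on the parent branch speciates into
both children.  Transfer recipients are uniform among the branches alive
at the moment of transfer, excluding the donor; the donor copy persists
(additive transfer), so a transfer-with-donor-loss only arises from a
coincidental loss.  The observed gene tree is the pruned genealogy of
surviving copies; the truth log records every event with its exact time,
branches and a surviving-descendants flag, and the family's total
lineage-time is reported so that event counts can be checked against
rate × exposure analytically.  Default rates are 0.05 duplications, 0.10
transfers and 0.05 losses per copy per Ga — a low-event regime in which
histories are sparse and mostly recoverable, chosen as fixture
conditions rather than as estimates for any real gene family.

What the simulator does *not* emulate matters for interpreting green
tests: there is no gene-tree estimation error (observed topologies are
exact), no sequence evolution, no extinct or unsampled species lineages,
no rate variation across branches, and the generating model matches the
reconciliation model's event vocabulary.  Passing the recovery suites
therefore shows the inference machinery is correct and calibrated on its
own terms, not that real single-gene phylogenies are this well behaved.

## Dating and summaries

Reconciliation localises a duplication, transfer or loss only to a
branch: the event could have occurred anywhere between the branch's two
nodes.  The default *branch* dating mode therefore reports the range
from the parent-node date to the child-node date (0 for leaf branches,
which extend to the present), with the midpoint as the point summary;
speciations are dated exactly at their node.  Transfers are dated on the
recipient branch.  The alternative *slice* mode intersects the range
with the event's time slice — the dated DP localises transfers more
tightly than a whole branch — and is offered because it never widens a
range; branch mode remains the default for fidelity to the conventional
whole-branch reading.  When only one end of a branch carries a CI, the
other end uses its point age.

Reported dates are rounded to two decimals, half away from zero
(2.765 → 2.77).  The earliest event of a gene is the one with the
maximum midpoint, ties broken by the larger old bound and then by event
priority; genes are ordered oldest-first by that midpoint with
alphabetical tie-breaks.  Count tables report losses, duplications,
transfers and speciations per gene with *total defined as their sum* —
a deliberate choice: a total column that can disagree with its own
addends is not reproducible.  Terminal leaf matches are not counted as
speciation events.  Binned histograms use half-open bins `[lower,
upper)` ascending from 0 with the oldest bin closed; the default width
of 0.25 Ga is configurable, and proportions are relative to the gene's
total event count so that each gene's bins-and-types sum to 1.

## Validation scale and determinism

The validation suites run at sizes chosen to exercise every code path
while keeping a full check fast on one CPU: 100 oracle instances with up
to 5 leaves, one 20-species chronogram with 200 simulated families for
the truth-bound, time-consistency, transfer-recovery and containment
suites, and 50 congruent families for the zero-cost identity.  Every
stochastic step is seed-derived, and identical inputs produce
byte-identical outputs end to end, including the written TSV/XML files.

## Known limitations

* One optimal history is reported per gene tree.  Co-optimal histories
  are common in DTL parsimony; `reconcile_many()` aggregates support
  over a set of input trees, but does not enumerate the optimum set of a
  single tree.
* Amalgamation over a gene-tree distribution is out of scope;
  per-tree reconciliation plus support aggregation is the provided
  approximation.
* Transfers to extinct or unsampled lineages are deliberately excluded,
  which is faithful to the intended setting but can force visible
  transfers onto sampled donors when the true donor lineage is missing.
* Branch-mode ranges are honest about uncertainty but wide on long leaf
  branches; midpoints on such branches cluster at half the branch span
  and should be read as summaries of ranges, not as dates.
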