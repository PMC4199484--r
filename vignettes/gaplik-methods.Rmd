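---
title: "Likelihood-based annotation and gap filling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based annotation and gap filling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaplik)
```

## The problem

Automated reconstruction of a genome-scale metabolic model (GEM) leaves
gaps: reactions that can carry no steady-state flux because annotation
of the genome missed an enzyme.  Classic parsimony-based gap filling
closes a gap with the *fewest* modifications drawn from a universal
reaction database — which systematically prefers short pathways even
when the genome carries clear evidence for a longer one.  `gaplik`
implements the alternative: score every candidate gene function by
sequence homology, propagate those scores to *reaction likelihoods*
$p(x)$, and let the gap-filling MILP minimize likelihood-weighted cost
instead of reaction count, so that the pathway most consistent with the
genome wins.

## The scoring chain

For every BLASTP hit of query gene $i$ against reference gene $j$
(pre-filtered at $E \le 10^{-5}$) the log-score is

$$ S_{ij} = -\log_{10}(E_{ij} + k), \qquad k = 10^{-200}, $$

so that reported E-values of zero give $S = 200$ rather than infinity.
With $A_a$ the set of reference genes carrying annotation $a$ and
$S_{i,\max}$ the gene's best score, the annotation likelihood is

$$ p(i \in A_a)
   = \frac{\sum_{j \in A_a} S_{ij}^2}
          {PC \cdot S_{i,\max} + \sum_{j} S_{ij}^2}, \qquad PC = 40. $$

Squaring prevents many weak hits from outvoting one strong hit; the
pseudocount term both calibrates the scale (a single hit at
$E = 10^{-40}$, i.e. $S = 40$, gives exactly $1/2$ — only base-10
scores make that work, which fixes the logarithm base) and guarantees
$\sum_a p(i \in A_a) < 1$ for every gene.  Propagation to reactions
follows the biochemistry template:

* **role**: per gene, *sum* over annotations mapping to the role; per
  organism, *max* over genes, retaining genes within 80% of the maximum
  (OR-linked — isoenzymes);
* **complex**: *min* over member roles (AND-linked — every subunit must
  exist);
* **reaction**: *max* over catalyzing complexes, retaining complexes
  within 80% of the maximum (OR-linked).

The retained clauses assemble a candidate Boolean gene–protein–reaction
(GPR) rule for every scored reaction.  Both equations above are stated
in the source as unreproduced figure images; the forms used here are
the unique reconstructions consistent with every property stated in
the accompanying prose (numerator restricted to $A_a$, squared scores,
pseudocount scaled by $S_{\max}$, the 50% calibration), and the
calibration anchor is asserted in the test suite to $10^{-9}$.

## Gap filling as a MILP

Given a draft model, a universal database and a target reaction
(usually biomass), the program is

$$ \min \textstyle\sum_j \lambda_j z_j \quad \text{s.t.}\quad
   S v = 0,\; 0 \le v_j \le M z_j,\; v_{\text{target}} \ge \epsilon $$

over binary selections $z$ of candidate modifications: adding a
universal reaction in either direction, or re-opening the closed
direction of a draft reaction.  Costs are

* parsimony: $\lambda = \text{base} + U$,
* likelihood: $\lambda = (1 - p(x)) \cdot \text{base} + U$,

with $\text{base} = 1 + 25\,[\text{transporter}] + 5\,[\text{low-confidence
source}]$ and the thermodynamic surcharge
$U(\Delta G) = (12 + 2\max(\Delta G, 0))/10$ applied only in an
unfavorable direction ($\Delta G$ of that direction known and
positive) and *never* likelihood-scaled.  Reversibility changes cost
$12 \cdot U/1.2$ in both modes.  Defaults are the likelihood-optimal
penalties (transporter 25, reversibility 12), used for both modes.
Units: $\Delta G$ in kcal/mol; fluxes in mmol/gDW/hr; $U$ is measured
in "average intracellular reaction additions", so a low-$\Delta G$
reversibility change costs about one to two reactions and a
10 kcal/mol one about three.

Design choices worth knowing:

* $\epsilon = 10^{-5}$, $M = 1000$; bounds are finite everywhere, so
  the LP can never be unbounded.
* The target's own reversal is excluded from the candidate set: in the
  direction-split MILP it would pair with the forward variable into a
  futile two-cycle that "activates" the target without any network
  change, which the integrated net-flux model cannot reproduce.
* Exchange reactions are not reversibility-change candidates (media
  bounds govern them), and a candidate exchange's uptake direction is
  capped by the gap-filling medium.
* Before search, bounds are tightened to a fixed point: a direction
  consuming an unproducible (or producing an unconsumable) metabolite
  is closed.  This is conservative (implied by $Sv = 0$) and typically
  removes most disconnected candidates.
* The solver is an LP-based branch and bound over the selection
  variables, with the relaxation objective $\sum \lambda_j v_j / M$
  (a valid lower bound since $z_j \ge v_j/M$) and branching on the
  most expensive fractional candidate.  Every node's LP support yields
  an incumbent, so the search has good primal behavior on
  pathway-structured instances.  A wall-clock budget is enforced; on
  timeout the budget doubles and the solve retries, up to
  $t_{\max} = 86400$ s (then a timeout error).
* Ties between equal-cost optima resolve deterministically (the search
  order is deterministic), but tests only assert objective values and
  target activation where ties are possible.

No LP/MILP solver package could be assumed available at run time, so
the package carries a dense two-phase primal simplex sized for these
toy-scale instances.  It is cross-validated in the test suite against
hand-solved LPs and against an external reference solver
(`scipy.optimize.linprog`) on seeded random instances; the MILP is
additionally checked against exhaustive subset enumeration.

## Workflows

The four workflows combine two cost modes with two strategies:

1. **Targeted**: activate biomass on *complete media* (every compound
   the draft can transport, uptake 100 mmol/gDW/hr), then again on a
   glucose-style minimal medium.
2. **Iterative**: additionally loop over every inactive gene-associated
   reaction in priority order (central carbon, then biosynthesis of
   essential metabolites, then peripheral utilization, then the rest;
   classes come from the reaction-attribute sidecar).  Activity is
   re-checked by FVA immediately before each target; per-target
   failures are logged, not fatal; failed targets are not retried in a
   second pass (single-pass semantics, documented rather than looped,
   since later integrations rarely rescue an unfillable target in
   practice).  Iterative runs end with *reaction sensitivity analysis*
   (is each gap-filled reaction essential for biomass? does its removal
   inactivate other reactions?) and greedy pruning of non-contributing
   reactions, re-evaluating after each removal so that of two mutually
   redundant additions exactly one survives.

FVA inactivity uses tolerance $10^{-9}$ on both directions (a
reversible reaction is inactive only if *both* directions are within
tolerance), with no biomass constraint by default
(`fraction_of_optimum = 0`, exposed as an argument).

## Phenotype simulation

Knockouts: evaluate every GPR with the gene removed, close both bounds
of FALSE reactions, maximize biomass; lethal below
$10^{-9}\,\text{hr}^{-1}$.  The model must grow on the assay medium
first — the error message points at gap filling, mirroring the intended
pipeline order.  Biolog-style arrays: the model is augmented *once* with
a reversible transporter (magnitude 100) and exchange for every
compound in any assay medium, then each medium is applied in turn.
Confusion metrics with zero denominators are reported as undefined
(`NA`), never as 0.

## The synthetic universe

`make_toy_universe(seed)` generates the entire input world: a
universal database of roughly 40 reactions, a gold-standard model that
grows on its minimal glucose+ammonia medium, planted BLAST evidence,
the template, media and phenotypes.  Planted E-values are obtained by
*inverting* the likelihood formula ($n$ equal hits at score $S$ give
$p = nS/(PC + nS)$), so the fixture stays valid if $PC$ changes:

* the 4-reaction precursor pathway `L1`–`L4` gets two hits at
  $E = 10^{-180}$ per gene — likelihood exactly 0.9;
* the 2-reaction alternative `S1`–`S2` gets no evidence at all;
* core reactions sit at 0.8, one isoenzyme at 0.7 (exercising the 80%
  retention rule), a two-subunit transporter exercises AND complexes;
* seeded moderate-evidence degradation reactions are inactive in drafts
  and fillable only by adding secretion routes (iterative targets), one
  seeded distractor is gene-associated but unfillable (failure
  logging), and weak noise hits go to orphan annotations so they
  perturb nothing downstream.

Consequently the two-pathway experiment has analytically known optima:
parsimony picks `S1`+`S2` at cost $2.0$, likelihood picks `L1`–`L4` at
cost $4 \times (1 - 0.9) = 0.4$.  What the generator does *not*
emulate: real sequence data (E-values are planted, not aligned),
biomass maintenance costs, periplasmic compartments (two compartments
only, matching the method's stated scope), mass/charge balancing, and
realistic database noise.  A green test therefore establishes the
*algorithms* — scoring arithmetic, MILP optimality, workflow
plumbing — not predictive accuracy on real genomes, which the original
study assessed on external organism panels that are out of scope here.

```{r}
u <- make_toy_universe(1)
draft <- remove_reactions(u$gold_model, c("L1", "L2", "L3", "L4"))
cm <- complete_media(draft)
parsimony <- gapfill_target(draft, u$universal,
                            compute_costs(u$universal, draft, NULL),
                            "bio1", cm)
likelihood <- gapfill_target(draft, u$universal,
                             compute_costs(u$universal, draft, u$rxn_lik),
                             "bio1", cm)
parsimony$objective_value; sort(parsimony$added$reaction_id)
likelihood$objective_value; sort(likelihood$added$reaction_id)
```

## Verification strategy

Every level has an independent oracle: annotation/role/complex/reaction
likelihoods against a naive loop-based reimplementation (agreement to
$10^{-12}$ over seeded random instances); the simplex against
hand-solved LPs and scipy; the MILP against exhaustive enumeration on
small universes whose unit-stoichiometry structure makes subset
feasibility equivalent to *graph reachability* — an oracle that shares
no linear algebra with the solver at all (chosen over per-subset LP
feasibility checks precisely for that independence).  Acceptance
criteria run at their stated sizes (100 oracle instances, 1000
normalization tables, 50 enumeration universes, 20-seed recovery and
pruning suites) in about two minutes total.

## Known limitations

* The dense simplex and enumeration-scale MILP are for toy networks
  (hundreds of columns at most), not genome-scale databases.
* One annotation per reference protein is assumed (guaranteed by the
  reference construction; it is what makes the sub-normalization
  property provable).  Multi-functional annotation strings must be
  pre-split by the template, not parsed from text.
* Per-gene role likelihoods are not capped: with a conforming
  reference they stay below 1 by construction, so no cap is needed.
* Parsimony base costs are unit (plus penalties); the original
  ModelSEED weighting that made a transporter penalty of 55 equal
  "about 7 intracellular reactions" used non-unit averages that are
  not reproduced here — documented rather than guessed.
* SBML support covers Level 3 flux bounds and gene associations only;
  gap-filling attributes travel in the sidecar TSV.
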