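---
title: "Literature-driven pocket prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-driven pocket prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketlit)
```

## The problem

Docking a ligand into a known binding site requires the site's geometric
extent, which is almost never published directly. Geometry-based
detectors such as Fpocket enumerate many candidate cavities; published
experimental work (mutagenesis, structural analysis, fluorescent probing)
identifies which residues matter. `pocketlit` connects the two: residues
are extracted from article text by a staged, prompt-driven workflow,
mapped onto a concrete PDB structure, and used to filter and merge the
geometric candidates, which are finally converted to a cleaned volumetric
grid suitable for docking-box definition.

This vignette is the package's own account of the method: the procedure
and its assumptions, the parameters that matter, what the synthetic
fixtures do and do not emulate, and the places where the design was
genuinely open.

## The extraction workflow and its contract

Extraction runs three sequential stages against one backend:

1. **Relevance.** Does the article describe the target protein *and*
   contain a residue-level description of a small-molecule binding site?
   Articles about the wrong protein, or describing only protein–protein
   interaction or nucleic-acid-binding surfaces, are filtered out here
   and never reach later stages.
2. **Extraction.** Every distinct small-molecule site is returned with a
   name, a one-sentence description and explicit residue tokens.
3. **Refinement.** The extraction is handed back for correction: missing
   residues are added, improperly split sites are re-unified, sites
   irrelevant to small-molecule binding are dropped.

The backend contract is a single `complete(prompt, document, stage,
doc_id)` function, so a production chat-completion service and the
deterministic mock are interchangeable. Stages must answer inside a
fenced JSON block; the parser takes the first parseable block, retries a
malformed response up to `retries` (default 2) times, and then fails
loudly. Residue tokens are validated (`A:TYR:123` dialect, with `TYR123`
and one-letter `Y123` accepted against a default chain); an invalid token
is dropped with a warning, and a pocket survives only while at least one
valid residue remains. Documents exceeding the character budget (default
400,000 characters, comfortably above typical article length) raise an
error rather than being silently truncated: whole-document prompting is
an assumption of the design, not an optimization.

Prompt templates ship as editable text assets (`inst/prompts/`). They
encode the directives that matter for accuracy: small-molecule sites
only; explicitly mentioned residues only, with hallucinated residues
called out as worse than missing ones; and a strict response format.
Temperature metadata defaults to 0.

## Benchmark evaluation

The matching criterion between an extracted and an annotated pocket is
deliberately explicit, because "correctly extracted" is otherwise
ambiguous: pairs are ranked by annotated-residue recall |A∩E|/|A|, ties
broken by annotated then extracted index, and accepted greedily
one-to-one at a threshold of 0.5 (configurable). Greedy matching is
simple and order-stable; on benchmark-shaped inputs (near-disjoint
annotated sites, extracted pockets derived from at most one site each)
it provably coincides with maximum-cardinality matching, and the test
suite checks that equivalence against an exhaustive oracle.

Pocket Recall is pooled across papers (`sum(matched)/sum(annotated)`);
per-paper averaging is available via `pooled = FALSE` since both
conventions are defensible. Residue precision/recall/F1 are
macro-averaged over matched pairs only — unmatched pockets are already
penalized by the pocket-level metrics, and mixing them into the residue
average would double-count the failure. Degenerate denominators are
defined, not NaN: zero extracted pockets give specificity 1 (no fake
pocket was possible), zero annotated pockets give recall 1; both are
logged when they occur.

## Residue-to-structure mapping

Literature residue lists rarely match a deposited structure exactly:
constructs are engineered and renumbered, chain identifiers are wrong or
absent, names get garbled. The mapping stage therefore treats the
literature chain id only as a tie-breaking hint and scores every chain by
**positional similarity**: the fraction of pocket residues whose residue
number (plus insertion code) exists in the chain with an agreeing name.
Full sequence alignment would be more general but is unnecessary for the
intended use (the paper describes *this* target) and would add a heavy
dependency surface; an optional constant-offset scan (`offset_scan`)
handles uniformly renumbered constructs and is off by default. Chains at
or above the 0.6 similarity threshold (inclusive) become candidates; if
none passes, the pocket is reported unmappable with its best score and
skipped, never fatal.

Mapped residues from all candidate chains are clustered jointly with
**MeanShift** (flat kernel), chosen because the number of clusters is not
known in advance — one literature pocket may be one physical site, one
site per chain of a homomer, or one inter-chain interface site. The
implementation is in-package and deterministic: every point is shifted to
the mean of its bandwidth neighbourhood until convergence, and converged
modes are merged within bandwidth/2 in input order. The default
bandwidth is 8 Å: binding-site residues contact a common ligand, so
their heavy-atom centroids typically sit within a ~10 Å ball, while
distinct sites (and homomer copies) are tens of Å apart; the value is
configurable for unusually large or tightly packed sites. Each residue
is represented by its heavy-atom centroid rather than Cα only, which
behaves better for glycine-rich shells and arbitrary synthetic geometry.

A cluster is matched back to a pocket when it covers at least 0.7
(inclusive) of the pocket's residues, compared chain-agnostically —
necessary because the pocket's chain assignment is exactly what is being
decided. Normalization is by pocket size, not cluster size: the question
is whether the cluster *represents* the pocket. A matched cluster
spanning two or more chains becomes a single interface pocket carrying
the cluster's residues; otherwise the originally mapped residues are
replicated once per candidate chain, which is how a homotetramer yields
four equivalent pockets from one literature description. A cluster
matching several pockets goes to the first by pocket order; in practice
distinct pockets rarely pass the 0.7 bar simultaneously.

## Geometric selection, merging and the grid

Fpocket output is consumed as-is (`pockets/pocket<N>_atm.pdb` +
`pocket<N>_vert.pqr`); alpha-sphere detection itself is out of scope. A
residue belongs to a geometric pocket when at least `residue_match_threshold`
(default 0.5) of its heavy atoms lie within sphere radius +
`contact_tol` (default 1.0 Å) of some sphere center — the output files do
not preserve Fpocket's internal four-atom tangency, so contact must be
reconstructed from distances, and the 1 Å tolerance absorbs that
discretization. A geometric pocket is selected when the Jaccard index
between its residue set and some mapped literature pocket reaches
`pocket_match_jaccard` (default 0.3, inclusive — a deliberately
permissive floor, since literature residue lists are often partial).
Selected pockets merge transitively when their residue Jaccard strictly
exceeds `merge_overlap_threshold` (default 0.5) *or* when they share a
supporting literature pocket; the second route is what re-unifies
ATP-site fragments and blends evidence from different publications.
Selection thresholds are inclusive floors while the merge trigger is
strict, so a pair sitting exactly at the merge threshold stays separate.
Sphere sets union without duplication, so merging conserves the total
sphere inventory.

The grid stage is three membership predicates applied in sequence on a
lattice with 1.5 Å default spacing, anchored at the per-axis minimum of
the pocket heavy atoms and inclusive of the maximum face when it lands on
a node:

- **sphere membership** — node-to-center distance ≤ radius (keeps the
  cavity volume);
- **convex-hull truncation** — nodes strictly outside the hull of the
  pocket heavy atoms are removed, boundary nodes retained (alpha spheres
  protruding into bulk solvent would otherwise inflate the pocket and
  admit oversized ligands in docking);
- **Van der Waals pruning** — nodes strictly closer than an atom's
  radius (Bondi-style table, 1.70 Å fallback with a warning) are
  removed. Docking engines prevent steric clashes anyway, so this stage
  is optional (`prune_vdw = FALSE`) and kept mainly for representation
  quality.

The point-in-hull test enumerates facet half-spaces by brute force over
atom triples: for pocket-sized atom sets (tens of atoms) this is far
below a millisecond budget, numerically transparent, and avoids an extra
dependency; degenerate inputs (fewer than four unique atoms, or all
coplanar) return the grid unchanged with a warning. Numerical tie-breaks
are fixed throughout: ≤ for sphere membership, boundary-inclusive hull
membership with a 1e-7 relative tolerance, strict < for Van der Waals
pruning, and a 1e-9 slack on squared-distance comparisons so lattice
points generated by exact arithmetic behave identically across
platforms. The test suite checks the staged grid against an independent
node-by-node oracle that uses a quadratic-programming hull test rather
than facet enumeration.

Which bounding box to use was genuinely open (pocket atoms only vs atoms
plus sphere extents); pocket heavy atoms were chosen, matching the hull
that later truncates the grid — a sphere-extended box would only add
nodes destined for removal.

## The synthetic fixtures

All tests and the acceptance script run on generated fixtures with
planted ground truth. The generator emulates the *logical* structure of
real inputs, not protein physics: chains are bead strings (five heavy
atoms per residue at fixed sub-Å offsets), planted pockets are concave
two-ring shells of radius ~4.7 Å around a cavity center, interface
pockets straddle two chains around one shared center, distinct sites are
70 Å apart, and chains are 100 Å apart. Alpha-sphere sets (one 4.6 Å
and one 2.0 Å sphere per cavity) guarantee every planted residue a
contact fraction of 1.0; decoy sphere sets sit on unplanted backbone
stretches. The corpus generator emits the three benchmark tiers
(negative controls, single-site, multi-site documents), annotations
matching the planted truth, and canned mock responses — optionally
corrupted with split pockets, hallucinated residues and malformed tokens
to exercise refinement and validation, with the refinement response
always restoring the truth.

Passing on these fixtures therefore demonstrates the pipeline's *logic*:
threshold semantics, interface vs replica decisions, selection and
merging behaviour, grid-predicate correctness, and end-to-end
determinism. It deliberately does not demonstrate robustness to real
LLM output variability, real structural noise (missing density,
conformational heterogeneity), or real prose — those depend on the
backend model and corpus, which are external to the package. Problem
sizes are kept small by design (chains of 25–40 residues, grids of
tens of points, oracle checks over dozens of random pockets), which is
ample for exercising every predicate the pipeline evaluates.

## Parameter summary

| Parameter | Default | Units | Role |
|---|---|---|---|
| `chain_match_threshold` | 0.6 | fraction | candidate-chain similarity floor (inclusive) |
| `cluster_match_threshold` | 0.7 | fraction | cluster-to-pocket overlap floor (inclusive) |
| `residue_match_threshold` | 0.5 | fraction | heavy-atom contact fraction per residue |
| `pocket_match_jaccard` | 0.3 | fraction | geometric-vs-literature selection floor (inclusive) |
| `merge_overlap_threshold` | 0.5 | fraction | pairwise merge trigger (strict) |
| `spacing` | 1.5 | Å | grid step |
| `bandwidth` | 8 | Å | MeanShift kernel radius |
| `contact_tol` | 1.0 | Å | atom-to-sphere contact tolerance |
| `retries` | 2 | – | backend retries per stage |

The 0.6/0.7 thresholds and the 1.5 Å spacing are the calibrated
operating points of the method; the residue-match, pocket-match and
merge-overlap defaults are the package's own choices (sensible floors
rather than tuned optima) and are exposed in `pipeline_config()` for
exactly that reason.

## Known limitations

- Positional similarity cannot resolve chains with insertions/deletions
  relative to the published construct; only constant offsets are
  recoverable via `offset_scan`.
- Merging cannot split a geometric pocket that wrongly fuses two
  physical sites; the pipeline inherits that failure mode from the
  upstream detector.
- Interface detection requires the clustering step to isolate the
  interface residues; two distinct sites closer than the MeanShift
  bandwidth can collapse into one cluster.
- The brute-force hull enumeration is cubic in atom count and intended
  for pocket-sized atom sets, not whole structures.
- With a real backend, end-to-end determinism holds only at temperature
  0 and subject to the service's own stability; bit-reproducibility is
  guaranteed only with the mock.
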