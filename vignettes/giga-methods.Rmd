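---
title: "Methods: species-tree-constrained gene-tree inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-tree-constrained gene-tree inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giga)
```

## The model

`giga` infers a rooted gene family tree by greedy agglomeration over raw
pairwise sequence differences, under two hard constraints that become
available once whole genomes are sequenced: a known rooted species tree and
complete knowledge of the family's gene content per genome. The tree is
represented as **orthologous subtrees** (OS's) — groups of genes related
only by speciation, at most one gene per species — connected by **founding
copy events** (FCEs), i.e. gene duplications located on species-tree edges.

The assumptions this buys, and their price:

* *The species tree is correct.* Incongruence caused by incomplete lineage
  sorting, hybridization or horizontal transfer is outside the model; short
  speciation intervals should be encoded as multifurcations in the input
  species tree (multifurcations are fully supported and never resolved
  arbitrarily).
* *Gene content is complete.* Dating a duplication by deletion parsimony is
  only meaningful when absence of a gene is established absence, not missing
  data. Partial gene predictions are handled separately (fragment
  quarantine), but missing genes silently make inferred duplication dates
  too recent.
* *Sequence similarity indicates common ancestry but not reliable dates.*
  Distances order the agglomeration and arbitrate revisions; they never
  override genomic evidence.

## The iteration

Each step takes the globally closest untreated sequence pair whose members
lie in different live OS's. If the two OS's share a species, the pair can
only be joined by a duplication (genomic proof); the founded OS is the one
with the more recent species-tree MRCA, and its FCE is placed on the edge
immediately above that MRCA — the placement minimizing implied gene losses.
With equal MRCAs both OS's are founded, as mutual siblings. If the species
sets are disjoint, the OS's are merged into one OS whose internal topology
is rebuilt as the species-tree restriction over the union. A merge or join
that contradicts an already-dated FCE is allowed only under the
significance test described below; otherwise the pair is marked treated and
skipped. The run is complete when the pair list is exhausted; quarantined
fragments then get one re-insertion attempt each, and remaining unconnected
OS components are attached at an unresolved multifurcating root.

"Phylogenetic span" comparisons are operationalized as MRCA containment:
span(B) ≤ span(A) iff the species-tree MRCA of B lies in the subtree rooted
at the MRCA of A. When both OS's of a pair already carry located FCEs, none
of the enumerated conditions applies and the pair is skipped; such
components meet only at the unresolved root.

## Tunable parameters

All constants live in `giga_config()`:

| parameter | default | meaning |
|---|---|---|
| `gap_threshold` | 0.15 | maximum weighted fraction of gapped sequences for a kept alignment column |
| `fragment_coverage` | 0.5 | fraction of expected ancestral sites at or below which a sequence is a fragment |
| `fragment_exempt_os_size` | 3 | other sequences in an OS that exempt a member from the fragment test |
| `ortholog_sd_multiplier` | 1.5 | significance multiplier when the alternative hypothesis implies no duplication |
| `paralog_sd_multiplier` | 0.5 | multiplier when the alternative implies a duplication |
| `alphabet_states` | 20 | states for the Jukes–Cantor correction (amino acids) |
| `max_distance` | 5 | substitutions/site substituted for saturated branch lengths |
| `revision_literal_sign` | FALSE | see "Sign of the revision test" |

Distances are dimensionless fractions of differing sites; branch lengths
are expected substitutions per site after the s-state Jukes–Cantor
correction `d = -((s-1)/s)·ln(1 - (s/(s-1))p)`, with standard deviation
`sqrt(p(1-p)/(n(1-(s/(s-1))p)^2))` for `n` compared sites.

## Design choices where the procedure was genuinely open

**Sequence weighting.** The trimming threshold needs redundancy-aware
weights but no particular scheme; Henikoff-style position-based weighting
is implemented (each column's residues share weight `1/(r·s)`), with gapped
sequences contributing nothing at a column. Weights are normalized to sum
to the sequence count and feed only the 15% trim rule.

**Pairwise-complete distances.** `p` and `n` for a pair use only kept
columns where both sequences carry a residue; gaps and ambiguity characters
('X', 'B', 'Z', '*') never count as matches or mismatches. Fragments are
guarded against separately, so excluding gapped sites does not let short
sequences dominate.

**Sign of the revision test.** The operational inequality is stated over
`dist1` (focal group to candidate orthologs) and `dist2` (focal group to
the established paralogous sibling). Read literally, "dist1 − dist2 >
m·(sd1+sd2)" would fire when the focal group is *farther* from the
candidate orthologs, contradicting the surrounding rationale that strong
orthology evidence should license the revision. The package follows the
rationale: the test passes when `dist2 − dist1 > m·(sd1+sd2)`. The literal
orientation is preserved behind `revision_literal_sign = TRUE` rather than
silently discarded.

**Fragment test denominators.** Expected ancestral sites are the trimmed
columns at which more than half of the candidate merged group — *excluding
the sequence under test* — carry a residue. Including the candidate makes
the two-sequence case degenerate (the poll reduces to the pairwise
intersection, so a truncated sequence driving its first merge can never be
flagged and is exempt by the time larger comparisons occur). Excluding it
restores the intended meaning, an estimate of the ancestral sites from
independent evidence, and makes detection of a planted 60%-truncated
sequence deterministic.

**Ancestral-state outgroup.** The "closest outgroup" of a node is its
sibling subtree(s) at its parent. In post-order, a sibling already
reconstructed contributes its own state; an unvisited sibling contributes
the strict majority of its leaf residues. The root has no outgroup, so
unresolved ties there become 'X'. Gaps count toward the per-site majority
but are never emitted as ancestral residues ('X' instead), and 'X' children
are excluded from the majority denominator.

**Branch lengths under a duplication.** For edges descending directly from
a duplication node, sites are restricted to those carrying a residue in
*every leaf descendant* of that node, so the two post-duplication branches
are measured on a common support despite site-rate heterogeneity. Leaf
residues rather than reconstructed internal states define this mask,
because an internal 'X' encodes uncertainty, not absence.

**Determinism.** Distance ties in the pair queue are broken by the
lexicographic order of the sorted id pair; group distances resolve ties
toward the lexicographically first pair; root components are ordered by
their smallest leaf id. Identical inputs therefore produce byte-identical
trees and event logs.

**Degenerate inputs.** A species tree may contain species with no
sequences (they are logged and never match); a pair with zero shared
columns gets `p = 0` with a flag; saturated p-distances (≥ 19/20) raise an
error in `jc_distance` and are capped at `max_distance` in branch lengths;
an OS emptied by quarantine simply stops anchoring attachments, and any
founded OS whose sibling can no longer host it falls back to the unresolved
root. A cyclic sibling graph (possible only through pathological distance
matrices) is reported as an internal error together with the event log.

## What the simulator emulates — and what it does not

`simulate_family()` evolves one root gene down the species tree:
duplications arrive per edge as Poisson events (default 0.05/edge) or at
forced positions, each founding a sibling lineage whose ground-truth
placement is recorded; lineages are lost per edge with probability 0.01 by
default; substitutions hit each site per edge with probability 0.05 under a
uniform 20-state exchange model, times an acceleration factor (default 1.5)
on a newly founded copy for the remainder of its founding edge. Those
defaults are chosen to resemble well-diverged curated protein families:
average pairwise identities around 50–60% at typical tree depths, roughly
one duplication per family, occasional loss. Alignments are gap-free except
for planted fragments, which replace a trailing fraction of a sequence with
gaps.

The simulator deliberately omits indel evolution, alignment error,
site-rate heterogeneity within a lineage, codon structure, horizontal
transfer and incomplete lineage sorting. Passing tests on simulated
families therefore demonstrates the *algorithmic* properties — congruence,
placement recovery, soundness of the genomic-proof rule, fragment handling,
robustness, determinism — not performance on real alignments, whose main
difficulties (alignment quality, rate heterogeneity) are outside the model.

## Validation battery and problem sizes

The test suite and `scripts/acceptance.R` use random 10–20-leaf species
trees with 300-site alignments for congruence and placement recovery,
12–16-leaf families for fragment handling, 10–14-leaf families for the
taxon-removal robustness protocol, and trees of at most 10 leaves for the
brute-force oracle comparisons (where the package's Robinson–Foulds and
ortholog-pair implementations must agree exactly with independent
enumerators). These sizes exercise every rule, including multifurcations
and nested duplications, while keeping a full run in the order of a minute.

Two behaviours deserve emphasis because they are properties of the method,
not defects of the implementation:

* *Placement recovery is near-perfect but not guaranteed.* When a
  cross-copy sequence pair happens, by substitution noise, to be closer
  than the last within-copy pair, a duplication is dated too recently and
  the later revision needs a margin of roughly twice one edge's divergence
  against 0.5–1.5 summed standard deviations. At 300 sites this is usually,
  but not always, significant; the acceptance script reports the measured
  recovery rate.
* *Dropping taxa can move duplications.* The genomic-proof rule depends on
  exactly the information that taxon removal deletes. In particular, a
  terminal-edge duplication whose two copies meet as the first pair becomes
  a mutual-sibling component that can only rejoin the main subtree with
  significant distance evidence, whose expected margin is zero for
  terminal-edge events. The robustness rate the script reports reflects
  this.

## Known limitations

* Vertical inheritance only: no horizontal-transfer FCEs, no
  whole-genome-duplication-aware rules, no ILS modeling.
* The local ancestral reconstruction and Jukes–Cantor branch lengths are
  deliberately simple; for publication-grade branch lengths, re-estimate on
  the fixed topology with an ML tool.
* Dating quality degrades with incomplete genomes, since established
  absence is what deletion parsimony consumes.
* Distances come from the given alignment; the package neither builds nor
  scores alignments.
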