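# giga

Gene-tree inference under species-tree and genome-content constraints.

## The problem

Gene trees built from a single family's sequences are notoriously unstable:
alignments are short, lineage-specific rate acceleration is common
(especially after gene duplication), and distance- or likelihood-based
methods happily produce topologies that contradict well-established species
relationships. In the genomic era two additional sources of evidence are
available for free: a reliable rooted **species tree** and the (near)
complete **gene content** of each genome. `giga` uses both as hard
constraints while building a gene family tree agglomeratively from nothing
more than raw pairwise sequence differences.

The package is aimed at phylogenomics work — large-scale ortholog
inference, family-by-family tree building across whole genomes, and
stable identification of ancestral genes — where speed, determinism and
explainability matter more than a fully parameterized substitution model.

## The model

A gene tree is conceived as a set of **orthologous subtrees** (OS's):
maximal groups of genes related only by speciation events, containing at
most one gene per species. Distinct OS's are connected by **founding copy
events** (FCEs) — gene duplications, each located on a species-tree edge.
The inference iterates over sequence pairs `(x, y)` in ascending order of
raw p-distance

```
p = (# differing residues at homologous sites) / (# homologous sites)
```

computed once on a weighted-gap-trimmed alignment and never updated
(the distance between groups is the minimum over inter-group pairs).
At each step, with `OS1` and `OS2` the subtrees containing `x` and `y`:

* **Rule 1 (species-tree constraint).** Inside an OS the topology is the
  species tree restricted to the species present — sequence distances never
  rearrange it.
* **Rule 2 (genomic proof of duplication).** A duplication is inferred only
  when the union of the two groups would contain two genes from one species
  (a witness of non-orthology). Otherwise the groups are merged as
  orthologs, however divergent.
* **Rule 3 (dating by deletion parsimony).** A new duplication is placed on
  the species-tree edge immediately above the MRCA of the founded group's
  species — the placement implying the fewest independent gene losses. Equal
  MRCAs make the two groups mutual siblings.
* **Rule 4 (revision on significant evidence).** Merging into a group whose
  FCE is already dated is allowed only if the newcomers are closer to it
  than to its paralogous sibling by more than `m·(sd1 + sd2)`, where the
  standard deviations come from the Jukes–Cantor error formula
  `sd = sqrt(p(1-p) / (n (1 - (s/(s-1))p)^2))` (s = 20 for proteins), and
  `m` is 1.5 when the alternative implies no duplication, 0.5 otherwise.
  Dates are only ever revised rootward.
* **Rule 5 (fragment quarantine).** A sequence aligning ≤ 50% of the sites
  expected present in its candidate subtree's ancestor is quarantined and
  re-inserted (one attempt) after all full-length sequences are placed.

After the topology is fixed, ancestral sequences are reconstructed by a
local strict-majority rule with outgroup tie-breaking, and branch lengths
are the Jukes–Cantor-corrected parent–child differences
`d = -((s-1)/s) · ln(1 - (s/(s-1)) p)`.

## Worked example

Simulate a family with one duplication at the base of the fungi, then
recover it:

```r
library(giga)
sp  <- parse_species_tree(
  "(((HUMAN,MOUSE)Euarchontoglires,CHICK)Amniota,((YEAST,SCHPO)Fungi,DICDI)Opisthokonta)Root;")
fam <- simulate_family(simulation_config(sp, dup_rate = 0, loss_prob = 0,
                                         forced_duplications = "Fungi",
                                         seed = 42))
trm <- trim_alignment(fam$alignment)
fit <- run_giga(trm, sptree = sp)
fit
#> Gene-tree inference: 8 sequences -> 2 orthologous subtree(s)
#> Gene tree: 8 sequences, 6 speciation and 1 duplication node(s)
#> (((g1_HUMAN[&&NHX:S=HUMAN],g1_MOUSE[&&NHX:S=MOUSE])[&&NHX:Ev=S:S=Euarchontoglires],
#>  g1_CHICK[...])[&&NHX:Ev=S:S=Amniota],(((g1_YEAST[...],g1_SCHPO[...])[&&NHX:Ev=S:S=Fungi],
#>  (g2_YEAST[...],g2_SCHPO[...])[&&NHX:Ev=S:S=Fungi])[&&NHX:Ev=D:P=Fungi],
#>  g1_DICDI[...])[&&NHX:Ev=S:S=Opisthokonta])[&&NHX:Ev=S:S=Root];
```

The two fungal copies form their own orthologous subtree whose founding
duplication is placed on the edge just above the fungal ancestor
(`Ev=D:P=Fungi`), exactly where it was simulated:

```r
fit$os[, c("os", "n_members", "mrca", "fce_placement", "sibling")]
#>   os n_members  mrca fce_placement sibling
#> 1  1         6  Root          <NA>      NA
#> 2  6         2 Fungi         Fungi       1

rf_distance(fit$tree, fam$true_tree)
#> [1] 0
```

Orthologs are the leaf pairs whose MRCA is a speciation node — 24 pairs
here; the two fungal paralog pairs (e.g. `g1_YEAST`–`g2_YEAST`) are
correctly excluded:

```r
length(extract_ortholog_pairs(fit$tree))
#> [1] 24
```

Ancestral states and corrected branch lengths:

```r
anc <- infer_ancestral_states(fit$tree, trm)
bl  <- branch_lengths(anc)
head(bl$edges[, c("parent", "child", "p", "n_sites", "length")], 4)
#>   parent    child          p n_sites     length
#> 1     A1       A2 0.00000000     270 0.00000000
#> 2     A2       A3 0.07142857     294 0.07425653
#> 3     A3 g1_HUMAN 0.03355705     298 0.03416406
#> 4     A3 g1_MOUSE 0.06375839     298 0.06599875
```

Every decision the algorithm took — merges, duplication joins, date
revisions, refusals, quarantines — is in `fit$events`, so any feature of
the tree can be traced to the rule and sequence pair that produced it.

A command-line front end (`inst/scripts/giga`) wraps the same functions:

```sh
giga infer --alignment family.fasta --species-tree species.nwk \
     --out-tree tree.nhx --out-orthologs orthologs.tsv
giga compare --tree-a tree.nhx --tree-b other.nhx --mode orthologs
```

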