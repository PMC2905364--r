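# Evaluation metrics: ortholog-pair extraction and difference, normalized
# Robinson-Foulds distance, and the clean-vs-full robustness comparison.

#' Extract ortholog pairs from a labeled gene tree
#'
#' Two sequences are orthologs iff their most recent common ancestor in the
#' gene tree is a speciation event. Pairs whose MRCA is a duplication node or
#' the unresolved root are excluded (the latter are reported in the
#' \code{unresolved} attribute). Pairs within one species under a speciation
#' MRCA would violate the one-gene-per-species property of orthologous
#' subtrees; they are excluded and counted in the \code{within_species}
#' attribute so the invariant can be asserted rather than assumed.
#'
#' @param tree A \code{gene_tree} with every internal node labeled
#'   speciation, duplication or (unresolved) root.
#' @return Character vector of canonical pairs \code{"id1|id2"} (ids sorted
#'   within the pair, vector sorted), with attributes \code{unresolved} and
#'   \code{within_species} (counts).
#' @export
extract_ortholog_pairs <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  pairs <- character(0)
  unresolved <- 0L
  within_species <- 0L
  sp_map <- new.env(parent = emptyenv())
  collect <- function(node) {
    if (node$type == "leaf")
      assign(node$id,
             if (!is.null(node$species) && !is.na(node$species))
               node$species else species_from_id(node$id),
             envir = sp_map)
    else lapply(node$children, collect)
    invisible(NULL)
  }
  collect(tree$root)
  species_of <- function(id) get(id, envir = sp_map)
  rec <- function(node) {
    if (node$type == "leaf") return(node$id)
    if (!node$type %in% c("speciation", "duplication", "root"))
      stop("unlabeled internal node in gene tree")
    kid_leaves <- lapply(node$children, rec)
    if (node$type == "speciation") {
      k <- length(kid_leaves)
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
        for (x in kid_leaves[[a]]) for (y in kid_leaves[[b]]) {
          if (identical(species_of(x), species_of(y))) {
            within_species <<- within_species + 1L
          } else {
            pairs[[length(pairs) + 1L]] <<- paste(min(x, y), max(x, y),
                                                  sep = "|")
          }
        }
      }
    } else if (node$type == "root") {
      k <- length(kid_leaves)
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
        unresolved <<- unresolved +
          length(kid_leaves[[a]]) * length(kid_leaves[[b]])
    }
    unlist(kid_leaves, use.names = FALSE)
  }
  rec(tree$root)
  structure(sort(pairs), unresolved = unresolved,
            within_species = within_species)
}

#' Ortholog-pair difference between two trees
#'
#' \code{1 - |intersection| / |union|} of the two ortholog-pair sets (one
#' minus the Jaccard overlap); 0 when both sets are empty. A local
#' rearrangement of speciation nodes leaves this measure unchanged, so it
#' isolates disagreement about duplication events.
#'
#' @param a,b Ortholog-pair sets from \code{\link{extract_ortholog_pairs}}
#'   (any character vectors of canonical pairs).
#' @return A fraction in \code{[0, 1]}.
#' @export
ortholog_pair_difference <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

# Non-trivial bipartitions of a tree over its leaf set, as canonical keys.
# Each internal node below the root defines the split (its leaves | rest);
# the canonical key is the sorted side not containing the reference leaf, so
# rooted placement does not affect the comparison.
tree_bipartitions <- function(tree) {
  if (inherits(tree, "phylo")) tree <- phylo_to_gene_tree(tree)
  leaves <- sort(tree$leaves)
  n <- length(leaves)
  ref <- leaves[1]
  keys <- character(0)
  rec <- function(node, is_root) {
    if (node$type == "leaf") return(node$id)
    lv <- unlist(lapply(node$children, rec, FALSE), use.names = FALSE)
    if (!is_root && length(lv) >= 2L && n - length(lv) >= 2L) {
      side <- if (ref %in% lv) setdiff(leaves, lv) else lv
      keys[[length(keys) + 1L]] <<- paste(sort(side), collapse = "|")
    }
    lv
  }
  rec(tree$root, TRUE)
  unique(keys)
}

# Minimal phylo -> gene_tree conversion (topology only) so metrics accept
# ape trees directly.
phylo_to_gene_tree <- function(phy) {
  n_tips <- length(phy$tip.label)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(nd) {
    if (nd <= n_tips) return(gene_leaf(phy$tip.label[nd]))
    gene_internal("speciation",
                  lapply(children[[as.character(nd)]], rec))
  }
  new_gene_tree(rec(n_tips + 1L))
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions; with
#' \code{normalized = TRUE} (the default) it is divided by the total number
#' of non-trivial bipartitions in the two trees, so 0 means identical
#' topologies and 1 means no shared bipartitions. This normalization handles
#' multifurcating trees, whose bipartition counts differ from the binary
#' \code{2(n-3)}. Trees with no non-trivial bipartitions at all (fewer than
#' 4 leaves, or star trees) are at distance 0 from each other.
#'
#' @param t1,t2 \code{gene_tree} or \code{ape::phylo} objects over the same
#'   leaf set.
#' @param normalized Return the normalized distance (default) or the raw
#'   symmetric-difference count.
#' @return A number, in \code{[0, 1]} when normalized.
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  if (inherits(t1, "phylo")) t1 <- phylo_to_gene_tree(t1)
  if (inherits(t2, "phylo")) t2 <- phylo_to_gene_tree(t2)
  if (!setequal(t1$leaves, t2$leaves))
    stop("trees must share an identical leaf set")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  raw <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (!normalized) return(raw)
  denom <- length(b1) + length(b2)
  if (denom == 0L) return(0)
  raw / denom
}

#' Clean-vs-full robustness comparison
#'
#' Measures how much additional sequences changed the inferred topology for
#' a core ("clean") set: the full tree is restricted to the clean leaves
#' (suppressing unary nodes) and compared to the clean-only tree by
#' normalized Robinson-Foulds distance. 0 means the extra sequences did not
#' perturb the core topology at all.
#'
#' @param full_tree A \code{gene_tree} containing all sequences.
#' @param clean_tree A \code{gene_tree} over the clean subset.
#' @param clean_leaves Leaves defining the clean subset; defaults to the
#'   leaves of \code{clean_tree}.
#' @return Normalized RF distance in \code{[0, 1]}.
#' @export
robustness_compare <- function(full_tree, clean_tree,
                               clean_leaves = clean_tree$leaves) {
  if (!all(clean_leaves %in% full_tree$leaves))
    stop("clean leaves must be a subset of the full tree's leaves")
  restricted <- restrict_gene_tree(full_tree, clean_leaves)
  rf_distance(restricted, restrict_gene_tree(clean_tree, clean_leaves))
}
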