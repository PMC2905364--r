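#' Parse and validate a rooted species tree
#'
#' Reads a rooted, possibly multifurcating species tree in newick format and
#' builds the indexed structure used for MRCA and ancestry queries during
#' gene-tree inference. The species tree supplies the topological constraint:
#' inside an orthologous subtree the gene-tree topology is always the species
#' tree restricted to the species present.
#'
#' Branch lengths and comments in the input are ignored; only the topology and
#' the leaf labels (species codes) are used. Internal node labels are kept if
#' present; unlabeled internal nodes receive stable auto-generated identifiers
#' of the form \code{N<k>} so duplication placements are always reportable.
#'
#' @param text A newick string, or the path of a file containing one.
#' @return An object of class \code{species_tree} with components:
#'   \describe{
#'     \item{phy}{the underlying \code{ape::phylo} object (rooted)}
#'     \item{n_tips}{number of species}
#'     \item{labels}{character vector of labels indexed by node id
#'       (tips \code{1..n_tips}, internal nodes after)}
#'     \item{parent}{parent node id per node (\code{NA} at the root)}
#'     \item{children}{list of child node ids per node}
#'     \item{depth}{edge count from the root per node}
#'     \item{ancestors}{per node, the node ids on its path to the root,
#'       starting with the node itself}
#'     \item{leaf_index}{named integer vector mapping species code to tip id}
#'     \item{root}{the root node id}
#'   }
#' @examples
#' sp <- parse_species_tree("((HUMAN,MOUSE),YEAST);")
#' species_mrca(sp, c("HUMAN", "MOUSE"))
#' @export
parse_species_tree <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop("species tree input must be a single newick string or file path")
  if (file.exists(text) && !grepl(";", text, fixed = TRUE))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(phy)) {
    # locate the first structural defect for the error message
    bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                         ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
    pos <- if (any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop(sprintf("malformed newick near character %d", pos))
  }
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (anyDuplicated(phy$tip.label))
    stop("duplicate species code in species tree: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (any(!nzchar(phy$tip.label)))
    stop("empty leaf label in species tree")
  phy$edge.length <- NULL # topology only
  new_species_tree(phy)
}

# Build the indexed species_tree structure from a rooted ape phylo.
new_species_tree <- function(phy) {
  n_tips <- length(phy$tip.label)
  n_nodes <- n_tips + phy$Nnode
  parent <- rep(NA_integer_, n_nodes)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1]]] <- c(children[[phy$edge[i, 1]]], phy$edge[i, 2])
  root <- which(is.na(parent) & seq_len(n_nodes) > n_tips)
  if (length(root) != 1L) {
    if (n_tips == 1L && n_nodes == 1L) root <- 1L else
      stop("species tree must have a single root")
  }
  depth <- rep(NA_integer_, n_nodes)
  depth[root] <- 0L
  # breadth-first: parents always precede children
  queue <- root
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    for (ch in children[[nd]]) {
      depth[ch] <- depth[nd] + 1L
      queue <- c(queue, ch)
    }
  }
  ancestors <- vector("list", n_nodes)
  for (nd in seq_len(n_nodes)) {
    path <- nd
    cur <- nd
    while (!is.na(parent[cur])) {
      cur <- parent[cur]
      path <- c(path, cur)
    }
    ancestors[[nd]] <- path
  }
  labels <- character(n_nodes)
  labels[seq_len(n_tips)] <- phy$tip.label
  internal <- setdiff(seq_len(n_nodes), seq_len(n_tips))
  given <- phy$node.label
  for (i in seq_along(internal)) {
    lab <- if (!is.null(given) && i <= length(given)) given[i] else ""
    if (is.na(lab) || !nzchar(lab)) lab <- paste0("N", i)
    labels[internal[i]] <- lab
  }
  leaf_index <- stats::setNames(seq_len(n_tips), phy$tip.label)
  structure(
    list(phy = phy, n_tips = n_tips, labels = labels, parent = parent,
         children = children, depth = depth, ancestors = ancestors,
         leaf_index = leaf_index, root = root),
    class = "species_tree"
  )
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("Species tree: %d species, %d internal nodes (root %s)\n",
              x$n_tips, length(x$labels) - x$n_tips, x$labels[x$root]))
  invisible(x)
}

# Map species codes to tip ids, failing loudly on unknown codes.
species_tips <- function(tree, species) {
  idx <- tree$leaf_index[species]
  if (anyNA(idx))
    stop("unknown species code(s): ",
         paste(species[is.na(idx)], collapse = ", "))
  unname(idx)
}

#' Most recent common ancestor of a set of species
#'
#' Returns the deepest species-tree node ancestral to every listed species.
#' The MRCA of a single species is that species' leaf. This is the "MRCA
#' speciation event" used to date founding copy events: a group of orthologs
#' must be at least as old as the MRCA of its species.
#'
#' @param tree A \code{species_tree}.
#' @param species Character vector of species codes (nonempty).
#' @return The node id of the MRCA (an index into \code{tree$labels}).
#' @export
species_mrca <- function(tree, species) {
  stopifnot(length(species) >= 1L)
  tips <- species_tips(tree, unique(species))
  if (length(tips) == 1L) return(tips)
  common <- Reduce(intersect, tree$ancestors[tips])
  common[which.max(tree$depth[common])]
}

# TRUE iff node `b` lies in the subtree rooted at node `a`.
node_within <- function(tree, a, b) a %in% tree$ancestors[[b]]

#' Compare phylogenetic spans of two species sets
#'
#' The phylogenetic span of a set of species is its MRCA on the species tree.
#' \code{span_within(tree, a, b)} is \code{TRUE} iff the span of \code{b} is
#' less than or equal to the span of \code{a}, i.e. \code{mrca(b)} is
#' \code{mrca(a)} itself or one of its descendants. This is the constraint
#' used when deciding whether joining two orthologous subtrees would force a
#' revision of an earlier duplication-dating hypothesis.
#'
#' @param tree A \code{species_tree}.
#' @param span_a,span_b Nonempty character vectors of species codes.
#' @return Logical scalar.
#' @export
span_within <- function(tree, span_a, span_b) {
  node_within(tree, species_mrca(tree, span_a), species_mrca(tree, span_b))
}

#' Serialize a species tree back to newick
#'
#' @param tree A \code{species_tree}.
#' @return A newick string (topology and labels only).
#' @export
write_species_tree <- function(tree) {
  ape::write.tree(tree$phy)
}

# Species-tree restriction: the gene-subtree topology over one gene per
# species (Rule 1). `members` is a named character vector species -> seq id.
# Returns a gene_node (see gene_tree.R) with unary nodes suppressed, or NULL.
restrict_topology <- function(tree, members) {
  tips <- species_tips(tree, names(members))
  keep <- stats::setNames(unname(members), tips)
  rec <- function(nd) {
    if (nd <= tree$n_tips) {
      sid <- keep[as.character(nd)]
      if (is.na(sid)) return(NULL)
      return(gene_leaf(unname(sid), species = tree$labels[nd]))
    }
    kids <- Filter(Negate(is.null), lapply(tree$children[[nd]], rec))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    gene_internal("speciation", kids, species_node = nd,
                  species = tree$labels[nd])
  }
  rec(tree$root)
}
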