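# Gene-tree node structure. A gene tree is a rooted tree whose leaves are
# sequences and whose internal nodes are labeled evolutionary events:
#   speciation  - maps to a species-tree node
#   duplication - a founding copy event, located on the species-tree edge
#                 immediately above the recorded `placement` node
#   root        - an unresolved multifurcation joining components that no
#                 event connected
# Nodes are plain lists; the tree object (class "gene_tree") wraps the root.

gene_leaf <- function(id, species = NA_character_) {
  list(type = "leaf", id = id, species = species, children = list())
}

gene_internal <- function(type, children, species_node = NA_integer_,
                          species = NA_character_,
                          placement_node = NA_integer_,
                          placement = NA_character_) {
  stopifnot(type %in% c("speciation", "duplication", "root"))
  list(type = type, id = NA_character_, species = species,
       species_node = species_node, placement_node = placement_node,
       placement = placement, children = children)
}

#' Construct a gene tree object
#'
#' @param root The root gene node (internal representation).
#' @return An object of class \code{gene_tree}.
#' @keywords internal
new_gene_tree <- function(root) {
  structure(list(root = root, leaves = gene_node_leaves(root)),
            class = "gene_tree")
}

# All leaf sequence ids below a node, in traversal order.
gene_node_leaves <- function(node) {
  if (node$type == "leaf") return(node$id)
  unlist(lapply(node$children, gene_node_leaves), use.names = FALSE)
}

#' @export
print.gene_tree <- function(x, ...) {
  counts <- table(factor(
    unlist(gene_node_apply(x$root, function(n) n$type)),
    levels = c("leaf", "speciation", "duplication", "root")))
  cat(sprintf(
    "Gene tree: %d sequences, %d speciation and %d duplication node(s)%s\n",
    counts[["leaf"]], counts[["speciation"]], counts[["duplication"]],
    if (counts[["root"]] > 0) ", unresolved root" else ""))
  cat(write_newick(x), "\n")
  invisible(x)
}

# Apply FUN to every node, returning a flat list of results.
gene_node_apply <- function(node, fun) {
  c(list(fun(node)), unlist(lapply(node$children, gene_node_apply, fun),
                            recursive = FALSE))
}

#' Convert a gene tree to an ape phylo object
#'
#' Internal nodes carry labels of the form \code{S:<species>} for speciation
#' nodes, \code{D:<placement>} for duplication nodes and \code{ROOT} for an
#' unresolved root. Branch lengths, when present on the nodes (set by
#' \code{\link{branch_lengths}}), are carried over.
#'
#' @param x A \code{gene_tree}.
#' @param ... Unused.
#' @return An object of class \code{phylo}.
#' @exportS3Method ape::as.phylo
as.phylo.gene_tree <- function(x, ...) {
  tips <- x$leaves
  n_tips <- length(tips)
  if (n_tips < 2L)
    stop("cannot convert a gene tree with fewer than 2 leaves to phylo")
  edges <- list(); edge_len <- c()
  node_label <- character(0)
  next_internal <- n_tips
  has_len <- FALSE
  rec <- function(node) {
    if (node$type == "leaf") return(match(node$id, tips))
    next_internal <<- next_internal + 1L
    me <- next_internal
    node_label[me - n_tips] <<- node_label_string(node)
    for (ch in node$children) {
      ch_id <- rec(ch)
      edges[[length(edges) + 1L]] <<- c(me, ch_id)
      len <- if (!is.null(ch$length)) ch$length else NA_real_
      if (!is.na(len)) has_len <<- TRUE
      edge_len <<- c(edge_len, len)
    }
    me
  }
  rec(x$root)
  phy <- list(edge = do.call(rbind, edges),
              tip.label = tips,
              node.label = node_label,
              Nnode = next_internal - n_tips)
  if (has_len) phy$edge.length <- ifelse(is.na(edge_len), 0, edge_len)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  stats::reorder(phy)
}

node_label_string <- function(node) {
  switch(node$type,
         speciation = paste0("S:", node$species),
         duplication = paste0("D:", node$placement),
         root = "ROOT")
}

#' Write a gene tree as newick, optionally with NHX event annotations
#'
#' With \code{nhx = TRUE} each internal node carries an NHX comment:
#' \code{[&&NHX:Ev=S:S=<species node>]} for speciation nodes and
#' \code{[&&NHX:Ev=D:P=<placement node>]} for duplication nodes, where the
#' placement names the species-tree node immediately below the duplication.
#' Leaves carry \code{[&&NHX:S=<species>]}.
#'
#' @param x A \code{gene_tree}.
#' @param path Optional file path; when \code{NULL} the string is returned.
#' @param nhx Include NHX annotations (default \code{TRUE}).
#' @param digits Digits for branch lengths, when present.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(x, path = NULL, nhx = TRUE, digits = 8) {
  fmt_len <- function(node) {
    if (is.null(node$length) || is.na(node$length)) ""
    else paste0(":", format(node$length, digits = digits, scientific = FALSE))
  }
  rec <- function(node) {
    if (node$type == "leaf") {
      ann <- if (nhx && !is.na(node$species))
        paste0("[&&NHX:S=", node$species, "]") else ""
      return(paste0(node$id, ann, fmt_len(node)))
    }
    inner <- paste(vapply(node$children, rec, character(1)), collapse = ",")
    ann <- if (!nhx) "" else switch(
      node$type,
      speciation = paste0("[&&NHX:Ev=S:S=", node$species, "]"),
      duplication = paste0("[&&NHX:Ev=D:P=", node$placement, "]"),
      root = "[&&NHX:Ev=R]")
    paste0("(", inner, ")", ann, fmt_len(node))
  }
  s <- paste0(rec(x$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a gene tree written by \code{write_newick}
#'
#' NHX comments are extracted first and the remaining plain newick is parsed
#' with \code{ape::read.tree}; event annotations are then re-attached, so
#' \code{read_newick(write_newick(x, path))} reproduces the tree exactly.
#' Plain newick without NHX comments is accepted: internal nodes then come
#' back with labels but no event types.
#'
#' @param path File path (or a newick string containing a semicolon).
#' @return A \code{gene_tree}.
#' @export
read_newick <- function(path) {
  text <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                       collapse = "") else path
  m <- gregexpr("\\[&&NHX:[^]]*\\]", text)[[1]]
  anns <- character(0)
  if (m[1] != -1) {
    anns <- regmatches(text, list(m))[[1]]
    parts <- regmatches(text, list(m), invert = TRUE)[[1]]
    out <- parts[1]
    for (i in seq_along(anns))
      out <- paste0(out, "@@", i, "@@", parts[i + 1])
    text <- out
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse newick input")
  strip <- function(lab) sub("@@[0-9]+@@$", "", lab)
  ann_of <- function(lab) {
    mm <- regmatches(lab, regexpr("@@([0-9]+)@@$", lab))
    if (!length(mm)) return(NULL)
    parse_nhx(anns[as.integer(gsub("@", "", mm))])
  }
  n_tips <- length(phy$tip.label)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  edge_len <- if (!is.null(phy$edge.length))
    stats::setNames(phy$edge.length, phy$edge[, 2]) else NULL
  root <- n_tips + 1L
  rec <- function(nd) {
    if (nd <= n_tips) {
      lab <- phy$tip.label[nd]
      ann <- ann_of(lab)
      leaf <- gene_leaf(strip(lab),
                        species = if (!is.null(ann$S)) ann$S
                                  else species_from_id(strip(lab)))
      if (!is.null(edge_len)) leaf$length <- unname(edge_len[as.character(nd)])
      return(leaf)
    }
    lab <- if (!is.null(phy$node.label)) phy$node.label[nd - n_tips] else ""
    ann <- ann_of(lab)
    kids <- lapply(children[[as.character(nd)]], rec)
    node <- if (!is.null(ann$Ev) && ann$Ev == "D") {
      gene_internal("duplication", kids, placement = ann$P)
    } else if (!is.null(ann$Ev) && ann$Ev == "R") {
      gene_internal("root", kids)
    } else {
      gene_internal("speciation", kids, species = if (!is.null(ann$S))
        ann$S else if (nzchar(strip(lab))) strip(lab) else NA_character_)
    }
    if (!is.null(edge_len) && nd != root)
      node$length <- unname(edge_len[as.character(nd)])
    node
  }
  new_gene_tree(rec(root))
}

parse_nhx <- function(s) {
  body <- sub("^\\[&&NHX:?", "", sub("\\]$", "", s))
  if (!nzchar(body)) return(list())
  kv <- strsplit(strsplit(body, ":", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- lapply(kv, function(x) if (length(x) > 1) x[2] else "")
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

#' Plot a gene tree
#'
#' Draws the tree with \code{ape::plot.phylo}; duplication nodes are marked
#' with filled squares, speciation nodes with circles.
#'
#' @param x A \code{gene_tree}.
#' @param ... Passed to \code{ape::plot.phylo}.
#' @method plot gene_tree
#' @export
plot.gene_tree <- function(x, ...) {
  phy <- as.phylo.gene_tree(x)
  ape::plot.phylo(phy, ...)
  types <- substr(phy$node.label, 1, 1)
  ape::nodelabels(pch = ifelse(types == "D", 15, 16),
                  col = ifelse(types == "D", "darkorange", "steelblue"),
                  cex = 0.8)
  invisible(x)
}

# Default species extraction: the UniProt-style suffix after the final '_'.
species_from_id <- function(id) {
  ifelse(grepl("_", id), sub(".*_", "", id), NA_character_)
}

# Restrict a gene tree to a subset of its leaves, suppressing unary nodes.
# Used by the robustness protocol (compare a full tree, restricted to the
# clean sequences, against the clean-only tree).
restrict_gene_tree <- function(x, keep) {
  rec <- function(node) {
    if (node$type == "leaf")
      return(if (node$id %in% keep) node else NULL)
    kids <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    node$children <- kids
    node
  }
  root <- rec(x$root)
  if (is.null(root)) stop("restriction removed every leaf")
  new_gene_tree(root)
}
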