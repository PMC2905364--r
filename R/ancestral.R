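# Approximate ancestral sequence reconstruction and corrected branch lengths
# on an inferred gene tree. The reconstruction is local and parsimony-like:
# each internal node is determined only by its children and closest outgroup.

# Residue classes at a trimmed-alignment site: amino-acid letters are
# informative states; '-' is a countable gap state that is never emitted as
# an ancestral residue; ambiguity codes collapse to 'X' (unknown).
canonical_state <- function(ch) {
  ifelse(ch %in% c("X", "B", "Z", "*", "."), "X",
         ifelse(ch == "-", "-", ch))
}

# strict-majority state among `states`, excluding 'X' from the denominator;
# returns "" when there is no strict majority
strict_majority <- function(states) {
  states <- states[states != "X"]
  if (!length(states)) return("")
  counts <- table(states)
  top <- names(counts)[which.max(counts)]
  if (counts[[top]] * 2L > length(states)) top else ""
}

#' Infer approximate ancestral sequences at every internal node
#'
#' Post-order recursion from the leaves: at each site, if over half of a
#' node's (non-unknown) child states agree, that state is ancestral; on
#' disagreement the closest outgroup (the node's sibling subtree; its
#' reconstructed sequence if already available, otherwise the majority of its
#' leaf residues) breaks the tie when it matches one of the children;
#' otherwise the site is unknown ('X'). Gaps count toward the majority but a
#' gap is never emitted as an ancestral residue (it becomes 'X'). The root
#' has no outgroup, so its ties become 'X'.
#'
#' @param tree A \code{gene_tree}.
#' @param trimmed The \code{trimmed_alignment} the tree was inferred from;
#'   every tree leaf must be one of its sequences.
#' @return An object of class \code{ancestral_states}: list with
#'   \code{states} (named character vector of residue strings, one per node;
#'   internal nodes are keyed \code{A1}, \code{A2}, ... in preorder) and
#'   \code{tree} (the input tree with an \code{anc_id} on every node).
#' @export
infer_ancestral_states <- function(tree, trimmed) {
  leaves <- tree$leaves
  if (!all(leaves %in% trimmed$ids))
    stop("tree leaves must be sequences of the trimmed alignment")
  L <- ncol(trimmed$matrix)
  leaf_state <- function(id) canonical_state(trimmed$matrix[id, ])
  counter <- 0L
  states <- list()
  # majority over the leaves of a subtree, used when an outgroup node's own
  # sequence has not been determined yet
  leaf_majority <- function(node) {
    lv <- gene_node_leaves(node)
    mat <- do.call(rbind, lapply(lv, leaf_state))
    vapply(seq_len(L), function(j) strict_majority(mat[, j]), character(1))
  }
  outgroup_profile <- function(siblings) {
    if (!length(siblings)) return(NULL)
    profs <- lapply(siblings, function(s) {
      key <- s$anc_id
      if (!is.null(key) && !is.null(states[[key]])) states[[key]]
      else if (s$type == "leaf") leaf_state(s$id)
      else leaf_majority(s)
    })
    if (length(profs) == 1L) return(profs[[1]])
    mat <- do.call(rbind, profs)
    vapply(seq_len(L), function(j)
      strict_majority(mat[, j][mat[, j] != ""]), character(1))
  }
  rec <- function(node, siblings) {
    if (node$type == "leaf") {
      node$anc_id <- node$id
      states[[node$id]] <<- leaf_state(node$id)
      return(node)
    }
    counter <<- counter + 1L
    node$anc_id <- paste0("A", counter)
    kids <- node$children
    for (k in seq_along(kids))
      kids[[k]] <- rec(kids[[k]], kids[-k])
    node$children <- kids
    child_states <- do.call(rbind, lapply(kids, function(k)
      states[[k$anc_id]]))
    og <- outgroup_profile(siblings)
    anc <- vapply(seq_len(L), function(j) {
      col <- child_states[, j]
      maj <- strict_majority(col)
      if (nzchar(maj)) return(if (maj == "-") "X" else maj)
      if (!is.null(og)) {
        o <- og[j]
        if (nzchar(o) && o != "X" && o != "-" && o %in% col) return(o)
      }
      "X"
    }, character(1))
    states[[node$anc_id]] <<- anc
    node
  }
  root <- rec(tree$root, list())
  structure(list(states = vapply(states, paste, character(1), collapse = ""),
                 states_chars = states,
                 tree = new_gene_tree(root)),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  n_int <- sum(grepl("^A[0-9]+$", names(x$states)))
  cat(sprintf("Ancestral states: %d internal node(s), %d sites\n",
              n_int, nchar(x$states[[1]])))
  invisible(x)
}

#' Write ancestral (and leaf) sequences to FASTA
#'
#' @param anc An \code{ancestral_states} object.
#' @param path Output path.
#' @param internal_only Write only internal-node sequences.
#' @export
write_ancestral_fasta <- function(anc, path, internal_only = TRUE) {
  s <- anc$states
  if (internal_only) s <- s[grepl("^A[0-9]+$", names(s))]
  Biostrings::writeXStringSet(Biostrings::AAStringSet(s), path)
  invisible(path)
}

#' Jukes-Cantor corrected branch lengths from node sequences
#'
#' For every edge, the raw distance is the fraction of differing residues
#' over sites where both endpoint states are known residues (neither unknown
#' nor gap); the corrected length is \code{\link{jc_distance}} of that
#' fraction. For the edges descending directly from a duplication node, only
#' sites carrying a residue in \emph{all} of the duplication node's leaf
#' descendants are used, so that the relative lengths of the two
#' post-duplication branches are comparable despite rate heterogeneity among
#' sites. Edges with no comparable sites get length 0 and are flagged;
#' saturated edges are capped at \code{cfg$max_distance} and flagged.
#'
#' @param anc An \code{ancestral_states} object (from
#'   \code{\link{infer_ancestral_states}}).
#' @param cfg A \code{\link{giga_config}} (alphabet size and saturation cap).
#' @return An object of class \code{branch_lengths}: list with \code{edges}
#'   (data frame: \code{parent}, \code{child}, \code{p}, \code{n_sites},
#'   \code{length}, \code{flag}) and \code{tree} (the gene tree with a
#'   \code{length} on every non-root node).
#' @export
branch_lengths <- function(anc, cfg = giga_config()) {
  stopifnot(inherits(anc, "ancestral_states"))
  states <- anc$states_chars
  s <- cfg$alphabet_states
  sat <- (s - 1) / s
  trimmed_res <- function(st) st != "X" & st != "-"
  rows <- list()
  rec <- function(node) {
    if (node$type == "leaf") return(node)
    # restriction mask for child edges of a duplication node: sites aligned
    # in every leaf descendant
    mask <- NULL
    if (node$type == "duplication") {
      lv <- gene_node_leaves(node)
      mask <- Reduce(`&`, lapply(lv, function(id) trimmed_res(states[[id]])))
    }
    p_state <- states[[node$anc_id]]
    for (k in seq_along(node$children)) {
      ch <- node$children[[k]]
      c_state <- states[[if (ch$type == "leaf") ch$id else ch$anc_id]]
      ok <- trimmed_res(p_state) & trimmed_res(c_state)
      if (!is.null(mask)) ok <- ok & mask
      n <- sum(ok)
      p <- if (n > 0) sum(p_state[ok] != c_state[ok]) / n else 0
      flag <- ""
      len <- if (n == 0) { flag <- "no-comparable-sites"; 0
      } else if (p >= sat) { flag <- "saturated"; cfg$max_distance
      } else jc_distance(p, s)
      rows[[length(rows) + 1L]] <<- data.frame(
        parent = node$anc_id,
        child = if (ch$type == "leaf") ch$id else ch$anc_id,
        p = p, n_sites = n, length = len, flag = flag,
        stringsAsFactors = FALSE)
      ch$length <- len
      node$children[[k]] <- rec(ch)
    }
    node
  }
  root <- rec(anc$tree$root)
  structure(list(edges = do.call(rbind, rows),
                 tree = new_gene_tree(root)),
            class = "branch_lengths")
}

#' @export
print.branch_lengths <- function(x, ...) {
  cat(sprintf("Branch lengths: %d edges, total %.4f substitutions/site\n",
              nrow(x$edges), sum(x$edges$length)))
  flagged <- x$edges[nzchar(x$edges$flag), ]
  if (nrow(flagged))
    cat("Flagged edges:", nrow(flagged), "\n")
  invisible(x)
}
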