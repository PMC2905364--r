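# Shared fixtures and independent oracles for the test suite. All fixtures
# are built in code; the oracles deliberately use different algorithms from
# the package internals they check.

toy_sptree <- function() parse_species_tree("((HUMAN,MOUSE),YEAST);")

opisthokont_sptree <- function() parse_species_tree(
  "(((HUMAN,MOUSE)Euarchontoglires,CHICK)Amniota,((YEAST,SCHPO)Fungi,DICDI)Opisthokonta)Root;")

# alignment whose sequences differ from `base` at chosen positions
diverged_seq <- function(base, positions, to = "W") {
  s <- strsplit(base, "")[[1]]
  s[positions] <- ifelse(s[positions] == to, "Y", to)
  paste(s, collapse = "")
}

# random residue string
rand_seq <- function(L) paste(sample(giga:::AA20, L, replace = TRUE),
                              collapse = "")

# random symmetric p-distance matrix object over sequence ids
rand_distance_matrix <- function(ids, n_sites = 300L, max_p = 0.85) {
  k <- length(ids)
  p <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    p[i, j] <- p[j, i] <- stats::runif(1, 0, max_p)
  n <- matrix(n_sites, k, k, dimnames = list(ids, ids))
  diag(n) <- 0L
  structure(list(p = p, n = n, no_overlap = matrix(FALSE, k, k), ids = ids),
            class = "distance_matrix")
}

# gap-free trimmed alignment (distances are supplied separately)
flat_trimmed <- function(ids, species = NULL, L = 60L) {
  seqs <- stats::setNames(vapply(ids, function(i) rand_seq(L), character(1)),
                          ids)
  aln <- family_alignment(seqs, species_map = species)
  trim_alignment(aln)
}

# ---- brute-force oracles --------------------------------------------------

# bipartitions by per-edge leaf harvesting over the phylo edge matrix,
# independently of the package's recursive traversal
oracle_bipartitions <- function(tree) {
  phy <- if (inherits(tree, "phylo")) tree else ape::as.phylo(tree)
  n <- length(phy$tip.label)
  tips_below <- function(node) {
    if (node <= n) return(phy$tip.label[node])
    out <- character(0)
    for (ch in phy$edge[phy$edge[, 1] == node, 2])
      out <- c(out, tips_below(ch))
    out
  }
  ref <- sort(phy$tip.label)[1]
  keys <- character(0)
  for (node in unique(phy$edge[, 2])) {
    if (node <= n) next
    side <- tips_below(node)
    if (length(side) < 2 || n - length(side) < 2) next
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2, normalized = TRUE) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  raw <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (!normalized) return(raw)
  if (length(b1) + length(b2) == 0) return(0)
  raw / (length(b1) + length(b2))
}

# all-pairs MRCA scan over the converted phylo: a pair is orthologous iff
# the MRCA's node label starts with "S:" and the species differ
oracle_ortholog_pairs <- function(tree) {
  phy <- ape::as.phylo(tree)
  n <- length(phy$tip.label)
  parent <- rep(NA_integer_, n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  path_up <- function(node) {
    p <- node
    while (!is.na(parent[node])) { node <- parent[node]; p <- c(p, node) }
    p
  }
  out <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi <- path_up(i)
    mrca <- pi[match(TRUE, pi %in% path_up(j))]
    lab <- phy$node.label[mrca - n]
    sp_i <- sub(".*_", "", phy$tip.label[i])
    sp_j <- sub(".*_", "", phy$tip.label[j])
    if (startsWith(lab, "S:") && sp_i != sp_j) {
      a <- phy$tip.label[i]; b <- phy$tip.label[j]
      out <- c(out, paste(min(a, b), max(a, b), sep = "|"))
    }
  }
  sort(out)
}

# random labeled gene tree: recursive random partition of leaves, internal
# nodes randomly speciation or duplication
rand_gene_tree <- function(n_leaves, n_species = max(2, n_leaves %/% 2),
                           p_dup = 0.3) {
  species <- sprintf("SP%02d", seq_len(n_species))
  ids <- sprintf("q%d_%s", seq_len(n_leaves),
                 sample(species, n_leaves, replace = TRUE))
  build <- function(leaves) {
    if (length(leaves) == 1)
      return(giga:::gene_leaf(leaves, species = sub(".*_", "", leaves)))
    k <- if (length(leaves) == 2) 2 else sample(2:min(3, length(leaves)), 1)
    grp <- cut(sample(seq_along(leaves)), k, labels = FALSE)
    while (length(unique(grp)) < k)
      grp <- cut(sample(seq_along(leaves)), k, labels = FALSE)
    kids <- lapply(split(leaves, grp), build)
    if (stats::runif(1) < p_dup)
      giga:::gene_internal("duplication", kids, placement = "P")
    else
      giga:::gene_internal("speciation", kids, species = "S")
  }
  giga:::new_gene_tree(build(ids))
}

# random rooted topology as a gene tree with all-speciation labels and
# distinct species (for RF tests)
rand_topology <- function(n_leaves, tag = "t") {
  ids <- sprintf("%s%02d_SX%02d", tag, seq_len(n_leaves), seq_len(n_leaves))
  build <- function(leaves) {
    if (length(leaves) == 1)
      return(giga:::gene_leaf(leaves, species = sub(".*_", "", leaves)))
    k <- if (length(leaves) == 2) 2 else sample(c(2, 2, 3), 1)
    k <- min(k, length(leaves))
    grp <- cut(sample(seq_along(leaves)), k, labels = FALSE)
    while (length(unique(grp)) < k)
      grp <- cut(sample(seq_along(leaves)), k, labels = FALSE)
    giga:::gene_internal("speciation", lapply(split(leaves, grp), build),
                         species = "S")
  }
  giga:::new_gene_tree(build(ids))
}

# species-tree restriction as a gene tree, for congruence checks
expected_restriction <- function(sptree, ids, species) {
  members <- stats::setNames(ids, species)
  giga:::new_gene_tree(giga:::restrict_topology(sptree, members))
}
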