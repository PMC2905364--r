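# Gene-family simulator with known event histories. Genes evolve down the
# species tree: duplications spawn sibling lineages on the species-tree edge
# where they occur (the ground-truth founding copy event), losses prune
# lineages, and substitutions accumulate per edge under a uniform 20-state
# exchange model (so the expected p-distance has a closed form). Alignments
# are gap-free except for planted fragments; indels are not modeled.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' @param species_tree A \code{species_tree} (or newick string) to evolve
#'   along.
#' @param dup_rate Expected number of duplication events per species-tree
#'   edge (Poisson).
#' @param loss_prob Probability that a gene lineage is lost on an edge.
#' @param seq_length Number of sites.
#' @param sub_prob Per-site substitution probability per edge (the clock).
#' @param post_dup_multiplier Rate multiplier (>= 1) applied to a newly
#'   founded copy for the remainder of its founding edge, emulating the
#'   accelerated evolution commonly seen after duplication.
#' @param fragment_prob Probability that a leaf sequence is truncated into a
#'   fragment.
#' @param truncation_fraction Fraction of trailing sites gapped in a planted
#'   fragment.
#' @param forced_duplications Character vector of species-tree node labels;
#'   one duplication is forced on the edge immediately above each listed
#'   node.
#' @param forced_losses Optional data frame with columns \code{copy} and
#'   \code{node}: the lineage of that copy is deleted on the edge above the
#'   named species-tree node.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(species_tree, dup_rate = 0.05,
                              loss_prob = 0.01,
                              seq_length = 300, sub_prob = 0.05,
                              post_dup_multiplier = 1.5,
                              fragment_prob = 0, truncation_fraction = 0.6,
                              forced_duplications = character(0),
                              forced_losses = NULL, seed = NULL) {
  if (is.character(species_tree)) species_tree <-
      parse_species_tree(species_tree)
  stopifnot(inherits(species_tree, "species_tree"),
            dup_rate >= 0, loss_prob >= 0, loss_prob <= 1,
            seq_length >= 1, sub_prob >= 0, sub_prob <= 1,
            post_dup_multiplier >= 1,
            fragment_prob >= 0, fragment_prob <= 1,
            truncation_fraction > 0, truncation_fraction < 1)
  structure(list(species_tree = species_tree, dup_rate = dup_rate,
                 loss_prob = loss_prob, seq_length = as.integer(seq_length),
                 sub_prob = sub_prob,
                 post_dup_multiplier = post_dup_multiplier,
                 fragment_prob = fragment_prob,
                 truncation_fraction = truncation_fraction,
                 forced_duplications = forced_duplications,
                 forced_losses = forced_losses, seed = seed),
            class = "simulation_config")
}

#' Simulate a gene family along the species tree
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @return A list of class \code{simulated_family}:
#'   \describe{
#'     \item{alignment}{a gap-free \code{family_alignment}; ids are
#'       \code{g<copy>_<SPECIES>}}
#'     \item{true_tree}{the true \code{gene_tree} with speciation and
#'       duplication labels and ground-truth placements}
#'     \item{duplications}{data frame: \code{copy} (the founded lineage) and
#'       \code{placement} (species-tree node label immediately below the
#'       event)}
#'     \item{fragments}{ids of planted fragments}
#'     \item{config}{the configuration}
#'   }
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sp <- cfg$species_tree
  L <- cfg$seq_length
  copy_counter <- 1L
  duplications <- list()
  seqs <- list()
  mutate <- function(seq, prob) {
    hit <- which(stats::runif(L) < prob)
    if (length(hit))
      seq[hit] <- ((seq[hit] - 1L + sample.int(19L, length(hit),
                                               replace = TRUE)) %% 20L) + 1L
    seq
  }
  forced_loss_here <- function(copy, node_label) {
    fl <- cfg$forced_losses
    !is.null(fl) && any(fl$copy == copy & fl$node == node_label)
  }
  # a lineage arriving at species node `nd` (events of the edge above
  # already applied); returns a gene node or NULL
  at_node <- function(nd, seq, copy) {
    if (nd <= sp$n_tips) {
      id <- paste0("g", copy, "_", sp$labels[nd])
      seqs[[id]] <<- seq
      return(gene_leaf(id, species = sp$labels[nd]))
    }
    kids <- Filter(Negate(is.null),
                   lapply(sp$children[[nd]], function(ch)
                     down_edge(ch, seq, copy)))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    gene_internal("speciation", kids, species_node = nd,
                  species = sp$labels[nd])
  }
  # a lineage entering the edge above species node `nd`
  down_edge <- function(nd, seq, copy) {
    lab <- sp$labels[nd]
    n_dup <- stats::rpois(1, cfg$dup_rate) +
      sum(cfg$forced_duplications == lab)
    lineages <- list(list(copy = copy, mult = 1))
    for (k in seq_len(n_dup)) {
      new_copy <- as.character(copy_counter + 1L)
      copy_counter <<- copy_counter + 1L
      duplications[[length(duplications) + 1L]] <<-
        list(copy = new_copy, parent_copy = copy, placement = lab)
      lineages[[length(lineages) + 1L]] <-
        list(copy = new_copy, mult = cfg$post_dup_multiplier)
    }
    subtrees <- list()
    for (ln in lineages) {
      if (forced_loss_here(ln$copy, lab)) next
      if (cfg$loss_prob > 0 && stats::runif(1) < cfg$loss_prob) next
      sq <- mutate(seq, min(1, cfg$sub_prob * ln$mult))
      node <- at_node(nd, sq, ln$copy)
      if (!is.null(node)) subtrees[[length(subtrees) + 1L]] <- node
    }
    if (length(subtrees) == 0L) return(NULL)
    if (length(subtrees) == 1L) return(subtrees[[1]])
    gene_internal("duplication", subtrees, placement_node = nd,
                  placement = lab)
  }
  root_seq <- sample.int(20L, L, replace = TRUE)
  root <- at_node(sp$root, root_seq, "1")
  if (is.null(root) || length(seqs) == 0L)
    stop("all gene lineages were lost; nothing to simulate")
  aln <- family_alignment(vapply(seqs, function(s)
    paste(AA20[s], collapse = ""), character(1)))
  fam <- structure(list(alignment = aln,
                        true_tree = new_gene_tree(root),
                        duplications = if (length(duplications))
                          do.call(rbind, lapply(duplications, function(d)
                            data.frame(copy = d$copy,
                                       parent_copy = d$parent_copy,
                                       placement = d$placement,
                                       stringsAsFactors = FALSE)))
                        else data.frame(copy = character(0),
                                        parent_copy = character(0),
                                        placement = character(0)),
                        fragments = character(0), config = cfg),
                   class = "simulated_family")
  if (cfg$fragment_prob > 0) {
    for (id in fam$alignment$ids)
      if (stats::runif(1) < cfg$fragment_prob)
        fam <- plant_fragment(fam, id, cfg$truncation_fraction)
  }
  fam
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf(
    "Simulated family: %d sequences, %d duplication(s), %d fragment(s)\n",
    length(x$alignment$ids), nrow(x$duplications), length(x$fragments)))
  invisible(x)
}

#' Plant a sequence fragment
#'
#' Replaces the trailing \code{fraction} of a sequence's aligned sites with
#' gaps, emulating a partial gene prediction, and records the ground truth.
#'
#' @param fam A \code{simulated_family}.
#' @param id A sequence id in the family.
#' @param fraction Fraction of trailing sites to gap, in (0, 1).
#' @return The modified \code{simulated_family}.
#' @export
plant_fragment <- function(fam, id, fraction = 0.6) {
  stopifnot(inherits(fam, "simulated_family"), fraction > 0, fraction < 1)
  if (!id %in% fam$alignment$ids) stop("unknown sequence id: ", id)
  L <- ncol(fam$alignment$matrix)
  n_gap <- round(fraction * L)
  if (n_gap >= 1)
    fam$alignment$matrix[id, (L - n_gap + 1L):L] <- "-"
  fam$fragments <- unique(c(fam$fragments, id))
  fam
}

#' Write a simulated family to disk
#'
#' Writes the alignment (FASTA), the true tree (newick with NHX event
#' labels) and a JSON ground-truth manifest (duplications, fragments,
#' configuration scalars).
#'
#' @param fam A \code{simulated_family}.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The manifest path, invisibly.
#' @export
write_simulated_family <- function(fam, dir, prefix = "family") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  nw <- file.path(dir, paste0(prefix, "_true.nhx"))
  js <- file.path(dir, paste0(prefix, "_truth.json"))
  write_family_alignment(fam$alignment, fa)
  write_newick(fam$true_tree, nw)
  cfg <- fam$config
  jsonlite::write_json(
    list(alignment = basename(fa), true_tree = basename(nw),
         duplications = fam$duplications, fragments = fam$fragments,
         seq_length = cfg$seq_length, dup_rate = cfg$dup_rate,
         loss_prob = cfg$loss_prob, sub_prob = cfg$sub_prob,
         post_dup_multiplier = cfg$post_dup_multiplier),
    js, auto_unbox = TRUE, digits = NA)
  invisible(js)
}

#' Random rooted species tree for simulations
#'
#' Draws a random rooted binary topology over \code{n} synthetic species
#' codes (SP01, SP02, ...) using \code{ape::rtree} (topology only).
#'
#' @param n Number of species.
#' @return A \code{species_tree}.
#' @export
random_species_tree <- function(n) {
  phy <- ape::rtree(n, rooted = TRUE, br = NULL)
  phy$tip.label <- sprintf("SP%02d", seq_len(n))
  new_species_tree(phy)
}
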