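# Core agglomeration: orthologous subtrees (OS's) joined by founding copy
# events (FCEs). Each iteration takes the closest untreated sequence pair and
# either merges the two OS's containing them into one OS (same species never
# appearing twice), or joins them by a duplication event dated by deletion
# parsimony, or refuses and records why. The final tree is assembled from the
# OS topologies (each the species-tree restriction over its members) and the
# sibling/placement links of the FCEs.

# ---- state ----------------------------------------------------------------

new_state <- function(trimmed, dm, sptree, cfg) {
  ids <- trimmed$ids
  species <- trimmed$species
  missing <- setdiff(unique(species), names(sptree$leaf_index))
  if (length(missing)) {
    bad <- ids[species[ids] %in% missing]
    stop("species absent from the species tree for sequence(s): ",
         paste(bad, collapse = ", "))
  }
  st <- new.env(parent = emptyenv())
  st$trimmed <- trimmed
  st$dm <- dm
  st$sptree <- sptree
  st$cfg <- cfg
  st$ids <- ids
  st$species <- species
  st$os <- vector("list", length(ids))
  st$alias <- seq_along(ids)
  st$os_of <- stats::setNames(seq_along(ids), ids)
  for (i in seq_along(ids)) {
    st$os[[i]] <- list(id = i, members = ids[i],
                       mrca = species_mrca(sptree, species[[ids[i]]]),
                       fce = NULL, alive = TRUE)
  }
  st$quarantined <- character(0)
  st$ever_quarantined <- character(0)
  st$discarded <- character(0)
  st$reinserted <- character(0)
  st$events <- list()
  st$step <- 0L
  # ascending-distance pair list; ties broken by the lexicographic order of
  # the (sorted) sequence-id pair for determinism
  k <- length(ids)
  pairs <- t(utils::combn(k, 2L))
  a <- pmin(ids[pairs[, 1]], ids[pairs[, 2]])
  b <- pmax(ids[pairs[, 1]], ids[pairs[, 2]])
  d <- dm$p[cbind(pairs[, 1], pairs[, 2])]
  ord <- order(d, a, b)
  st$pairs <- cbind.data.frame(i = pairs[ord, 1], j = pairs[ord, 2],
                               d = d[ord], stringsAsFactors = FALSE)
  st$cursor <- 0L
  unseen <- setdiff(names(sptree$leaf_index), unique(species))
  if (length(unseen))
    log_event(st, "info", reason = "species-without-sequences",
              detail = paste(unseen, collapse = ","))
  st
}

resolve_os <- function(st, i) {
  while (st$alias[i] != i) i <- st$alias[i]
  i
}

os_species <- function(st, o) unname(st$species[st$os[[o]]$members])

log_event <- function(st, action, seq1 = NA, seq2 = NA, distance = NA,
                      os1 = NA, os2 = NA, reason = NA, detail = NA) {
  st$step <- st$step + 1L
  st$events[[st$step]] <- list(step = st$step, action = action,
                               seq1 = seq1, seq2 = seq2,
                               distance = distance, os1 = os1, os2 = os2,
                               reason = reason, detail = detail)
}

events_frame <- function(st) {
  if (!length(st$events))
    return(data.frame(step = integer(0), action = character(0),
                      seq1 = character(0), seq2 = character(0),
                      distance = numeric(0), os1 = character(0),
                      os2 = character(0), reason = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(st$events, function(e)
    data.frame(step = e$step, action = e$action,
               seq1 = as.character(e$seq1), seq2 = as.character(e$seq2),
               distance = as.numeric(e$distance),
               os1 = as.character(e$os1), os2 = as.character(e$os2),
               reason = as.character(e$reason),
               detail = as.character(e$detail),
               stringsAsFactors = FALSE)))
}

# ---- pair iteration -------------------------------------------------------

# Advance to the next untreated pair whose sequences sit in different live
# OS's and are not quarantined; returns list(i, j, d) or NULL when exhausted.
next_pair <- function(st) {
  repeat {
    if (st$cursor >= nrow(st$pairs)) return(NULL)
    st$cursor <- st$cursor + 1L
    pr <- st$pairs[st$cursor, ]
    x <- st$ids[pr$i]; y <- st$ids[pr$j]
    if (x %in% st$quarantined || y %in% st$quarantined) next
    if (resolve_os(st, st$os_of[[x]]) == resolve_os(st, st$os_of[[y]])) next
    return(list(x = x, y = y, d = pr$d))
  }
}

# ---- group distances ------------------------------------------------------

# Minimum raw distance between two groups of sequences, with the site count
# of the minimizing pair (ties resolved toward the lexicographically first
# pair). The distance between groups is always this minimum: raw distances
# are never averaged or updated.
group_distance <- function(st, members_a, members_b) {
  sub_p <- st$dm$p[members_a, members_b, drop = FALSE]
  best <- which(sub_p == min(sub_p), arr.ind = TRUE)
  key <- paste(pmin(members_a[best[, 1]], members_b[best[, 2]]),
               pmax(members_a[best[, 1]], members_b[best[, 2]]))
  pick <- best[order(key)[1], , drop = TRUE]
  list(p = sub_p[pick[1], pick[2]],
       n = st$dm$n[members_a[pick[1]], members_b[pick[2]]])
}

# ---- Rule 4: revision significance test -----------------------------------

#' Significance test for revising a dated duplication
#'
#' Given evidence \code{ev} (a list with \code{dist1}, \code{std_dev1}:
#' minimum raw distance between the focal group and the candidate orthologs
#' with its Jukes-Cantor standard deviation; and \code{dist2},
#' \code{std_dev2}: the same against the established paralogous sibling
#' group), decides whether the sequence evidence is strong enough to revise
#' an earlier duplication-dating hypothesis. The threshold multiplier is 1.5
#' when the alternative hypothesis implies no duplication (the focal group
#' shares no species with the sibling and might be orthologous to it) and 0.5
#' when the alternative itself implies a duplication.
#'
#' By default the test passes exactly when the focal group is significantly
#' \emph{closer} to the candidate orthologs than to the sibling,
#' \code{dist2 - dist1 > m*(std_dev1 + std_dev2)}; setting
#' \code{revision_literal_sign} in the config flips the orientation.
#'
#' @param ev List with numeric \code{dist1}, \code{std_dev1}, \code{dist2},
#'   \code{std_dev2} (all >= 0).
#' @param alternative_implies_duplication Logical.
#' @param cfg A \code{\link{giga_config}}.
#' @return Logical scalar.
#' @export
revision_test <- function(ev, alternative_implies_duplication,
                          cfg = giga_config()) {
  m <- if (alternative_implies_duplication) cfg$paralog_sd_multiplier
       else cfg$ortholog_sd_multiplier
  margin <- if (cfg$revision_literal_sign) ev$dist1 - ev$dist2
            else ev$dist2 - ev$dist1
  isTRUE(margin > m * (ev$std_dev1 + ev$std_dev2))
}

# ---- Rule 5: fragment test ------------------------------------------------

#' Test whether a sequence is a likely fragment
#'
#' The expected ancestral sites of a candidate merged group are the trimmed
#' columns at which more than half of the group's sequences other than the
#' candidate carry a residue.
#' A sequence aligning at most \code{cfg$fragment_coverage} (default 50\%) of
#' those sites is a potential fragment. A sequence whose current subtree
#' already holds at least \code{cfg$fragment_exempt_os_size} \emph{other}
#' sequences is never flagged: it passed the test when those were added.
#'
#' @param candidate A sequence id.
#' @param merged_members Ids of the candidate merged group (including
#'   \code{candidate}).
#' @param trimmed A \code{trimmed_alignment}.
#' @param n_others Number of other sequences in the candidate's current
#'   subtree.
#' @param cfg A \code{\link{giga_config}}.
#' @return Logical: \code{TRUE} if the sequence is a potential fragment.
#' @export
fragment_test <- function(candidate, merged_members, trimmed, n_others = 0L,
                          cfg = giga_config()) {
  if (n_others >= cfg$fragment_exempt_os_size) return(FALSE)
  res <- !(trimmed$matrix %in% GAP_CHARS)
  dim(res) <- dim(trimmed$matrix)
  rownames(res) <- trimmed$ids
  # expected ancestral sites are estimated from the members other than the
  # candidate: a sequence must not vouch for its own sites (with only two
  # sequences the poll would otherwise degenerate to their intersection and
  # a fragment could never be detected)
  others <- setdiff(merged_members, candidate)
  if (!length(others)) return(FALSE)
  expected <- colMeans(res[others, , drop = FALSE]) > 0.5
  n_exp <- sum(expected)
  if (n_exp == 0L) return(FALSE)
  aligned <- sum(res[candidate, expected])
  aligned <= cfg$fragment_coverage * n_exp
}

# ---- join (Rule 2 + Rule 3) -----------------------------------------------

# Attempt to join two OS's by a duplication event. Precondition: their
# species sets intersect (genomic proof of duplication). Returns TRUE on
# success. Rule 3 places the FCE of the OS with the more recent MRCA on the
# species-tree edge immediately above that MRCA; equal MRCAs make the two
# OS's mutual siblings, each with an FCE on the shared edge.
try_join_duplication <- function(st, o1, o2, x = NA, y = NA, d = NA) {
  f1 <- !is.null(st$os[[o1]]$fce); f2 <- !is.null(st$os[[o2]]$fce)
  if (f1 && f2) {
    log_event(st, "skip", x, y, d, o1, o2, reason = "both-fce-located")
    return(FALSE)
  }
  if (f2 && !f1) { tmp <- o1; o1 <- o2; o2 <- tmp; f1 <- TRUE; f2 <- FALSE }
  sp1 <- os_species(st, o1); sp2 <- os_species(st, o2)
  ov <- paste0("|ov:", paste(sort(intersect(sp1, sp2)), collapse = ";"))
  m1 <- st$os[[o1]]$mrca; m2 <- st$os[[o2]]$mrca
  if (f1) {
    # 2.1.1.2: the span of the unlocated OS must fit within the located one's
    if (!node_within(st$sptree, m1, m2)) {
      log_event(st, "refuse-join", x, y, d, o1, o2,
                reason = "span-exceeds-located-os")
      return(FALSE)
    }
    st$os[[o2]]$fce <- list(placement = m2, sibling = o1)
    log_event(st, "join", x, y, d, o1, o2, reason = "rule2",
              detail = paste0(sprintf("fce:os%d@%s|sib:os%d", o2,
                                      st$sptree$labels[m2], o1), ov))
    return(TRUE)
  }
  # 2.1.1.1: neither located; MRCAs are comparable because the species sets
  # intersect, so depth decides recency
  if (st$sptree$depth[m1] == st$sptree$depth[m2]) {
    st$os[[o1]]$fce <- list(placement = m1, sibling = o2)
    st$os[[o2]]$fce <- list(placement = m2, sibling = o1)
    log_event(st, "join", x, y, d, o1, o2, reason = "rule2-mutual",
              detail = paste0(sprintf("fce:os%d@%s|fce:os%d@%s", o1,
                                      st$sptree$labels[m1], o2,
                                      st$sptree$labels[m2]), ov))
  } else {
    if (st$sptree$depth[m2] > st$sptree$depth[m1]) {
      founded <- o2; sib <- o1; mf <- m2
    } else {
      founded <- o1; sib <- o2; mf <- m1
    }
    st$os[[founded]]$fce <- list(placement = mf, sibling = sib)
    log_event(st, "join", x, y, d, o1, o2, reason = "rule2",
              detail = paste0(sprintf("fce:os%d@%s|sib:os%d", founded,
                                      st$sptree$labels[mf], sib), ov))
  }
  TRUE
}

# ---- merge (Rule 1 + Rule 4 + Rule 5) -------------------------------------

# Attempt to merge two OS's into one (species sets disjoint). The driving
# sequences x and y face the fragment test unless skip_fragment_test (used
# during fragment re-insertion). Returns TRUE on success.
try_merge <- function(st, o1, o2, x, y, d = NA, skip_fragment_test = FALSE) {
  f1 <- !is.null(st$os[[o1]]$fce); f2 <- !is.null(st$os[[o2]]$fce)
  if (f1 && f2) {
    log_event(st, "skip", x, y, d, o1, o2, reason = "both-fce-located")
    return(FALSE)
  }
  if (!skip_fragment_test) {
    merged_members <- c(st$os[[o1]]$members, st$os[[o2]]$members)
    frag <- character(0)
    for (cand in c(x, y)) {
      oc <- resolve_os(st, st$os_of[[cand]])
      if (fragment_test(cand, merged_members, st$trimmed,
                        n_others = length(st$os[[oc]]$members) - 1L,
                        cfg = st$cfg))
        frag <- c(frag, cand)
    }
    if (length(frag)) {
      for (f in frag) quarantine(st, f)
      log_event(st, "refuse-merge", x, y, d, o1, o2, reason = "fragment",
                detail = paste(frag, collapse = ","))
      return(FALSE)
    }
  }
  if (f2 && !f1) { tmp <- o1; o1 <- o2; o2 <- tmp; f1 <- TRUE; f2 <- FALSE }
  union_sp <- unique(c(os_species(st, o1), os_species(st, o2)))
  union_mrca <- species_mrca(st$sptree, union_sp)
  if (f1 && union_mrca != st$os[[o1]]$mrca) {
    # 2.1.2.4: the merge deepens the located OS's MRCA; demand significant
    # sequence evidence before revising the duplication date (Rule 4)
    sib <- resolve_os(st, st$os[[o1]]$fce$sibling)
    d1 <- group_distance(st, st$os[[o2]]$members, st$os[[o1]]$members)
    d2 <- group_distance(st, st$os[[o2]]$members, st$os[[sib]]$members)
    sat <- (st$cfg$alphabet_states - 1) / st$cfg$alphabet_states
    ev <- list(
      dist1 = d1$p,
      std_dev1 = if (d1$n >= 1 && d1$p < sat)
        jc_stddev(d1$p, d1$n, st$cfg$alphabet_states) else Inf,
      dist2 = d2$p,
      std_dev2 = if (d2$n >= 1 && d2$p < sat)
        jc_stddev(d2$p, d2$n, st$cfg$alphabet_states) else Inf)
    alt_dup <- length(intersect(os_species(st, o2), os_species(st, sib))) > 0
    if (!revision_test(ev, alternative_implies_duplication = alt_dup,
                       cfg = st$cfg)) {
      log_event(st, "refuse-merge", x, y, d, o1, o2, reason = "fce-conflict",
                detail = sprintf("dist1=%.6g|dist2=%.6g|sd1=%.6g|sd2=%.6g|m=%s",
                                 ev$dist1, ev$dist2, ev$std_dev1, ev$std_dev2,
                                 if (alt_dup) st$cfg$paralog_sd_multiplier
                                 else st$cfg$ortholog_sd_multiplier))
      return(FALSE)
    }
    old <- st$os[[o1]]$fce$placement
    st$os[[o1]]$fce$placement <- union_mrca
    log_event(st, "revise-fce", x, y, d, o1, o2, reason = "rule4",
              detail = sprintf("os%d:%s->%s", o1, st$sptree$labels[old],
                               st$sptree$labels[union_mrca]))
  }
  # merge o2 into o1 (o1 keeps any FCE); topology is implicit: the species
  # tree restricted to the member species (Rule 1)
  keep <- if (f1) o1 else min(o1, o2)
  drop <- if (keep == o1) o2 else o1
  st$os[[keep]]$members <- sort(c(st$os[[o1]]$members, st$os[[o2]]$members))
  st$os[[keep]]$mrca <- union_mrca
  if (f1 && keep != o1) st$os[[keep]]$fce <- st$os[[o1]]$fce
  st$os[[drop]]$alive <- FALSE
  st$alias[drop] <- keep
  log_event(st, "merge", x, y, d, o1, o2, reason = "rule1",
            detail = sprintf("os%d(%d seqs)@%s", keep,
                             length(st$os[[keep]]$members),
                             st$sptree$labels[union_mrca]))
  TRUE
}

quarantine <- function(st, id) {
  st$quarantined <- c(st$quarantined, id)
  st$ever_quarantined <- c(st$ever_quarantined, id)
  o <- resolve_os(st, st$os_of[[id]])
  rest <- setdiff(st$os[[o]]$members, id)
  if (length(rest) == 0L) {
    st$os[[o]]$alive <- FALSE
    st$os[[o]]$fce <- NULL
  } else {
    st$os[[o]]$members <- rest
    st$os[[o]]$mrca <- species_mrca(st$sptree, unname(st$species[rest]))
  }
  log_event(st, "quarantine", seq1 = id, os1 = o, reason = "rule5")
}

# ---- one iteration --------------------------------------------------------

step_pair <- function(st, pr) {
  o1 <- resolve_os(st, st$os_of[[pr$x]])
  o2 <- resolve_os(st, st$os_of[[pr$y]])
  overlap <- length(intersect(os_species(st, o1), os_species(st, o2))) > 0
  if (overlap) try_join_duplication(st, o1, o2, pr$x, pr$y, pr$d)
  else try_merge(st, o1, o2, pr$x, pr$y, pr$d)
}

# ---- fragment re-insertion (step 2.2) -------------------------------------

# Each quarantined fragment gets exactly one merge/join attempt, against the
# OS holding its nearest non-fragment sequence, in ascending order of that
# best distance. The fragment test itself is skipped here. Failures leave
# the fragment discarded.
reinsert_fragments <- function(st) {
  frags <- st$quarantined
  if (!length(frags)) return(invisible(st))
  nonfrag <- setdiff(st$ids, frags)
  nonfrag <- nonfrag[vapply(nonfrag, function(id)
    st$os[[resolve_os(st, st$os_of[[id]])]]$alive, logical(1))]
  if (!length(nonfrag)) {
    st$discarded <- sort(frags)
    for (f in st$discarded)
      log_event(st, "discard", seq1 = f, reason = "no-non-fragment")
    st$quarantined <- character(0)
    return(invisible(st))
  }
  best <- vapply(frags, function(f) min(st$dm$p[f, nonfrag]), numeric(1))
  for (f in frags[order(best, frags)]) {
    dists <- st$dm$p[f, nonfrag]
    target <- nonfrag[order(dists, nonfrag)[1]]
    d <- st$dm$p[f, target]
    # the fragment re-enters as a fresh singleton OS (its original slot may
    # meanwhile have been kept by a merged OS)
    i <- length(st$os) + 1L
    st$os[[i]] <- list(id = i, members = f,
                       mrca = species_mrca(st$sptree,
                                           unname(st$species[[f]])),
                       fce = NULL, alive = TRUE)
    st$alias <- c(st$alias, i)
    st$os_of[[f]] <- i
    st$quarantined <- setdiff(st$quarantined, f)
    of <- i
    ot <- resolve_os(st, st$os_of[[target]])
    overlap <- length(intersect(os_species(st, of),
                                os_species(st, ot))) > 0
    ok <- if (overlap) try_join_duplication(st, ot, of, target, f, d)
          else try_merge(st, ot, of, target, f, d,
                         skip_fragment_test = TRUE)
    if (ok) {
      st$reinserted <- c(st$reinserted, f)
      log_event(st, "reinsert", seq1 = f, seq2 = target, distance = d,
                reason = "step2.2")
    } else {
      st$os[[i]]$alive <- FALSE
      st$discarded <- c(st$discarded, f)
      log_event(st, "discard", seq1 = f, seq2 = target, distance = d,
                reason = "single-attempt-failed")
    }
  }
  invisible(st)
}

# ---- assembly -------------------------------------------------------------

# Assemble the labeled gene tree from the live OS's and their FCE links.
# Every founded OS's realized subtree is grafted as a child of a duplication
# node inserted on its sibling's lineage at the recorded placement; OS's with
# identical placement and sibling share one multifurcating duplication node;
# components never connected by any event meet at an unresolved root.
assemble_tree <- function(st) {
  live <- which(vapply(st$os, function(o) isTRUE(o$alive), logical(1)))
  live <- live[vapply(live, function(o)
    length(st$os[[o]]$members) > 0, logical(1))]
  if (!length(live)) stop("no sequences left to assemble")
  fce_of <- function(o) st$os[[o]]$fce
  host_of <- rep(NA_integer_, length(st$os))
  placement_of <- rep(NA_integer_, length(st$os))
  for (o in live) {
    f <- fce_of(o)
    if (!is.null(f)) {
      h <- resolve_os(st, f$sibling)
      # a host emptied by quarantine, or one no longer holding any species
      # under the placement, cannot anchor the attachment; the founded OS
      # then falls back to the unresolved root
      anchor_ok <- h %in% live &&
        any(vapply(os_species(st, h), function(s)
          node_within(st$sptree, f$placement,
                      st$sptree$leaf_index[[s]]), logical(1)))
      if (anchor_ok) {
        host_of[o] <- h
        placement_of[o] <- f$placement
      }
    }
  }
  # mutual pairs: the OS with the older (shallower) placement hosts; the
  # other attaches. Cycles longer than two are inconsistent.
  for (o in live) {
    h <- host_of[o]
    if (!is.na(h) && !is.na(host_of[h]) && host_of[h] == o) {
      depth_o <- st$sptree$depth[placement_of[o]]
      depth_h <- st$sptree$depth[placement_of[h]]
      host <- if (depth_o < depth_h) o
              else if (depth_h < depth_o) h
              else min(o, h)
      host_of[host] <- NA_integer_
    }
  }
  for (o in live) {
    seen <- integer(0); cur <- o
    while (!is.na(cur) && !is.na(host_of[cur])) {
      if (cur %in% seen)
        stop("inconsistent sibling graph (cycle) among OS ids: ",
             paste(seen, collapse = ","), "\nEvent log:\n",
             paste(utils::capture.output(print(events_frame(st))),
                   collapse = "\n"))
      seen <- c(seen, cur)
      cur <- host_of[cur]
    }
  }
  attachments <- split(live[!is.na(host_of[live])],
                       host_of[live[!is.na(host_of[live])]])
  realized <- list()
  realize <- function(o) {
    key <- as.character(o)
    if (!is.null(realized[[key]])) return(realized[[key]])
    members <- st$os[[o]]$members
    named <- stats::setNames(members, unname(st$species[members]))
    topo <- restrict_topology(st$sptree, named)
    att <- attachments[[key]]
    if (!is.null(att)) {
      # deepest (most recent) placements graft first so older duplications
      # end up closer to the root
      placs <- placement_of[att]
      for (p in unique(placs[order(-st$sptree$depth[placs], placs)])) {
        founders <- sort(att[placs == p])
        roots <- lapply(founders, function(f) realize(f)$root)
        in_clade <- vapply(members, function(m)
          node_within(st$sptree,
                      p,
                      st$sptree$leaf_index[[st$species[[m]]]]),
          logical(1))
        c_set <- members[in_clade]
        topo <- graft_duplication(topo, c_set, roots, p,
                                  st$sptree$labels[p], members)
      }
    }
    out <- new_gene_tree(topo)
    realized[[key]] <<- out
    out
  }
  comp_roots <- sort(live[is.na(host_of[live])])
  parts <- lapply(comp_roots, function(o) realize(o)$root)
  root <- if (length(parts) == 1L) parts[[1]]
          else gene_internal("root", parts[order(vapply(parts, function(p)
            min(gene_node_leaves(p)), character(1)))])
  new_gene_tree(root)
}

# Insert a duplication node above the (unique) subtree of `topo` whose
# host-member leaf set equals c_set; `roots` are the realized founded
# subtrees sharing this placement. When the found anchor is already a
# duplication node with the same placement, the new subtrees join it as
# additional children (unresolved multifurcation).
graft_duplication <- function(topo, c_set, roots, placement_node,
                              placement_label, host_members) {
  # find the highest node whose leaf set, restricted to the host OS's own
  # members (leaves introduced by earlier grafts do not count), equals c_set
  covers <- function(node) all(c_set %in% gene_node_leaves(node))
  exact_host <- function(node) {
    setequal(intersect(gene_node_leaves(node), host_members), c_set)
  }
  rec <- function(node) {
    # descend toward the minimal covering node, but stop at the highest node
    # whose host-member leaves are exactly c_set
    if (exact_host(node)) {
      if (node$type == "duplication" &&
          identical(node$placement_node, placement_node)) {
        node$children <- c(node$children, roots)
        return(node)
      }
      return(gene_internal("duplication", c(list(node), roots),
                           placement_node = placement_node,
                           placement = placement_label))
    }
    for (k in seq_along(node$children)) {
      if (covers(node$children[[k]])) {
        node$children[[k]] <- rec(node$children[[k]])
        return(node)
      }
    }
    stop("internal error: placement clade is not a clade of the host subtree")
  }
  if (!all(c_set %in% host_members))
    stop("internal error: placement clade missing from host")
  rec(topo)
}

# ---- driver ---------------------------------------------------------------

#' Infer a gene tree by species-tree-constrained agglomeration
#'
#' Runs the full iterative inference: sequence pairs are visited in ascending
#' raw-distance order; at each step the two orthologous subtrees containing
#' the pair are merged (when their species sets are disjoint and no fragment
#' or dating conflict intervenes) or joined by a duplication event dated by
#' deletion parsimony (when a species occurs in both, the genomic proof of
#' duplication). Previously dated duplications are revised rootward only on
#' significant sequence evidence. Detected fragments are quarantined and
#' offered a single re-insertion attempt after the main pass. The run is
#' fully deterministic: ties are broken lexicographically.
#'
#' @param trimmed A \code{trimmed_alignment} (see \code{\link{trim_alignment}}).
#' @param dm A \code{distance_matrix} from \code{\link{pairwise_distances}};
#'   computed from \code{trimmed} when \code{NULL}.
#' @param sptree A \code{species_tree}; every sequence's species must appear
#'   in it.
#' @param cfg A \code{\link{giga_config}}.
#' @return An object of class \code{giga_fit}: a list with \code{tree} (the
#'   labeled \code{gene_tree}), \code{events} (the step-by-step event log as
#'   a data frame), \code{fragments} (quarantined / reinserted / discarded
#'   ids), \code{os} (a summary data frame of the final orthologous
#'   subtrees), and the inputs.
#' @examples
#' sp <- parse_species_tree("((HUMAN,MOUSE),YEAST);")
#' aln <- family_alignment(c(A_HUMAN = "MKLVVAGHK", B_MOUSE = "MKLVVAGHR",
#'                           C_YEAST = "MKIVIAAHR"))
#' fit <- run_giga(trim_alignment(aln), sptree = sp)
#' fit$tree
#' @export
run_giga <- function(trimmed, dm = NULL, sptree, cfg = giga_config()) {
  if (!inherits(trimmed, "trimmed_alignment"))
    stop("`trimmed` must be a trimmed_alignment (see trim_alignment())")
  if (is.null(dm)) dm <- pairwise_distances(trimmed)
  if (length(trimmed$ids) == 1L)
    stop("need at least two sequences")
  st <- new_state(trimmed, dm, sptree, cfg)
  repeat {
    pr <- next_pair(st)
    if (is.null(pr)) break
    step_pair(st, pr)
  }
  reinsert_fragments(st)
  tree <- assemble_tree(st)
  live <- which(vapply(st$os, function(o)
    isTRUE(o$alive) && length(o$members) > 0, logical(1)))
  os_summary <- do.call(rbind, lapply(live, function(o) {
    f <- st$os[[o]]$fce
    data.frame(os = o, n_members = length(st$os[[o]]$members),
               mrca = st$sptree$labels[st$os[[o]]$mrca],
               fce_placement = if (is.null(f)) NA_character_
                               else st$sptree$labels[f$placement],
               sibling = if (is.null(f)) NA_integer_
                         else resolve_os(st, f$sibling),
               members = paste(st$os[[o]]$members, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(list(tree = tree, events = events_frame(st),
                 fragments = list(quarantined = sort(st$ever_quarantined),
                                  reinserted = sort(st$reinserted),
                                  discarded = sort(st$discarded)),
                 os = os_summary, config = cfg, species_tree = sptree,
                 trimmed = trimmed, distances = dm),
            class = "giga_fit")
}

#' @export
print.giga_fit <- function(x, ...) {
  cat(sprintf(
    "Gene-tree inference: %d sequences -> %d orthologous subtree(s)\n",
    length(x$trimmed$ids), nrow(x$os)))
  if (length(x$fragments$discarded))
    cat("Discarded fragments:",
        paste(x$fragments$discarded, collapse = ", "), "\n")
  if (length(x$fragments$reinserted))
    cat("Re-inserted fragments:",
        paste(x$fragments$reinserted, collapse = ", "), "\n")
  print(x$tree)
  invisible(x)
}
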