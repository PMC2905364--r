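# helpers to craft alignments with controlled pairwise differences
base_seq <- function(L = 200) paste(rep("A", L), collapse = "")

with_diffs <- function(base, positions, ch = "W") {
  s <- strsplit(base, "")[[1]]
  s[positions] <- ch
  paste(s, collapse = "")
}

test_that("a paralog-free family yields the species-tree restriction", {
  sp <- toy_sptree()
  b <- base_seq(100)
  aln <- family_alignment(c(
    A_HUMAN = b,
    B_MOUSE = with_diffs(b, 1:5),
    C_YEAST = with_diffs(b, 10:40, "Y")))
  fit <- run_giga(trim_alignment(aln), sptree = sp)
  expect_equal(nrow(fit$os), 1L)
  types <- unlist(giga:::gene_node_apply(fit$tree$root, function(n) n$type))
  expect_false("duplication" %in% types)
  expect_identical(
    write_newick(fit$tree, nhx = FALSE),
    "((A_HUMAN,B_MOUSE),C_YEAST);")
})

test_that("a lineage-accelerated ortholog is merged by species-tree
           knowledge, not join order", {
  sp <- parse_species_tree(
    "(((HUMAN,MOUSE)Euarch,YEAST)Opisthokonta,DICDI)Root;")
  b <- base_seq(200)
  aln <- family_alignment(c(
    MTH_HUMAN = b,
    MTH_MOUSE = with_diffs(b, 1:6),
    MET_YEAST = with_diffs(b, 81:160, "Y"), # accelerated fungal lineage
    MTH_DICDI = with_diffs(b, 21:80, "C")))
  fit <- run_giga(trim_alignment(aln), sptree = sp)
  # single orthologous subtree: the divergent yeast gene is recognized as
  # orthologous despite being the last to join
  expect_equal(nrow(fit$os), 1L)
  expect_identical(write_newick(fit$tree, nhx = FALSE),
                   "(((MTH_HUMAN,MTH_MOUSE),MET_YEAST),MTH_DICDI);")
  merges <- fit$events[fit$events$action == "merge", ]
  dicdi_step <- min(which(merges$seq1 == "MTH_DICDI" |
                          merges$seq2 == "MTH_DICDI"))
  yeast_step <- min(which(merges$seq1 == "MET_YEAST" |
                          merges$seq2 == "MET_YEAST"))
  expect_lt(dicdi_step, yeast_step) # join order differed from topology
})

test_that("a fungal-only duplicate group is dated just prior to the fungal
           MRCA and later same-span merges use the no-conflict rule", {
  sp <- parse_species_tree(paste0(
    "((HUMAN,MOUSE)Metazoa,((YEAST,SCHPO,CANAL)Fungi,DICDI)Inner)Root;"))
  b <- base_seq(200)
  copy2 <- function(extra, block = 100:139) with_diffs(
    with_diffs(b, block, "Y"), extra, "H")
  aln <- family_alignment(c(
    g1_HUMAN = with_diffs(b, 1:4),
    g1_MOUSE = with_diffs(b, 5:8),
    g1_YEAST = with_diffs(b, 9:12),
    g1_SCHPO = with_diffs(b, 13:16),
    g1_CANAL = with_diffs(b, 17:20),
    g1_DICDI = with_diffs(b, 21:24),
    g2_YEAST = copy2(25:28),
    g2_SCHPO = copy2(29:32),
    g2_CANAL = with_diffs(copy2(33:36), 140:199, "C")))
  fit <- run_giga(trim_alignment(aln), sptree = sp)

  # Rule 3: the more recent group gets the founding event on the edge just
  # above the fungal MRCA
  placed <- fit$os[!is.na(fit$os$fce_placement), ]
  expect_equal(nrow(placed), 1L)
  expect_identical(placed$fce_placement, "Fungi")
  expect_setequal(strsplit(placed$members, ",")[[1]],
                  c("g2_YEAST", "g2_SCHPO", "g2_CANAL"))

  # the divergent third fungal copy joined its group under 2.1.2.3 (same
  # MRCA, no revision needed)
  ev <- fit$events
  join_step <- min(which(ev$action == "join"))
  canal_merge <- which(ev$action == "merge" &
                       (ev$seq1 == "g2_CANAL" | ev$seq2 == "g2_CANAL"))
  expect_true(length(canal_merge) == 1 && canal_merge > join_step)
  expect_false(any(ev$action == "revise-fce"))
  # span-violating joins were refused
  expect_true(any(ev$action == "refuse-join" &
                  ev$reason == "span-exceeds-located-os"))

  # one multifurcating duplication node whose child clades share species
  nodes <- giga:::gene_node_apply(fit$tree$root, function(n)
    list(type = n$type, k = length(n$children)))
  dups <- Filter(function(n) n$type == "duplication", nodes)
  expect_length(dups, 1L)
  # fungal speciation nodes stay multifurcating (3 children)
  expect_true(any(vapply(nodes, function(n)
    n$type == "speciation" && n$k == 3, logical(1))))

  # orthology: cross-copy pairs through the duplication are paralogs, but
  # the founded group is co-orthologous to the metazoan genes
  orth <- extract_ortholog_pairs(fit$tree)
  expect_false("g1_YEAST|g2_YEAST" %in% orth)
  expect_true("g1_HUMAN|g2_YEAST" %in% orth)
})

test_that("equal-MRCA duplicates become mutual siblings and block
           unsupported merges", {
  sp <- toy_sptree()
  b <- base_seq(200)
  aln <- family_alignment(c(
    p1_HUMAN = b,
    p2_HUMAN = with_diffs(b, 1:4),
    q_MOUSE = with_diffs(b, 50:110, "Y")))
  fit <- run_giga(trim_alignment(aln), sptree = sp)
  ev <- fit$events
  expect_true(any(ev$reason == "rule2-mutual"))
  # both duplicates carry founding events at the shared (leaf) MRCA
  expect_setequal(fit$os$fce_placement[!is.na(fit$os$fce_placement)],
                  "HUMAN")
  # merging the mouse gene into either copy would revise a dated event with
  # zero distance margin: refused
  expect_true(any(ev$action == "refuse-merge" &
                  ev$reason == "fce-conflict"))
  # the unconnected components meet at an unresolved root
  expect_identical(fit$tree$root$type, "root")
  orth <- extract_ortholog_pairs(fit$tree)
  expect_length(orth, 0L)
  expect_gt(attr(orth, "unresolved"), 0L)
})

test_that("revision significance test follows the stated margins", {
  cfg <- giga_config()
  ev_at <- function(margin, sd = 0.02)
    list(dist1 = 0.2, std_dev1 = sd, dist2 = 0.2 + margin, std_dev2 = sd)
  # zero margin fails under both multipliers
  expect_false(revision_test(ev_at(0), TRUE, cfg))
  expect_false(revision_test(ev_at(0), FALSE, cfg))
  # margin of 2 summed-sd units passes the duplication alternative (0.5)
  expect_true(revision_test(ev_at(2 * 0.04), TRUE, cfg))
  # margin of 1 summed-sd unit fails the orthology alternative (1.5)
  expect_false(revision_test(ev_at(1 * 0.04), FALSE, cfg))
  expect_true(revision_test(ev_at(1.6 * 0.04), FALSE, cfg))
  # literal orientation flips the sign convention
  lit <- giga_config(revision_literal_sign = TRUE)
  expect_false(revision_test(ev_at(2 * 0.04), TRUE, lit))
  expect_true(revision_test(list(dist1 = 0.28, std_dev1 = 0.02,
                                 dist2 = 0.2, std_dev2 = 0.02), TRUE, lit))
})

test_that("fragment detection follows the coverage and exemption rules", {
  ids <- c("frag_SPA", "full1_SPB", "full2_SPC", "full3_SPD")
  L <- 100
  seqs <- stats::setNames(c(
    paste0(strrep("A", 45), strrep("-", 55)),
    strrep("A", L), strrep("A", L), strrep("A", L)), ids)
  trm <- trim_alignment(family_alignment(seqs),
                        cfg = giga_config(gap_threshold = 0.99))
  expect_equal(ncol(trm$matrix), 100L)
  # 45 of 100 expected sites: fragment
  expect_true(fragment_test("frag_SPA", ids, trm, n_others = 0L))
  # 80 of 100: not a fragment
  seqs80 <- seqs
  seqs80["frag_SPA"] <- paste0(strrep("A", 80), strrep("-", 20))
  trm80 <- trim_alignment(family_alignment(seqs80),
                          cfg = giga_config(gap_threshold = 0.99))
  expect_false(fragment_test("frag_SPA", ids, trm80, n_others = 0L))
  # an OS holding enough other sequences exempts the candidate entirely
  expect_false(fragment_test("frag_SPA", ids, trm, n_others = 3L))
  expect_true(fragment_test("frag_SPA", ids, trm, n_others = 2L))
})

test_that("quarantined fragments are re-inserted where their species is
           missing, and failures are reported", {
  sp <- parse_species_tree("((ALPHA,BRAVO),CHARL);")
  b <- base_seq(100)
  frag <- paste0(substr(with_diffs(b, 1:10, "Y"), 1, 40), strrep("-", 60))
  aln <- family_alignment(c(
    a_ALPHA = b,
    b_BRAVO = with_diffs(b, 11:16),
    c_CHARL = frag))
  fit <- run_giga(trim_alignment(aln,
                                 cfg = giga_config(gap_threshold = 0.9)),
                  sptree = sp,
                  cfg = giga_config(gap_threshold = 0.9))
  expect_identical(fit$fragments$quarantined, "c_CHARL")
  expect_identical(fit$fragments$reinserted, "c_CHARL")
  expect_identical(write_newick(fit$tree, nhx = FALSE),
                   "((a_ALPHA,b_BRAVO),c_CHARL);")
  # no fragments: state untouched
  aln2 <- family_alignment(c(a_ALPHA = b, b_BRAVO = with_diffs(b, 1:5)))
  fit2 <- run_giga(trim_alignment(aln2), sptree = sp)
  expect_length(fit2$fragments$quarantined, 0L)
})

test_that("sequences whose species is missing from the tree are refused
           by name", {
  sp <- toy_sptree()
  aln <- family_alignment(c(A_HUMAN = "MKLV", B_MARS = "MKLI"))
  expect_error(run_giga(trim_alignment(aln), sptree = sp), "B_MARS")
})

test_that("runs are deterministic and conserve leaves", {
  set.seed(77)
  sp <- random_species_tree(10)
  fam <- simulate_family(simulation_config(sp, dup_rate = 0.15,
                                           loss_prob = 0.05, seed = 77))
  fam <- plant_fragment(fam, fam$alignment$ids[2], 0.6)
  run1 <- run_giga(trim_alignment(fam$alignment), sptree = sp)
  run2 <- run_giga(trim_alignment(fam$alignment), sptree = sp)
  expect_identical(write_newick(run1$tree), write_newick(run2$tree))
  expect_identical(run1$events, run2$events)
  expect_setequal(c(run1$tree$leaves, run1$fragments$discarded),
                  fam$alignment$ids)
})

test_that("paralog-free random-distance runs reproduce the species tree and
           paralog-bearing runs obey genomic proof and rootward revision", {
  set.seed(123)
  for (rep in 1:15) {
    sp <- random_species_tree(sample(5:10, 1))
    species <- names(sp$leaf_index)
    ids <- paste0("g1_", species)
    dm <- rand_distance_matrix(ids)
    trm <- flat_trimmed(ids)
    fit <- run_giga(trm, dm, sp)
    expect_identical(
      write_newick(fit$tree, nhx = FALSE),
      write_newick(expected_restriction(sp, ids, species), nhx = FALSE))
  }
  for (rep in 1:15) {
    sp <- random_species_tree(sample(5:8, 1))
    species <- names(sp$leaf_index)
    dup_sp <- sample(species, 2)
    ids <- c(paste0("g1_", species), paste0("g2_", dup_sp))
    dm <- rand_distance_matrix(ids)
    fit <- tryCatch(run_giga(flat_trimmed(ids), dm, sp),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      # the only sanctioned failure is an inconsistent sibling graph
      expect_match(conditionMessage(fit), "cycle")
      next
    }
    ev <- fit$events
    joins <- ev[ev$action == "join", "detail"]
    if (length(joins))
      expect_true(all(grepl("\\|ov:[^|]+$", joins)))
    revs <- ev[ev$action == "revise-fce", "detail"]
    for (d in revs) {
      lab <- strsplit(sub("^os[0-9]+:", "", d), "->", fixed = TRUE)[[1]]
      from <- match(lab[1], sp$labels); to <- match(lab[2], sp$labels)
      expect_lt(sp$depth[to], sp$depth[from]) # rootward only
    }
    expect_setequal(c(fit$tree$leaves, fit$fragments$discarded), ids)
  }
})
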