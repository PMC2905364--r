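find_node_by_leaves <- function(tree, leaves) {
  hit <- NULL
  rec <- function(node) {
    if (node$type == "leaf") return(invisible(NULL))
    if (setequal(giga:::gene_node_leaves(node), leaves)) hit <<- node
    lapply(node$children, rec)
    invisible(NULL)
  }
  rec(tree$root)
  hit
}

test_that("per-site majority, outgroup tie-break, unknown and gap rules", {
  sp <- parse_species_tree("(((SPA,SPB),SPC),SPD);")
  # columns: 1 child majority; 2 tie broken by outgroup; 3 tie, outgroup
  # disagrees; 4 gap majority (never emitted as residue); 5 majority again
  aln <- family_alignment(c(
    a_SPA = "AAC-A",
    b_SPB = "ACG-A",
    c_SPC = "ACAGA",
    d_SPD = "AAAGA"))
  trm <- trim_alignment(aln, cfg = giga_config(gap_threshold = 0.99))
  fit <- run_giga(trm, sptree = sp)
  anc <- infer_ancestral_states(fit$tree, trm)
  ab <- find_node_by_leaves(anc$tree, c("a_SPA", "b_SPB"))
  s <- strsplit(anc$states[[ab$anc_id]], "")[[1]]
  expect_identical(s, c("A", "C", "X", "X", "A"))
})

test_that("strict majority holds on multifurcations: {A,A,C} -> A", {
  sp <- parse_species_tree("((SPA,SPB,SPC),SPD);")
  trm <- trim_alignment(family_alignment(c(
    a_SPA = "A", b_SPB = "A", c_SPC = "C", d_SPD = "G")))
  fit <- run_giga(trm, sptree = sp)
  anc <- infer_ancestral_states(fit$tree, trm)
  abc <- find_node_by_leaves(anc$tree, c("a_SPA", "b_SPB", "c_SPC"))
  expect_identical(anc$states[[abc$anc_id]], "A")
})

test_that("star tree of identical leaves: identical states, zero lengths", {
  sp <- parse_species_tree("(SPA,SPB,SPC,SPD);")
  trm <- trim_alignment(family_alignment(stats::setNames(
    rep("MKLVHA", 4), c("a_SPA", "b_SPB", "c_SPC", "d_SPD"))))
  fit <- run_giga(trm, sptree = sp)
  anc <- infer_ancestral_states(fit$tree, trm)
  expect_true(all(anc$states == "MKLVHA"))
  bl <- branch_lengths(anc)
  expect_true(all(bl$edges$length == 0))
  expect_true(all(bl$edges$p == 0))
})

test_that("branch length is the corrected fraction over comparable sites
           and grows with mismatches", {
  # direct reconstruction on a fixed 2-leaf cherry inside a 3-leaf tree
  sp <- parse_species_tree("((SPA,SPB),SPC);")
  b <- strrep("A", 100)
  flip <- function(s, pos, ch = "W") {
    v <- strsplit(s, "")[[1]]; v[pos] <- ch; paste(v, collapse = "")
  }
  trm <- trim_alignment(family_alignment(c(
    a_SPA = flip(b, 1:10), b_SPB = b, c_SPC = b)))
  fit <- run_giga(trm, sptree = sp)
  anc <- infer_ancestral_states(fit$tree, trm)
  bl <- branch_lengths(anc)
  e <- bl$edges
  # ancestor of {a,b} resolves to the outgroup state; edge to a carries all
  # ten differences over 100 comparable sites
  a_edge <- e[e$child == "a_SPA", ]
  expect_equal(a_edge$p, 0.1)
  expect_equal(a_edge$n_sites, 100L)
  expect_equal(a_edge$length, jc_distance(0.1, 20), tolerance = 1e-12)
  expect_equal(a_edge$length, 0.10566, tolerance = 1e-4)
  expect_true(all(e[e$child != "a_SPA", "length"] == 0))
  # monotone in the number of mismatches at fixed site count
  expect_lt(jc_distance(5 / 100, 20), jc_distance(10 / 100, 20))
})

test_that("edges below a duplication use only sites aligned in all of its
           leaf descendants", {
  b <- strrep("A", 60)
  flip <- function(s, pos, ch) {
    v <- strsplit(s, "")[[1]]; v[pos] <- ch; paste(v, collapse = "")
  }
  seqs <- c(
    x1_SPA = flip(b, 41:60, "Y"), x2_SPB = flip(b, 41:60, "Y"),
    xg_SPC = flip(b, 41:60, "-"),
    z1_SPA = flip(b, 41:60, "C"), z2_SPB = flip(b, 41:60, "C"),
    out_SPD = flip(b, 41:60, "C"))
  trm <- trim_alignment(family_alignment(seqs),
                        cfg = giga_config(gap_threshold = 0.99))
  leafs <- function(ids) lapply(ids, function(i)
    giga:::gene_leaf(i, species = sub(".*_", "", i)))
  x_clade <- giga:::gene_internal("speciation",
                                  leafs(c("x1_SPA", "x2_SPB", "xg_SPC")),
                                  species = "S1")
  z_clade <- giga:::gene_internal("speciation",
                                  leafs(c("z1_SPA", "z2_SPB")),
                                  species = "S1")
  dup <- giga:::gene_internal("duplication", list(x_clade, z_clade),
                              placement = "S1")
  root <- giga:::gene_internal("speciation",
                               c(list(dup), leafs("out_SPD")),
                               species = "S0")
  tree <- giga:::new_gene_tree(root)
  anc <- infer_ancestral_states(tree, trm)
  x_anc <- anc$states[[find_node_by_leaves(
    anc$tree, c("x1_SPA", "x2_SPB", "xg_SPC"))$anc_id]]
  dup_id <- find_node_by_leaves(
    anc$tree, c("x1_SPA", "x2_SPB", "xg_SPC", "z1_SPA", "z2_SPB"))$anc_id
  dup_anc <- anc$states[[dup_id]]
  # the duplication ancestor takes the outgroup-supported residue C where
  # its two children disagree, so it genuinely differs from the x clade at
  # the private region
  expect_identical(substr(dup_anc, 50, 50), "C")
  expect_identical(substr(x_anc, 50, 50), "Y")
  bl <- branch_lengths(anc)
  dup_edges <- bl$edges[bl$edges$parent == dup_id, ]
  # xg is gapped over the disagreeing region, so post-duplication branch
  # lengths are measured on the first 40 columns only: zero differences
  expect_true(all(dup_edges$length == 0))
  expect_true(all(dup_edges$n_sites == 40L))
})
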