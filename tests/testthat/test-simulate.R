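test_that("no duplications and no losses give one gene per species and the
           species-tree topology", {
  sp <- parse_species_tree("(((SPA,SPB),SPC),(SPD,SPE));")
  fam <- simulate_family(simulation_config(sp, dup_rate = 0, loss_prob = 0,
                                           seq_length = 50, seed = 1))
  expect_setequal(unname(fam$alignment$species), names(sp$leaf_index))
  expect_equal(length(fam$alignment$ids), 5L)
  expect_equal(nrow(fam$duplications), 0L)
  expect_equal(rf_distance(
    fam$true_tree,
    expected_restriction(sp, fam$alignment$ids,
                         unname(fam$alignment$species))), 0)
})

test_that("simulation is deterministic under a fixed seed", {
  sp <- random_species_tree(8)
  f1 <- simulate_family(simulation_config(sp, dup_rate = 0.2,
                                          loss_prob = 0.05, seed = 99))
  f2 <- simulate_family(simulation_config(sp, dup_rate = 0.2,
                                          loss_prob = 0.05, seed = 99))
  expect_identical(f1$alignment$matrix, f2$alignment$matrix)
  expect_identical(write_newick(f1$true_tree), write_newick(f2$true_tree))
  expect_identical(f1$duplications, f2$duplications)
})

test_that("a forced duplication doubles gene counts below its edge", {
  sp <- parse_species_tree("(((SPA,SPB)AB,SPC)ABC,SPD)R;")
  fam <- simulate_family(simulation_config(sp, dup_rate = 0, loss_prob = 0,
                                           seq_length = 40,
                                           forced_duplications = "AB",
                                           seed = 2))
  counts <- table(unname(fam$alignment$species))
  expect_equal(as.integer(counts[c("SPA", "SPB")]), c(2L, 2L))
  expect_equal(as.integer(counts[c("SPC", "SPD")]), c(1L, 1L))
  expect_identical(fam$duplications$placement, "AB")
  # the true tree records the duplication at its edge
  types <- unlist(giga:::gene_node_apply(fam$true_tree$root,
                                         function(n) n$type))
  expect_equal(sum(types == "duplication"), 1L)
})

test_that("forced losses prune the named lineage", {
  sp <- parse_species_tree("(((SPA,SPB)AB,SPC)ABC,SPD)R;")
  fam <- simulate_family(simulation_config(
    sp, dup_rate = 0, loss_prob = 0, seq_length = 40,
    forced_duplications = "ABC",
    forced_losses = data.frame(copy = "2", node = "SPC"), seed = 3))
  ids <- fam$alignment$ids
  expect_true("g2_SPA" %in% ids && "g2_SPB" %in% ids)
  expect_false("g2_SPC" %in% ids)
})

test_that("planted fragments gap the trailing sites and fail the coverage
           test at 60% truncation", {
  sp <- parse_species_tree("((SPA,SPB),SPC);")
  fam <- simulate_family(simulation_config(sp, dup_rate = 0, loss_prob = 0,
                                           seq_length = 100, seed = 4))
  fam <- plant_fragment(fam, "g1_SPA", 0.6)
  row <- fam$alignment$matrix["g1_SPA", ]
  expect_identical(unname(row[41:100]), rep("-", 60))
  expect_false(any(row[1:40] == "-"))
  trm <- trim_alignment(fam$alignment,
                        cfg = giga_config(gap_threshold = 0.99))
  expect_true(fragment_test("g1_SPA", fam$alignment$ids, trm, 0L))
  # near-zero truncation passes the test
  fam2 <- simulate_family(simulation_config(sp, dup_rate = 0,
                                            loss_prob = 0,
                                            seq_length = 100, seed = 4))
  fam2 <- plant_fragment(fam2, "g1_SPA", 0.02)
  trm2 <- trim_alignment(fam2$alignment,
                         cfg = giga_config(gap_threshold = 0.99))
  expect_false(fragment_test("g1_SPA", fam2$alignment$ids, trm2, 0L))
  expect_error(plant_fragment(fam, "nope_SPX", 0.5), "unknown")
})

test_that("simulated families round-trip through the on-disk format", {
  sp <- random_species_tree(6)
  fam <- simulate_family(simulation_config(sp, dup_rate = 0.2,
                                           loss_prob = 0, seed = 12))
  dir <- tempfile()
  write_simulated_family(fam, dir)
  aln <- read_family_alignment(file.path(dir, "family.fasta"))
  expect_identical(aln$matrix, fam$alignment$matrix)
  tt <- read_newick(file.path(dir, "family_true.nhx"))
  expect_equal(rf_distance(tt, fam$true_tree), 0)
  truth <- jsonlite::read_json(file.path(dir, "family_truth.json"))
  expect_equal(length(truth$duplications), nrow(fam$duplications))
})
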