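# Rooted parsimony construction, tree length, recurrence, and the
# enumeration oracle.

test_that("single haplotype yields one mutated branch of its variant count", {
  db <- db_from_motifs(list(a = "16031T-16032T-16033T"))
  t <- build_tree(db)
  expect_equal(tree_length(t), 3L)
  bt <- branch_table(t)
  expect_equal(sum(bt$m > 0), 1L)
  expect_equal(max(bt$m), 3L)
})

test_that("the five-identical-plus-one-step clade builds a star of length one", {
  db <- founder_six_db()
  t <- build_tree(db, root_variants = "A16343G")
  expect_equal(tree_length(t), 1L)
  expect_equal(sort(t$tips$multiplicity), c(1L, 5L))
  expect_equal(t$n, 6L)
})

test_that("a star with one private mutation per tip has length n", {
  t <- build_tree(star_private_db(8))
  expect_equal(tree_length(t), 8L)
  expect_equal(nrow(t$tips), 8L)
  expect_true(all(t$branches$n_tips_below[lengths(t$branches$mutations) > 0] == 1L))
})

test_that("a root-only clade has length zero and rho zero", {
  db <- db_from_motifs(list(a = "A16343G", b = "A16343G"))
  t <- build_tree(db, root_variants = "A16343G")
  expect_equal(tree_length(t), 0L)
  expect_equal(rho(t), 0)
})

test_that("root-to-tip reconstruction reproduces every haplotype (500 random instances)", {
  set.seed(2024)
  for (r in 1:125) {
    n <- sample(3:10, 1)
    g <- simulate_genealogy(n, sample(c("star", "coalescent"), 1),
                            tmrca_years = 1500, ne_years = 1200)
    sm <- sprinkle_mutations(g, rate = 1e-3,
                             spectrum = mutation_spectrum("hvs1",
                                                          include_hotspots = FALSE))
    t <- build_tree(sm$haplotypes)
    rec <- mitofounder:::reconstruct_tips(t)
    for (i in seq_len(nrow(sm$haplotypes))) {
      id <- sm$haplotypes$id[i]
      grp <- which(vapply(t$tips$ids, function(x) id %in% x, TRUE))
      want <- sort(mitofounder:::relative_set(
        mitofounder:::present_tokens(sm$haplotypes$variants[[i]]), character(0)))
      got <- rec[[t$tips$ids[[grp]][1]]]
      expect_equal(sort(got), want)
    }
  }
})

test_that("brute_force_min handles compatible, disjoint and homoplasic cases", {
  # perfect phylogeny: length = number of segregating sites
  db <- db_from_motifs(list(a = "16031T", b = "16031T-16032T", c = "16033T"))
  expect_equal(brute_force_min(db), 3L)
  # two haplotypes sharing nothing: j + k
  db2 <- db_from_motifs(list(a = "16031T-16032T", b = "16033T-16034T-16035T"))
  expect_equal(brute_force_min(db2), 5L)
  # one homoplasic site: sites + 1
  db3 <- db_from_motifs(list(a = "16031T", b = "16032T", c = "16031T-16032T"))
  expect_equal(brute_force_min(db3), 3L)
  # guard rails
  big <- db_from_motifs(as.list(setNames(
    sprintf("16%03dT", 31:45), paste0("h", 1:15))))
  expect_error(brute_force_min(big, max_haps = 7), "too large")
})

test_that("build_tree length matches the enumeration oracle on random instances", {
  found <- 0L; seed <- 0L
  while (found < 60L && seed < 600L) {
    seed <- seed + 1L
    inst <- oracle_instance(seed)
    if (is.null(inst)) next
    found <- found + 1L
    expect_equal(tree_length(build_tree(inst)), brute_force_min(inst),
                 info = paste("seed", seed))
  }
  expect_gte(found, 50L)
})

test_that("collapsing identical haplotypes does not change the tree length", {
  set.seed(515)
  for (r in 1:20) {
    g <- simulate_genealogy(5, "coalescent", ne_years = 800)
    sm <- sprinkle_mutations(g, rate = 1.2e-3,
                             spectrum = mutation_spectrum("hvs1",
                                                          include_hotspots = FALSE))
    db <- sm$haplotypes
    dup <- db
    dup$id <- paste0(dup$id, "_b")
    both <- dplyr::bind_rows(db, dup)
    expect_equal(tree_length(build_tree(both)), tree_length(build_tree(db)))
  }
})

test_that("recurrence annotation flags exactly the repeated sites", {
  # perfect phylogeny: no recurrence
  db <- db_from_motifs(list(a = "16031T", b = "16031T-16032T"))
  expect_equal(nrow(annotate_recurrence(build_tree(db))), 0L)
  # same transition on two sibling branches
  db2 <- db_from_motifs(list(a = "16031T-16032T", b = "16031T-16033T",
                             c = "16032T", d = "16033T"))
  t2 <- build_tree(db2)
  rec <- annotate_recurrence(t2)
  expect_true(all(rec$events >= 2L))
  expect_true(all(rec$position %in% c(16031L, 16032L, 16033L)))
  # a spectrum concentrated on one site forces recurrence there
  g <- simulate_genealogy(12, "star", tmrca_years = 2000, seed = 33)
  sp <- mutation_spectrum("hvs1", include_hotspots = FALSE)
  sp <- sp[sp$position %in% c(16040L, 16041L), ]
  sp$weight <- sp$weight / sum(sp$weight)
  attr(sp, "range") <- c(16024L, 16400L)
  sm <- sprinkle_mutations(g, rate = 1e-3, spectrum = sp, seed = 34)
  t3 <- build_tree(sm$haplotypes)
  rec3 <- annotate_recurrence(t3)
  expect_true(all(rec3$position %in% c(16040L, 16041L)))
  expect_gt(nrow(rec3), 0L)
})

test_that("strict mode rejects unmasked hotspot variants", {
  db <- db_from_motifs(list(a = "A16182C-16031T"))
  expect_error(build_tree(db, strict = TRUE), "unmasked hotspot")
  # lenient mode masks silently
  expect_equal(tree_length(build_tree(db)), 1L)
})

test_that("output is deterministic and exports cleanly", {
  db <- founder_six_db()
  t1 <- build_tree(db, root_variants = "A16343G")
  t2 <- build_tree(db[sample(1:6), ], root_variants = "A16343G")
  expect_identical(branch_table(t1), branch_table(t2))
  nwk <- as_newick(t1)
  expect_match(nwk, "u1_x5")
  expect_match(nwk, "mutations=T16356C")
  expect_match(nwk, ";$")
})
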