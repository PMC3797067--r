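# Generators: genealogies, mutation sprinkling, mixed databases.

test_that("star genealogies are exact and ultrametric; n = 1 is a single branch", {
  g <- simulate_genealogy(10, "star", tmrca_years = 1000, seed = 1)
  expect_equal(nrow(g$edges), 10L)
  expect_true(all(g$edges$years == 1000))
  expect_true(all(tip_depths(g) == 1000))
  g1 <- simulate_genealogy(1, "star", tmrca_years = 500, seed = 1)
  expect_equal(nrow(g1$edges), 1L)
  expect_error(simulate_genealogy(0, "star"), "invalid")
})

test_that("coalescent genealogies are ultrametric and rescale to a requested TMRCA", {
  g <- simulate_genealogy(12, "coalescent", ne_years = 900, seed = 42)
  expect_equal(unname(diff(range(tip_depths(g)))), 0, tolerance = 1e-9)
  expect_equal(unname(tip_depths(g)[1]), g$tmrca_years)
  g2 <- simulate_genealogy(12, "coalescent", tmrca_years = 2500,
                           ne_years = 900, seed = 42)
  expect_equal(g2$tmrca_years, 2500)
  expect_equal(unname(tip_depths(g2)[5]), 2500, tolerance = 1e-9)
})

test_that("coalescent total branch length matches 2*Ne*H_{n-1} within 3 SE", {
  n <- 20; ne <- 1000; reps <- 400
  set.seed(1234)
  tot <- replicate(reps,
                   total_branch_length(simulate_genealogy(n, "coalescent",
                                                          ne_years = ne)))
  expected <- 2 * ne * sum(1 / seq_len(n - 1))
  se <- sd(tot) / sqrt(reps)
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("same seed gives identical output; different seeds differ", {
  a <- simulate_genealogy(8, "coalescent", ne_years = 700, seed = 5)
  b <- simulate_genealogy(8, "coalescent", ne_years = 700, seed = 5)
  expect_identical(a$edges, b$edges)
  sma <- sprinkle_mutations(a, 2e-3, seed = 9)
  smb <- sprinkle_mutations(a, 2e-3, seed = 9)
  expect_identical(sma$haplotypes$variants, smb$haplotypes$variants)
  smc <- sprinkle_mutations(a, 2e-3, seed = 10)
  expect_false(identical(sma$haplotypes$variants, smc$haplotypes$variants))
  # seeding does not disturb the caller's RNG stream
  set.seed(77); x1 <- runif(1)
  set.seed(77); invisible(simulate_genealogy(5, "star", seed = 3)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("rate zero leaves every haplotype at the root state", {
  g <- simulate_genealogy(6, "star", tmrca_years = 1000, seed = 2)
  sm <- sprinkle_mutations(g, rate = 0, root_variants = "A16343G", seed = 3)
  for (v in sm$haplotypes$variants) expect_equal(v$token, "A16343G")
})

test_that("per-tip mutation counts match the Poisson expectation within 3 SE", {
  g <- simulate_genealogy(200, "star", tmrca_years = 2000, seed = 11)
  rate <- 2 / 2000  # mu*T = 2
  sm <- sprinkle_mutations(g, rate = rate,
                           spectrum = mutation_spectrum("whole",
                                                        include_hotspots = FALSE),
                           seed = 12)
  counts <- vapply(sm$haplotypes$variants, nrow, 1L)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 2), 3 * se)
  # truth tree: per-tip event counts equal the haplotype variant counts
  per_tip_truth <- vapply(seq_len(g$n), function(tip) {
    node <- tip; acc <- 0L
    while (node != 0L) {
      k <- match(node, sm$events$child)
      acc <- acc + length(sm$events$tokens[[k]])
      node <- sm$events$parent[k]
    }
    acc
  }, 1L)
  expect_equal(unname(per_tip_truth), unname(counts))
})

test_that("perfect mode forces a perfect phylogeny", {
  g <- simulate_genealogy(10, "coalescent", ne_years = 2000, seed = 21)
  sm <- sprinkle_mutations(g, rate = 1.5e-3, perfect = TRUE, seed = 22,
                           spectrum = mutation_spectrum("hvs1",
                                                        include_hotspots = FALSE))
  all_tokens <- unlist(sm$events$tokens)
  expect_equal(anyDuplicated(mitofounder:::token_position(all_tokens)), 0L)
  t <- build_tree(sm$haplotypes)
  expect_equal(tree_length(t), length(all_tokens))
  expect_equal(nrow(annotate_recurrence(t)), 0L)
})

test_that("simulated databases carry exact planted counts and round-trip classify", {
  tr <- mini_haplogroup_tree()
  comp <- c(M5a1b1a1 = 0.25, U3b1c = 0.5, L2c = 0.25)
  db <- simulate_database(40, comp, tree = tr, private_rate = 0, seed = 31)
  expect_equal(as.integer(table(db$true_haplogroup)[names(comp)]),
               c(10L, 20L, 10L))
  asg <- classify_db(db, tr)
  expect_equal(mean(asg$haplogroup == db$true_haplogroup), 1)
  # private rate 0: records equal their motif exactly
  m <- cumulative_motif(tr, "U3b1c")
  rec <- db$variants[[which(db$true_haplogroup == "U3b1c")[1]]]
  expect_setequal(rec$token, m$token)
  expect_error(simulate_database(10, c(Zzz = 1), tree = tr), "unknown haplogroup")
})

test_that("database writer/reader round-trips simulated records", {
  tr <- mini_haplogroup_tree()
  db <- simulate_database(12, c(M18 = 0.5, H5a2 = 0.5), tree = tr,
                          private_rate = 0.5, seed = 41)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(db, path)
  back <- suppressMessages(read_haplotype_table(path, ref_check = "none"))
  expect_equal(back$id, db$id)
  for (i in seq_len(nrow(db))) {
    expect_setequal(back$variants[[i]]$token, db$variants[[i]]$token)
  }
})

test_that("full pipeline recovers the TMRCA of star founder clades", {
  rec <- simulate_founder_recovery(reps = 60, n = 20, mu_t = 2, seed = 99)
  expect_equal(nrow(rec), 60L)
  se <- sd(rec$rho) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$rho) - 2), 3 * se)
  expect_gte(mean(rec$covered), 0.85)  # small-sample check; the acceptance
                                       # suite runs the full design
})
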