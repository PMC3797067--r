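# Haplogroup tree loading, cumulative motifs, classification, motif search.

test_that("tree files load with depth, diagnostics and aliases", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("root", "\tM5 G16129A", "\t\tM5a1b1a1 T16298C"), path)
  tr <- load_haplogroup_tree(path)
  expect_equal(nrow(tr$nodes), 3L)
  expect_equal(tr$nodes$depth, 0:2)
  expect_equal(node_path(tr, "M5a1b1a1"), c("root", "M5", "M5a1b1a1"))

  writeLines(c("root", "\tA C16223T", "\tA G16129A"), path)
  expect_error(load_haplogroup_tree(path), "duplicate node name")
  writeLines(c("root", "\t\t\tX C16223T"), path)
  expect_error(load_haplogroup_tree(path), "indentation")
})

test_that("the packaged mini-tree loads with one node per non-comment line", {
  tr <- mini_haplogroup_tree()
  lines <- readLines(system.file("extdata", "haplogroups_mini.txt",
                                 package = "mitofounder"))
  n_lines <- sum(!grepl("^\\s*(#|$)", lines))
  expect_equal(nrow(tr$nodes), n_lines)
  # the alias table resolves the doubly-printed U3 landmark
  expect_equal(tr$aliases$alias, "A16344G")
  expect_equal(tr$aliases$canonical, "A16343G")
})

test_that("cumulative motifs accumulate along the path; back mutations remove", {
  tr <- mini_haplogroup_tree()
  expect_equal(nrow(cumulative_motif(tr, tree_root(tr))), 0L)
  m <- cumulative_motif(tr, "M5a1b1a1")
  expect_true(all(c("C3954T", "T9833C", "T16298C") %in% m$token))
  hv <- m[m$position >= 16024, ]
  expect_setequal(hv$token, c("G16129A", "C16223T", "C16291T", "T16298C"))
  expect_error(cumulative_motif(tr, "nope"), "unknown haplogroup")

  # '@' on a branch removes the ancestral variant
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("root", "\tX G16129A C16223T", "\t\tXrev @G16129A"), path)
  tr2 <- load_haplogroup_tree(path)
  expect_equal(cumulative_motif(tr2, "Xrev")$token, "C16223T")
})

test_that("motifs printed for the signature clades classify to those clades", {
  tr <- mini_haplogroup_tree()
  cases <- list(
    list("G16129A-C16223T-C16291T-T16298C", "16024-16400", "M5a1b1a1"),
    list("G16129A-C16223T-A16230G-C16233T-T16304C-C16344T", "16024-16400", "M35b2a1"),
    list("T246C-C16223T-A16318T", "57-372;16024-16400", "M18"),
    list("A16343G", "16024-16400", "U3"),
    list("A16293G-G16213A", "16024-16400", "H24")
  )
  for (cs in cases) {
    a <- classify(haplotype("x", cs[[1]], ranges = cs[[2]]), tr)
    expect_true(is_under(tr, a$haplogroup, cs[[3]]),
                info = sprintf("%s -> %s", cs[[3]], a$haplogroup))
    expect_equal(length(a$missing_covered[[1]]), 0L, info = cs[[3]])
  }
  # the HVS-I-only signature motif is a candidate: coding diagnostics
  # fall outside the sequenced range
  a <- classify(haplotype("x", "G16129A-C16223T-C16291T-T16298C"), tr)
  expect_equal(a$haplogroup, "M5a1b1a1")
  expect_true(a$candidate)
  expect_true(all(cumulative_motif(tr, "M5a1b1a1")$position[
    cumulative_motif(tr, "M5a1b1a1")$position < 16024] %in%
      parse_motif(paste(a$missing_uncovered[[1]], collapse = "-"))$position))
})

test_that("an rCRS-identical haplotype assigns to the root with score zero", {
  tr <- mini_haplogroup_tree()
  a <- classify(haplotype("x", "", ranges = "1-16569"), tr)
  expect_equal(a$haplogroup, tree_root(tr))
  expect_equal(a$score, 0L)
  expect_false(a$candidate)
})

test_that("every node's full-range cumulative motif classifies to itself with full score", {
  tr <- mini_haplogroup_tree()
  for (nm in tr$nodes$name) {
    motif <- cumulative_motif(tr, nm)
    h <- haplotype("x", motif, ranges = "1-16569")
    a <- classify(h, tr)
    # scaffold nodes (no own diagnostics) tie with an equal-scoring
    # descendant only if that descendant adds nothing; the assignment must
    # at least lie in the node's clade with every motif variant matched
    expect_true(is_under(tr, a$haplogroup, nm), info = nm)
    expect_equal(a$score, nrow(motif), info = nm)
    expect_equal(length(a$missing_covered[[1]]), 0L, info = nm)
  }
})

test_that("score is monotone in adding a missing diagnostic", {
  tr <- mini_haplogroup_tree()
  motifs <- all_motifs(tr)
  score_for <- function(h, nm) {
    asg <- mitofounder:::score_node(motifs[[nm]],
                                    mitofounder:::present_tokens(h$variants[[1]]),
                                    h$ranges[[1]])
    asg$score
  }
  h0 <- haplotype("x", "C16223T", ranges = "1-16569")
  for (nm in c("M5", "M5a1b1a1", "M18", "U3")) {
    miss <- setdiff(motifs[[nm]]$token, "C16223T")
    if (!length(miss)) next
    h1 <- haplotype("x", paste(c("C16223T", miss[1]), collapse = "-"),
                    ranges = "1-16569")
    expect_gte(score_for(h1, nm), score_for(h0, nm))
  }
})

test_that("private mutations never derail recovery of the true node", {
  tr <- mini_haplogroup_tree()
  set.seed(77)
  db <- simulate_database(200, c(M5a1b1a1 = 0.3, U3b1c = 0.2, H5a2 = 0.2,
                                 M18 = 0.1, L2c = 0.1, A2 = 0.1),
                          tree = tr, private_rate = 1.0, seed = 78)
  asg <- classify_db(db, tr)
  expect_equal(mean(asg$haplogroup == db$true_haplogroup), 1.0)
  # 0-2 private mutations per record by construction of the Poisson draw is
  # not guaranteed; spot-check extras are reported as free
  expect_true(all(asg$score >= 1L))
})

test_that("search_motif separates hits, misses and non-evaluable records", {
  tr <- mini_haplogroup_tree()
  db <- dplyr::bind_rows(
    haplotype("hit1", "A16293G-G16213A"),
    haplotype("hit2", "A16293G-G16213A-16031T"),
    haplotype("miss", "A16293G"),
    haplotype("nocov", "A16293G", ranges = "16024-16200;16250-16400"),
    haplotype("excl", "C16111T-C16223T-C16290T-G16319A-A16293G-G16213A")
  )
  res <- search_motif(db, "A16293G-G16213A", exclude = c("A2", "L2"), tree = tr)
  expect_setequal(res$hits$id, c("hit1", "hit2"))
  expect_equal(res$not_evaluable$id, "nocov")
  expect_match(res$not_evaluable$reason, "16213")
  # properties: hits are records, and disjoint from not_evaluable
  expect_true(all(res$hits$id %in% db$id))
  expect_length(intersect(res$hits$id, res$not_evaluable$id), 0L)
  # unknown excluded clade errors; empty database passes through
  expect_error(search_motif(db, "A16293G", exclude = "Zzz", tree = tr),
               "unknown haplogroup")
  empty <- db[0, ]
  res0 <- search_motif(empty, "A16293G")
  expect_equal(nrow(res0$hits), 0L)
  expect_equal(nrow(res0$not_evaluable), 0L)
})

test_that("planted motif carriers are found exactly (generator truth)", {
  tr <- mini_haplogroup_tree()
  motif <- "G16129A-C16223T-C16291T-T16298C"
  set.seed(91)
  for (k in c(0L, 3L, 7L)) {
    db <- simulate_database(40, c(M5a1b1a1 = k / 40, U3 = 1 - k / 40),
                            tree = tr, private_rate = 0, seed = 91 + k)
    res <- search_motif(db, motif)
    expect_equal(nrow(res$hits), k)
    # brute-force scan agrees
    manual <- sum(vapply(db$variants, function(v) {
      all(parse_motif(motif)$token %in% v$token)
    }, TRUE))
    expect_equal(nrow(res$hits), manual)
  }
})
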