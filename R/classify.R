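# Haplogroup classification and range-aware motif search.
#
# A haplotype is allocated to the node whose cumulative motif it matches
# best. Diagnostics covered by the record's sequenced range(s) score +1 when
# present and -1 when absent; diagnostics outside the range are neither
# credited nor penalised but flag the assignment as a candidate; private
# (extra) variants are free. Ties break by greatest depth, then
# lexicographic name — deterministic and documented.

empty_assignments <- function() {
  tibble(
    haplotype_id = character(), haplogroup = character(), score = integer(),
    depth = integer(), candidate = logical(),
    matched = list(), missing_covered = list(), missing_uncovered = list(),
    extras = list()
  )
}

score_node <- function(motif, present, ranges) {
  if (nrow(motif) == 0L) {
    return(list(matched = character(), missing_covered = character(),
                missing_uncovered = character(), score = 0L))
  }
  cov <- covers(motif$position, ranges)
  hit <- motif$token %in% present
  list(
    matched = motif$token[cov & hit],
    missing_covered = motif$token[cov & !hit],
    missing_uncovered = motif$token[!cov],
    score = as.integer(sum(cov & hit) - sum(cov & !hit))
  )
}

#' Classify one haplotype against a haplogroup tree
#'
#' @param h One-row haplotype tibble (see [haplotype()]); expected already
#'   hotspot-masked.
#' @param tree A `haplogroup_tree`.
#' @param motifs Optional precomputed [all_motifs()] list (for bulk use).
#' @return One-row assignment tibble: `haplotype_id`, `haplogroup`, `score`,
#'   `depth`, `candidate` (some diagnostics fall outside the sequenced
#'   range), and list-columns `matched`, `missing_covered`,
#'   `missing_uncovered`, `extras` of tokens.
#' @export
#' @examples
#' h <- haplotype("ex1", "G16129A-C16223T-C16291T-T16298C")
#' classify(h, mini_haplogroup_tree())
classify <- function(h, tree, motifs = NULL) {
  stopifnot(nrow(h) == 1L)
  if (is.null(motifs)) motifs <- all_motifs(tree)
  present <- present_tokens(h$variants[[1]])
  ranges <- h$ranges[[1]]
  best <- NULL
  for (i in seq_len(nrow(tree$nodes))) {
    name <- tree$nodes$name[i]
    sc <- score_node(motifs[[name]], present, ranges)
    cand <- list(name = name, depth = tree$nodes$depth[i], sc = sc)
    if (is.null(best) ||
        sc$score > best$sc$score ||
        (sc$score == best$sc$score && cand$depth > best$depth) ||
        (sc$score == best$sc$score && cand$depth == best$depth &&
           name < best$name)) {
      best <- cand
    }
  }
  motif_tokens <- motifs[[best$name]]$token
  tibble(
    haplotype_id = h$id, haplogroup = best$name, score = best$sc$score,
    depth = best$depth,
    candidate = length(best$sc$missing_uncovered) > 0L,
    matched = list(best$sc$matched),
    missing_covered = list(best$sc$missing_covered),
    missing_uncovered = list(best$sc$missing_uncovered),
    extras = list(setdiff(present, motif_tokens))
  )
}

#' Classify every record of a haplotype table
#'
#' @param db Haplotype tibble.
#' @param tree A `haplogroup_tree`.
#' @param policy [hotspot_policy()] applied to each record before scoring
#'   (`NULL` to skip).
#' @return Assignment tibble, one row per record, in input order.
#' @export
classify_db <- function(db, tree, policy = hotspot_policy()) {
  if (!is.null(policy)) db <- mask_db(db, policy)
  motifs <- all_motifs(tree)
  if (nrow(db) == 0L) return(empty_assignments())
  bind_rows(lapply(seq_len(nrow(db)), function(i) {
    classify(db[i, ], tree, motifs = motifs)
  }))
}

#' Range-aware motif search with haplogroup exclusions
#'
#' Finds database records whose sequenced ranges cover every motif position,
#' that carry every motif variant, and whose classification does not fall
#' under any excluded clade. Records lacking coverage of at least one motif
#' position are returned separately as not evaluable.
#'
#' @param db Haplotype tibble.
#' @param motif Variant tibble or motif string.
#' @param exclude Character vector of clade names whose members are
#'   disregarded (classified via `tree`).
#' @param tree Required when `exclude` is non-empty.
#' @param policy [hotspot_policy()] for the classification step.
#' @return List with tibbles `hits` and `not_evaluable` (the latter with a
#'   `reason` column).
#' @export
#' @examples
#' db <- haplotype("r1", "A16293G-G16213A")
#' search_motif(db, "A16293G-G16213A")
search_motif <- function(db, motif, exclude = character(), tree = NULL,
                         policy = hotspot_policy()) {
  if (is.character(motif)) motif <- parse_motif(motif)
  if (nrow(motif) == 0L) abort("empty search motif")
  if (length(exclude)) {
    if (is.null(tree)) abort("'tree' is required when 'exclude' is used")
    for (nm in exclude) assert_node(tree, nm)
  }
  if (nrow(db) == 0L) {
    return(list(hits = db, not_evaluable = mutate(db, reason = character(0))))
  }
  covered <- map_lgl(db$ranges, function(r) all(covers(motif$position, r)))
  not_eval <- db[!covered, , drop = FALSE]
  if (nrow(not_eval)) {
    not_eval$reason <- map_chr(not_eval$ranges, function(r) {
      sprintf("position(s) %s not covered",
              paste(motif$position[!covers(motif$position, r)], collapse = ", "))
    })
  } else {
    not_eval$reason <- character(0)
  }
  cand <- db[covered, , drop = FALSE]
  carries <- map_lgl(cand$variants,
                     function(v) all(motif$token %in% present_tokens(v)))
  hits <- cand[carries, , drop = FALSE]
  if (length(exclude) && nrow(hits)) {
    asg <- classify_db(hits, tree, policy = policy)
    excluded <- map_lgl(asg$haplogroup, function(hg) {
      any(vapply(exclude, function(cl) is_under(tree, hg, cl), TRUE))
    })
    hits <- hits[!excluded, , drop = FALSE]
  }
  list(hits = hits, not_evaluable = not_eval)
}
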