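# Haplogroup frequencies, maternal-ancestry partition, diversity counts.

#' Default haplogroup display categories
#'
#' Category scheme for frequency tables, mirroring the usual presentation of
#' Romani mtDNA pools: the signature clades shown on their own, macro-level
#' bins for the rest, and "other" for haplotypes that could not be assigned
#' unambiguously. A scheme is an ordered named list category -> clade names;
#' a record falls in the first category whose clade contains its assignment,
#' so order encodes precedence.
#'
#' @return Named list of character vectors of clade names.
#' @export
default_category_scheme <- function() {
  list(
    M5a1b1a1 = "M5a1b1a1",
    `M(other)` = "M",
    U3 = "U3",
    U = "U",
    H = c("H5", "H24", "H88a"),
    A = "A2",
    L = "L2",
    other = character()
  )
}

#' Default maternal-ancestry partition rules
#'
#' South Asian ancestry is indicated by macro-haplogroup M excluding M1
#' candidates (M(xM1)); sub-Saharan by the L clades outside M and N; West
#' Eurasian by the N-derived clades plus M1; "other" collects records that
#' could not be placed (root assignments). The M1-as-African alternative
#' reading is a toggle.
#'
#' @param m1_african Treat M1 (e.g. M1a1) as sub-Saharan instead of West
#'   Eurasian.
#' @return An `ancestry_rules` list.
#' @export
ancestry_rules <- function(m1_african = FALSE) {
  structure(
    list(id = if (m1_african) "phylogeo-m1-african" else "phylogeo-default",
         m1_african = m1_african,
         south_asian_clade = "M", m1_clade = "M1",
         sub_saharan_clades = "L2"),
    class = "ancestry_rules"
  )
}

category_of_path <- function(path, scheme) {
  for (cat in names(scheme)) {
    if (any(scheme[[cat]] %in% path)) return(cat)
  }
  "other"
}

#' Haplogroup frequency table by group
#'
#' @param db Haplotype tibble.
#' @param assignments Assignment tibble from [classify_db()] (computed if
#'   `NULL`).
#' @param tree A `haplogroup_tree` (needed to resolve clade membership).
#' @param scheme Category scheme (see [default_category_scheme()]).
#' @param by Grouping column of `db` (default `"group"`).
#' @return A `frequency_table` tibble: `group`, `category`, `count`,
#'   `fraction`, `percent` (one-decimal), with per-group fractions summing
#'   to one.
#' @export
frequency_table <- function(db, assignments = NULL, tree = mini_haplogroup_tree(),
                            scheme = default_category_scheme(), by = "group") {
  if (is.null(assignments)) assignments <- classify_db(db, tree)
  if (nrow(db) != nrow(assignments) ||
      !all(db$id == assignments$haplotype_id)) {
    abort("assignments do not line up with db records")
  }
  paths <- setNames(lapply(tree$nodes$name, node_path, tree = tree),
                    tree$nodes$name)
  category <- map_chr(assignments$haplogroup, function(hg) {
    # unplaced records (root, no diagnostics matched) go to "other"
    if (hg == tree_root(tree)) "other"
    else category_of_path(paths[[hg]], scheme)
  })
  out <- tibble(group = db[[by]], category = category) |>
    count(.data$group, .data$category, name = "count") |>
    group_by(.data$group) |>
    mutate(fraction = .data$count / sum(.data$count),
           percent = round(100 * .data$fraction, 1)) |>
    ungroup() |>
    arrange(.data$group, factor(.data$category,
                                levels = unique(c(names(scheme), "other"))))
  check <- out |> group_by(.data$group) |> summarise(s = sum(.data$fraction))
  stopifnot(all(abs(check$s - 1) < 1e-9))
  structure(out, class = c("frequency_table", class(out)),
            scheme_id = paste(names(scheme), collapse = "|"))
}

#' Phylogeographic maternal-ancestry partition
#'
#' Partitions classified records into South Asian (M excluding M1), West
#' Eurasian (N-derived plus M1 under the default rules), sub-Saharan (L
#' clades) and other (unplaced) fractions.
#'
#' @param assignments Assignment tibble from [classify_db()].
#' @param tree The `haplogroup_tree` used for classification.
#' @param rules [ancestry_rules()].
#' @return An `admixture_estimate` tibble (one row): the four fractions,
#'   `n`, and `rule_set`.
#' @export
ancestry_partition <- function(assignments, tree = mini_haplogroup_tree(),
                               rules = ancestry_rules()) {
  root <- tree_root(tree)
  cats <- map2_chr(assignments$haplogroup, assignments$extras, function(hg, ex) {
    path <- node_path(tree, hg)
    if (any(rules$sub_saharan_clades %in% path)) return("sub_saharan")
    if (rules$m1_clade %in% path) {
      return(if (rules$m1_african) "sub_saharan" else "west_eurasian")
    }
    if (rules$south_asian_clade %in% path) return("south_asian")
    # a root assignment with private variants could not be placed anywhere
    if (hg == root && length(ex) > 0L) return("other")
    "west_eurasian"
  })
  n <- length(cats)
  if (n == 0L) abort("no assignments")
  frac <- function(cat) sum(cats == cat) / n
  out <- tibble(
    south_asian = frac("south_asian"),
    west_eurasian = frac("west_eurasian"),
    sub_saharan = frac("sub_saharan"),
    other = frac("other"),
    n = n, rule_set = rules$id
  )
  stopifnot(abs(sum(out[1, 1:4]) - 1) < 1e-9)
  structure(out, class = c("admixture_estimate", class(out)))
}

#' Diversity summary of a clade's records
#'
#' Counts distinct haplotypes on a common sequenced range and the fraction
#' of records equal to the clade's basal motif on that range.
#'
#' @param records Haplotype tibble (members of one clade).
#' @param basal_motif Variant tibble or motif string (the clade root).
#' @param range Common comparison range `c(start, end)`; default HVS-I.
#' @param policy [hotspot_policy()].
#' @return One-row tibble: `n_records`, `n_distinct_haplotypes`,
#'   `fraction_basal`.
#' @export
diversity_summary <- function(records, basal_motif = empty_variants(),
                              range = HVS1_RANGE, policy = hotspot_policy()) {
  if (nrow(records) == 0L) abort("empty record set")
  if (is.character(basal_motif)) basal_motif <- parse_motif(basal_motif)
  restrict <- function(v) {
    v <- mask_hotspots(v, policy)
    sort(v$token[!v$back_mutation & !v$heteroplasmy &
                   v$position >= range[1] & v$position <= range[2]])
  }
  keys <- map_chr(records$variants, function(v) paste(restrict(v), collapse = "|"))
  basal_key <- paste(restrict(basal_motif), collapse = "|")
  tibble(
    n_records = nrow(records),
    n_distinct_haplotypes = length(unique(keys)),
    fraction_basal = mean(keys == basal_key)
  )
}

#' Write a tibble report as TSV
#' @param x Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  flat <- x
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- map_chr(flat[[col]], paste, collapse = ",")
    }
  }
  readr::write_tsv(as_tibble(flat), path)
  invisible(path)
}
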