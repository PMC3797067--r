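# Haplotype records and tab-separated haplotype tables.
#
# A haplotype database is a tibble with one row per record:
#   id          unique record identifier
#   population  free-text population label
#   group       "romani", "non_romani" or "unknown"
#   source      study / database tag
#   ranges      list-column of tibble(start, end): sequenced rCRS windows
#   variants    list-column of variant tibbles (rCRS-relative)
# The on-disk dialect is a TSV with columns id, population, group, source,
# range ("start-end", several windows ";"-separated) and variants
# (dash-separated tokens, empty = rCRS within the sequenced range). Writers
# emit the same dialect readers accept.

GROUP_LEVELS <- c("romani", "non_romani", "unknown")

#' Parse a sequenced-range field
#'
#' @param text Ranges like `"16024-16400"` or `"57-372;16024-16400"`.
#' @return Tibble with integer `start`, `end`.
#' @export
parse_ranges <- function(text) {
  text <- str_trim(text)
  if (is.na(text) || !nzchar(text)) abort("empty sequenced range")
  parts <- str_trim(str_split(text, ";")[[1]])
  parts <- parts[nzchar(parts)]
  m <- str_match(parts, "^(\\d+)\\s*-\\s*(\\d+)$")
  if (anyNA(m[, 1])) abort(sprintf("malformed range '%s'", text))
  out <- tibble(start = as.integer(m[, 2]), end = as.integer(m[, 3]))
  if (any(out$start > out$end) || any(out$start < 1L) ||
      any(out$end > RCRS_LENGTH)) {
    abort(sprintf("range '%s' outside 1..%d or start > end", text, RCRS_LENGTH))
  }
  out
}

format_ranges <- function(ranges) {
  paste(sprintf("%d-%d", ranges$start, ranges$end), collapse = ";")
}

#' Are positions covered by a record's sequenced ranges?
#' @param position Integer positions.
#' @param ranges Tibble with `start`, `end`.
#' @return Logical vector.
#' @export
covers <- function(position, ranges) {
  vapply(position, function(p) any(p >= ranges$start & p <= ranges$end), TRUE)
}

#' Construct a haplotype record
#'
#' @param id Record identifier.
#' @param variants Variant tibble or motif string.
#' @param ranges Range tibble or range string (default full HVS-I window).
#' @param population,group,source Labels.
#' @return One-row haplotype tibble.
#' @export
haplotype <- function(id, variants = empty_variants(),
                      ranges = sprintf("%d-%d", HVS1_RANGE[1], HVS1_RANGE[2]),
                      population = "unknown", group = "unknown",
                      source = "user") {
  if (is.character(variants)) variants <- parse_motif(variants)
  if (is.character(ranges)) ranges <- parse_ranges(ranges)
  group <- match.arg(group, GROUP_LEVELS)
  rec <- tibble(id = id, population = population, group = group,
                source = source, ranges = list(ranges),
                variants = list(variants))
  validate_haplotypes(rec)
}

#' Validate a haplotype table
#'
#' Enforces the record invariants: unique ids, every variant position inside
#' a sequenced range, and no duplicated positions within a record.
#'
#' @param db Haplotype tibble.
#' @return `db`, invisibly validated.
#' @export
validate_haplotypes <- function(db) {
  if (anyDuplicated(db$id)) {
    abort(sprintf("duplicate haplotype ids: %s",
                  paste(unique(db$id[duplicated(db$id)]), collapse = ", ")))
  }
  for (i in seq_len(nrow(db))) {
    v <- db$variants[[i]]
    if (nrow(v) == 0L) next
    cov <- covers(v$position, db$ranges[[i]])
    if (!all(cov)) {
      abort(sprintf("record '%s': variant %s outside declared range(s) %s",
                    db$id[i], paste(v$token[!cov], collapse = ", "),
                    format_ranges(db$ranges[[i]])))
    }
    subs <- v[!v$klass %in% "insertion", ]
    if (anyDuplicated(subs$position)) {
      abort(sprintf("record '%s': position %s appears more than once",
                    db$id[i],
                    paste(unique(subs$position[duplicated(subs$position)]),
                          collapse = ", ")))
    }
  }
  invisible(db)
}

#' Read a haplotype table (TSV dialect)
#'
#' Required columns: `id`, `population`, `group`, `range`, `variants`;
#' optional `source`. Rows that fail to parse are rejected with row-level
#' diagnostics; parse/reject counts are reported via a message.
#'
#' @param path TSV file path.
#' @inheritParams parse_variant
#' @return Haplotype tibble; rejected rows (with a `reason` column) are
#'   attached as attribute `"rejected"`.
#' @export
read_haplotype_table <- function(path, ref_check = c("error", "warn", "none")) {
  ref_check <- match.arg(ref_check)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  required <- c("id", "population", "group", "range", "variants")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("haplotype table '%s' lacks column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (!"source" %in% names(raw)) raw$source <- basename(path)
  if (anyDuplicated(raw$id)) {
    abort(sprintf("duplicate ids in '%s': %s", path,
                  paste(unique(raw$id[duplicated(raw$id)]), collapse = ", ")))
  }
  rows <- vector("list", nrow(raw))
  rejects <- list()
  for (i in seq_len(nrow(raw))) {
    rows[[i]] <- tryCatch({
      grp <- if (is.na(raw$group[i])) "unknown" else raw$group[i]
      haplotype(raw$id[i],
                variants = parse_motif(raw$variants[i] %|na|% "",
                                       ref_check = ref_check),
                ranges = raw$range[i],
                population = raw$population[i] %|na|% "unknown",
                group = grp, source = raw$source[i] %|na|% basename(path))
    }, error = function(e) {
      rejects[[length(rejects) + 1L]] <<-
        tibble(row = i, id = raw$id[i], reason = conditionMessage(e))
      NULL
    })
  }
  db <- bind_rows(rows)
  rejected <- bind_rows(rejects)
  inform(sprintf("read %d record(s) from '%s' (%d rejected)",
                 nrow(db), path, nrow(rejected)))
  if (nrow(rejected)) attr(db, "rejected") <- rejected
  db
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

#' Write a haplotype table in the same TSV dialect [read_haplotype_table()] reads
#'
#' @param db Haplotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(db, path) {
  flat <- tibble(
    id = db$id, population = db$population, group = db$group,
    source = db$source,
    range = map_chr(db$ranges, format_ranges),
    variants = map_chr(db$variants, format_motif)
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Variants of an rCRS-aligned sequence window
#'
#' Compares an aligned sequence against the reference within a window and
#' returns substitution/deletion variants. `N` sites are ignored. Gap
#' columns ("-") are reported as deletions, except inside the masked
#' length-variation region of `policy`, where they are dropped.
#'
#' @param seq Character scalar or per-base vector, same length as the window;
#'   symbols A/C/G/T/N/-.
#' @param window Range tibble row or `c(start, end)`.
#' @param reference Full-length reference base vector; defaults to
#'   [synthetic_reference()].
#' @param policy [hotspot_policy()] controlling in-region gap handling.
#' @return Variant tibble.
#' @export
diff_aligned <- function(seq, window, reference = synthetic_reference(),
                         policy = hotspot_policy()) {
  if (is.character(seq) && length(seq) == 1L) {
    seq <- str_split(seq, "")[[1]]
  }
  seq <- toupper(seq)
  if (is.data.frame(window)) window <- c(window$start[1], window$end[1])
  window <- as.integer(window)
  positions <- seq.int(window[1], window[2])
  if (length(seq) != length(positions)) {
    abort(sprintf("sequence length %d does not match window %d-%d",
                  length(seq), window[1], window[2]))
  }
  bad <- setdiff(unique(seq), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    abort(sprintf("unexpected symbol(s) in aligned sequence: %s",
                  paste(bad, collapse = ", ")))
  }
  ref <- rcrs_base(positions, reference)
  differs <- seq != ref & seq != "N"
  out <- list(empty_variants())
  for (j in which(differs)) {
    p <- positions[j]
    if (seq[j] == "-") {
      if (policy$drop_indels_in_region &&
          p >= policy$masked_region[1] && p <= policy$masked_region[2]) next
      out[[length(out) + 1L]] <- variant_row(paste0(p, "d"), p, ref[j], "-",
                                             "deletion")
    } else {
      out[[length(out) + 1L]] <-
        variant_row(paste0(ref[j], p, seq[j]), p, ref[j], seq[j],
                    classify_substitution(ref[j], seq[j]))
    }
  }
  bind_rows(out)
}
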