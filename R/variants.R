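# rCRS-relative variant notation.
#
# Accepted dialects (whitespace-trimmed):
#   T16298C    explicit ref + position + derived
#   16223T     position + derived (ref filled from the catalog when known)
#   16223      bare position: transition of the catalog base
#   @16129     back mutation (reversion to the rCRS state); also @G16129A
#   315+C      insertion after position 315 (also 315.1C ordinal dialect)
#   16166d     deletion of position 16166 (also "16166del")
#   C16093Y    IUPAC derived state: point heteroplasmy, parsed but flagged
# Annotation suffixes from figure notation — a leading "*", trailing "s",
# "-t", "-r", "-nc", or "(...)" — are carried in `annotation` and never
# affect identity or computation.

.transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
.iupac_ambiguous <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

empty_variants <- function() {
  tibble(
    token = character(), position = integer(), ref = character(),
    derived = character(), klass = character(), back_mutation = logical(),
    heteroplasmy = logical(), annotation = character()
  )
}

variant_row <- function(token, position, ref, derived, klass,
                        back_mutation = FALSE, heteroplasmy = FALSE,
                        annotation = NA_character_) {
  tibble(
    token = token, position = as.integer(position), ref = ref,
    derived = derived, klass = klass, back_mutation = back_mutation,
    heteroplasmy = heteroplasmy, annotation = annotation
  )
}

classify_substitution <- function(ref, derived) {
  if (is.na(ref) || is.na(derived)) return(NA_character_)
  if (identical(.transition_partner[[ref]], derived)) "transition"
  else "transversion"
}

check_position <- function(position, token) {
  if (is.na(position) || position < 1L || position > RCRS_LENGTH) {
    abort(sprintf("variant token '%s': position %s outside 1..%d",
                  token, position, RCRS_LENGTH))
  }
  as.integer(position)
}

# Split off annotation decorations; returns list(core, annotation).
strip_annotation <- function(token) {
  ann <- character()
  if (str_detect(token, "^\\*")) {
    ann <- c(ann, "*"); token <- str_remove(token, "^\\*")
  }
  m <- str_match(token, "^(.*?)(\\([^()]*\\))$")
  if (!is.na(m[1, 1])) {
    ann <- c(ann, m[1, 3]); token <- m[1, 2]
  }
  m <- str_match(token, "^(.*?)-(t|r|nc)$")
  if (!is.na(m[1, 1])) {
    ann <- c(ann, paste0("-", m[1, 3])); token <- m[1, 2]
  }
  # synonymous marker: trailing 's' after a complete substitution token
  m <- str_match(token, "^(@?[ACGT]?\\d+[ACGT])s$")
  if (!is.na(m[1, 1])) {
    ann <- c(ann, "s"); token <- m[1, 2]
  }
  list(core = token, annotation = if (length(ann)) paste(ann, collapse = "") else NA_character_)
}

#' Parse one rCRS-relative variant token
#'
#' @param token A single token such as `"T16298C"`, `"16223T"`, `"@16129"`,
#'   `"315+C"` or `"16166d"`.
#' @param ref_check How to treat a stated reference base that contradicts the
#'   curated rCRS catalog: `"error"` (default), `"warn"`, or `"none"`.
#' @return One-row variant tibble with columns `token` (canonical form),
#'   `position`, `ref`, `derived`, `klass` (transition / transversion /
#'   insertion / deletion), `back_mutation`, `heteroplasmy`, `annotation`.
#' @export
#' @examples
#' parse_variant("T16298C")
#' parse_variant("@16129")
#' parse_variant("315+C")
parse_variant <- function(token, ref_check = c("error", "warn", "none")) {
  ref_check <- match.arg(ref_check)
  raw <- token
  token <- str_trim(token)
  if (!nzchar(token)) abort("empty variant token")

  parts <- strip_annotation(token)
  core <- parts$core
  ann <- parts$annotation

  back <- str_detect(core, "^@")
  if (back) core <- str_remove(core, "^@")

  # insertion: 315+C or ordinal dialect 315.1C
  m <- str_match(core, "^(\\d+)\\+([ACGT]+)$")
  if (is.na(m[1, 1])) {
    m2 <- str_match(core, "^(\\d+)\\.(\\d+)([ACGT]+)$")
    if (!is.na(m2[1, 1])) {
      m <- m2[, c(1, 2, 4), drop = FALSE]
      ann <- paste0(ifelse(is.na(ann), "", ann), ".", m2[1, 3])
    }
  }
  if (!is.na(m[1, 1])) {
    if (back) abort(sprintf("variant token '%s': '@' applies to substitutions", raw))
    pos <- check_position(as.integer(m[1, 2]), raw)
    return(variant_row(paste0(pos, "+", m[1, 3]), pos, "", m[1, 3],
                       "insertion", annotation = ann))
  }

  # deletion: 16166d / 16166del / C16166d
  m <- str_match(core, "^([ACGT]?)(\\d+)(d|del)$")
  if (!is.na(m[1, 1])) {
    if (back) abort(sprintf("variant token '%s': '@' applies to substitutions", raw))
    pos <- check_position(as.integer(m[1, 3]), raw)
    ref <- resolve_ref(m[1, 2], pos, raw, ref_check)
    return(variant_row(paste0(pos, "d"), pos, ref %||% NA_character_, "-",
                       "deletion", annotation = ann))
  }

  # substitution (possibly bare-position transition, possibly IUPAC derived)
  m <- str_match(core, "^([ACGT]?)(\\d+)([ACGT]|[RYSWKMBDHVN])?$")
  if (is.na(m[1, 1])) {
    abort(sprintf("malformed variant token '%s'", raw))
  }
  pos <- check_position(as.integer(m[1, 3]), raw)
  ref <- resolve_ref(m[1, 2], pos, raw, ref_check)
  derived <- m[1, 4]

  if (back) {
    # reversion to the rCRS state: '@16129' or '@G16129A' (original mutation
    # with '@' prefix). Stored with ref = the pre-reversion (mutant) state
    # and derived = the rCRS base.
    rcrs <- rcrs_base(pos)
    if (nzchar(m[1, 2]) && !is.na(derived) && nzchar(derived)) {
      orig_ref <- m[1, 2]; orig_alt <- derived
      if (!is.na(rcrs) && rcrs != orig_ref && ref_check != "none") {
        msg <- sprintf("token '%s': stated base %s differs from rCRS %s at %d",
                       raw, orig_ref, rcrs, pos)
        if (ref_check == "error") abort(msg) else warn(msg)
      }
      rcrs <- orig_ref
    } else {
      if (is.na(rcrs)) {
        abort(sprintf("token '%s': cannot resolve back mutation at position %d without a cataloged rCRS base",
                      raw, pos))
      }
      orig_alt <- .transition_partner[[rcrs]]
    }
    return(variant_row(paste0("@", rcrs, pos, orig_alt), pos, orig_alt, rcrs,
                       classify_substitution(orig_alt, rcrs),
                       back_mutation = TRUE, annotation = ann))
  }

  if (is.na(derived) || !nzchar(derived)) {
    # bare position: transition of the reference base
    if (is.null(ref) || is.na(ref)) {
      abort(sprintf("token '%s': bare position needs a cataloged rCRS base", raw))
    }
    derived <- .transition_partner[[ref]]
  }
  ref <- ref %||% NA_character_
  if (!is.na(ref) && identical(ref, derived)) {
    abort(sprintf("token '%s': derived state equals the reference base", raw))
  }

  if (derived %in% .iupac_ambiguous) {
    return(variant_row(paste0(ifelse(is.na(ref), "", ref), pos, derived),
                       pos, ref, derived, NA_character_,
                       heteroplasmy = TRUE, annotation = ann))
  }
  variant_row(paste0(ifelse(is.na(ref), "", ref), pos, derived),
              pos, ref, derived, classify_substitution(ref, derived),
              annotation = ann)
}

# Reconcile a stated ref base with the catalog; returns the ref to store.
resolve_ref <- function(stated, pos, token, ref_check) {
  catalog <- rcrs_base(pos)
  if (nzchar(stated)) {
    if (!is.na(catalog) && catalog != stated && ref_check != "none") {
      msg <- sprintf("token '%s': stated reference base %s differs from rCRS %s at position %d",
                     token, stated, catalog, pos)
      if (ref_check == "error") abort(msg) else warn(msg)
    }
    stated
  } else {
    catalog
  }
}

#' Canonical text form of variants
#'
#' @param variants A variant tibble (from [parse_variant()] / [parse_motif()]).
#' @return Character vector of canonical tokens.
#' @export
format_variant <- function(variants) {
  variants$token
}

#' Parse a dash-separated variant motif
#'
#' @param text Motif string such as `"G16129A-C16223T-C16291T-T16298C"`;
#'   whitespace around tokens is tolerated; `""` yields an empty motif.
#' @inheritParams parse_variant
#' @return Variant tibble, one row per token, in motif order.
#' @export
#' @examples
#' parse_motif("G16129A-C16223T-C16291T-T16298C")
parse_motif <- function(text, ref_check = c("error", "warn", "none")) {
  ref_check <- match.arg(ref_check)
  text <- str_trim(text)
  if (is.na(text) || !nzchar(text)) return(empty_variants())
  tokens <- str_trim(str_split(text, "-")[[1]])
  tokens <- tokens[nzchar(tokens)]
  out <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    out[[i]] <- tryCatch(
      parse_variant(tokens[i], ref_check = ref_check),
      error = function(e) {
        abort(sprintf("motif token %d ('%s'): %s", i, tokens[i],
                      conditionMessage(e)))
      }
    )
  }
  bind_rows(out)
}

#' Format a variant tibble as a dash-separated motif
#' @param variants Variant tibble.
#' @return Single motif string (`""` for an empty tibble).
#' @export
format_motif <- function(variants) {
  paste(variants$token, collapse = "-")
}

# Tokens representing derived states actually present in a haplotype:
# back-mutation rows mean the position is at the rCRS state, heteroplasmies
# are excluded from all computation.
present_tokens <- function(variants) {
  variants$token[!variants$back_mutation & !variants$heteroplasmy]
}
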