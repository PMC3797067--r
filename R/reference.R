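# rCRS coordinate system and reference-base support.
#
# Variant notation is relative to the revised Cambridge Reference Sequence
# (rCRS, 16,569 bp). The package does not bundle the full genome; it ships a
# curated catalog of reference bases at the positions used by the packaged
# haplogroup tree, the mutational hotspots, and the common control-region
# nomenclature, which is what token validation needs. For operations that
# require a base at every position (aligned-sequence diffing, simulation) a
# deterministic synthetic reference is generated: real catalog bases at
# cataloged positions, pseudo-random bases elsewhere. It is synthetic and is
# documented as such; any true reference FASTA can be supplied instead.

#' Length of the rCRS mitochondrial coordinate system
#' @export
RCRS_LENGTH <- 16569L

#' Default HVS-I range used for control-region haplotypes
#'
#' Hypervariable segment I window 16024-16400, wide enough to contain every
#' control-region motif the packaged haplogroup tree uses. The exact right
#' edge used by compiled studies differs (16365 vs 16400); it is an argument
#' wherever it matters.
#' @export
HVS1_RANGE <- c(16024L, 16400L)

# Token corpus fixing known rCRS bases. Every packaged haplogroup diagnostic
# appears here, plus hotspots, the 303-315 length-variation stretch and
# standard control-region sites. The stated ref base of each token IS the
# catalog entry.
.catalog_tokens <- c(
  # control region (HVS-II / HVS-I) sites
  "A73G", "A93G", "T146C", "C150T", "T152C", "A153G", "G185A", "T195C",
  "C198T", "T246C", "A263G", "C325T", "T334C",
  "C16069T", "C16111T", "T16126C", "G16129A", "G16145A", "T16172C",
  "C16186T", "C16187T", "T16189C", "C16192T", "G16213A", "C16223T",
  "T16224C", "A16230G", "C16233T", "T16249C", "C16256T", "C16261T",
  "C16270T", "C16278T", "C16290T", "C16291T", "C16292T", "A16293G",
  "C16294T", "T16298C", "T16304C", "A16309G", "T16311C", "A16318T",
  "G16319A", "C16320T", "A16343G", "C16344T", "T16356C", "T16359C",
  "T16362C", "G16390A",
  # coding-region diagnostics of the packaged tree
  "A750G", "A1438G", "G1303A", "A2706G", "A2833G", "T3621C", "C3954T",
  "A4769G", "A6461G", "C7028T", "T7759C", "A8860G", "T8895C", "G9064A",
  "T9833C", "C10400T", "G11016A", "C11047T", "C11119T", "G11719A",
  "A12308G", "A12712G", "T12783C", "C14766T", "T14783C", "G15043A",
  "T15262C", "A15326G"
)

.hotspot_ref <- c("16182" = "A", "16183" = "A", "16519" = "T")
.cstretch_ref <- setNames(
  c(rep("C", 7), "T", rep("C", 5)),
  as.character(303:315)
)

.catalog_env <- new.env(parent = emptyenv())

#' Curated rCRS reference-base catalog
#'
#' Positions of the rCRS with a known reference base, as a named character
#' vector (names are 1-based positions). Covers every diagnostic position of
#' the packaged haplogroup tree, the hotspot positions 16182/16183/16519 and
#' the 303-315 length-variation stretch. Used by [parse_variant()] to
#' validate stated reference bases; positions outside the catalog are
#' accepted as stated.
#'
#' @return Named character vector of single bases.
#' @export
#' @examples
#' rcrs_base_catalog()[c("16223", "16298")]
rcrs_base_catalog <- function() {
  if (is.null(.catalog_env$catalog)) {
    m <- regmatches(.catalog_tokens,
                    regexec("^([ACGT])(\\d+)([ACGT])$", .catalog_tokens))
    pos <- vapply(m, `[`, "", 3)
    base <- vapply(m, `[`, "", 2)
    cat <- c(setNames(base, pos), .hotspot_ref, .cstretch_ref)
    cat <- cat[!duplicated(names(cat))]
    .catalog_env$catalog <- cat[order(as.integer(names(cat)))]
  }
  .catalog_env$catalog
}

#' Reference base at given rCRS positions
#'
#' Looks positions up in a reference: either the curated catalog (default,
#' `NA` where unknown) or a full-length reference vector such as
#' [synthetic_reference()] or a genome read with [read_reference_fasta()].
#'
#' @param position Integer vector of 1-based rCRS positions.
#' @param reference Either `NULL` (use the catalog) or a character vector of
#'   length [RCRS_LENGTH] of bases.
#' @return Character vector of bases (`NA` where unknown).
#' @export
rcrs_base <- function(position, reference = NULL) {
  stopifnot(all(position >= 1L & position <= RCRS_LENGTH))
  if (is.null(reference)) {
    unname(rcrs_base_catalog()[as.character(position)])
  } else {
    stopifnot(length(reference) == RCRS_LENGTH)
    reference[position]
  }
}

#' Synthetic full-length reference sequence
#'
#' A deterministic stand-in for the full rCRS: at every cataloged position it
#' carries the true rCRS base; everywhere else the base is pseudo-random
#' (fixed internal seed, so the sequence is identical across sessions). It is
#' *synthetic* — suitable for simulation and for exercising aligned-sequence
#' diffing, not for interpreting real genomes, for which a true reference
#' FASTA should be read with [read_reference_fasta()].
#'
#' @return Character vector of length [RCRS_LENGTH] with attribute
#'   `synthetic = TRUE`.
#' @export
synthetic_reference <- function() {
  if (is.null(.catalog_env$synthetic)) {
    seq <- with_preserved_rng(20130815L, {
      sample(c("A", "C", "G", "T"), RCRS_LENGTH, replace = TRUE,
             prob = c(0.31, 0.31, 0.13, 0.25))
    })
    cat <- rcrs_base_catalog()
    seq[as.integer(names(cat))] <- unname(cat)
    attr(seq, "synthetic") <- TRUE
    .catalog_env$synthetic <- seq
  }
  .catalog_env$synthetic
}

#' Read an rCRS-aligned reference FASTA
#'
#' Reads the first record of a FASTA file and returns it as an uppercase
#' per-base character vector, checked to be [RCRS_LENGTH] long.
#'
#' @param path Path to a FASTA file.
#' @return Character vector of length [RCRS_LENGTH].
#' @export
read_reference_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) < 1L) abort("no sequences in FASTA file")
  x <- toupper(as.character(as.matrix(seqs[1]))[1, ])
  if (length(x) != RCRS_LENGTH) {
    abort(sprintf("reference has %d bases; expected %d",
                  length(x), RCRS_LENGTH))
  }
  x
}

#' Write a per-base sequence to FASTA
#'
#' @param seq Character vector of bases.
#' @param path Output path.
#' @param name Sequence header.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(seq, path, name = "reference") {
  lines <- c(paste0(">", name),
             vapply(split(seq, ceiling(seq_along(seq) / 70)),
                    paste0, "", collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

# Run `code` with a locally seeded RNG, restoring the caller's RNG state.
with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
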