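# Hotspot masking.
#
# Phylogenetic reconstruction and founder dating exclude the fastest mtDNA
# positions: the point hotspots 16182, 16183 and 16519, and indel variation
# in the 303-315 length-variation stretch around position 310. Point
# heteroplasmies are likewise never counted.

#' Hotspot masking policy
#'
#' @param masked_positions Integer positions whose substitutions are excluded
#'   (default 16182, 16183, 16519).
#' @param masked_region Two-element interval within which length variation
#'   (insertions/deletions) is excluded; default 303-315.
#' @param drop_indels_in_region Drop indels inside `masked_region`? Default
#'   `TRUE`.
#' @param drop_heteroplasmies Drop flagged point heteroplasmies? Default
#'   `TRUE`.
#' @return A `hotspot_policy` list.
#' @export
hotspot_policy <- function(masked_positions = c(16182L, 16183L, 16519L),
                           masked_region = c(303L, 315L),
                           drop_indels_in_region = TRUE,
                           drop_heteroplasmies = TRUE) {
  stopifnot(length(masked_region) == 2L, masked_region[1] <= masked_region[2])
  structure(
    list(masked_positions = as.integer(masked_positions),
         masked_region = as.integer(masked_region),
         drop_indels_in_region = drop_indels_in_region,
         drop_heteroplasmies = drop_heteroplasmies),
    class = "hotspot_policy"
  )
}

#' Remove hotspot variants from a variant set
#'
#' Idempotent; the input tibble is not modified.
#'
#' @param variants Variant tibble.
#' @param policy A [hotspot_policy()].
#' @return Variant tibble without masked variants.
#' @export
#' @examples
#' mask_hotspots(parse_motif("A16182C-T16298C"))
mask_hotspots <- function(variants, policy = hotspot_policy()) {
  stopifnot(inherits(policy, "hotspot_policy"))
  keep <- !(variants$position %in% policy$masked_positions &
              variants$klass %in% c("transition", "transversion", NA))
  if (policy$drop_indels_in_region) {
    in_region <- variants$position >= policy$masked_region[1] &
      variants$position <= policy$masked_region[2]
    keep <- keep & !(in_region & variants$klass %in% c("insertion", "deletion"))
  }
  if (policy$drop_heteroplasmies) keep <- keep & !variants$heteroplasmy
  variants[keep, , drop = FALSE]
}

#' Apply hotspot masking to every record of a haplotype table
#'
#' @param db Haplotype tibble with a `variants` list-column.
#' @inheritParams mask_hotspots
#' @return `db` with masked variant sets.
#' @export
mask_db <- function(db, policy = hotspot_policy()) {
  db$variants <- map(db$variants, mask_hotspots, policy = policy)
  db
}
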