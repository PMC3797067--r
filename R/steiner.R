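# Exact minimum-mutation oracle for small instances.
#
# The minimum number of mutation events over all rooted trees containing the
# root haplotype and every observed haplotype equals the length of a minimum
# Steiner tree in the {0,1}^k Hamming hypercube whose coordinates are the
# segregating variant tokens (1 = derived state carried). Solved exactly
# with the Dreyfus-Wagner dynamic programme; the metric min-plus step uses
# the separable per-dimension relaxation valid for Hamming distance.

#' Exact minimum mutation count (enumeration oracle)
#'
#' Guarded to small instances; intended as the verification oracle for
#' [build_tree()].
#'
#' @param haps Haplotype tibble.
#' @param root_variants Basal motif (variant tibble or motif string).
#' @param policy [hotspot_policy()] applied first.
#' @param max_haps,max_sites Guard rails (defaults 7 distinct haplotypes,
#'   12 segregating sites).
#' @return Integer: exact minimum number of mutation events.
#' @export
brute_force_min <- function(haps, root_variants = empty_variants(),
                            policy = hotspot_policy(),
                            max_haps = 7L, max_sites = 12L) {
  if (nrow(haps) == 0L) abort("no haplotypes")
  if (is.character(root_variants)) root_variants <- parse_motif(root_variants)
  haps <- mask_db(haps, policy)
  root_set <- present_tokens(mask_hotspots(root_variants, policy))
  rel <- map(haps$variants, function(v) relative_set(present_tokens(v), root_set))
  rel <- unique(map(rel, sort))
  if (length(rel) > max_haps) {
    abort(sprintf("instance too large: %d distinct haplotypes (max %d)",
                  length(rel), max_haps))
  }
  sites <- sort(unique(sub("^@", "", unlist(rel))))
  k <- length(sites)
  if (k == 0L) return(0L)
  if (k > max_sites) {
    abort(sprintf("instance too large: %d segregating sites (max %d)",
                  k, max_sites))
  }
  # vertex encoding: bit i set = derived state at sites[i]; relative to the
  # root, a plain token means bit gained, an "@token" means the root carries
  # the derived state and this haplotype reverted it -- both encodings give
  # the same Hamming geometry, so encode each haplotype by the tokens it
  # differs from the root at.
  masks <- vapply(rel, function(s) {
    sum(bitwShiftL(1L, match(sub("^@", "", s), sites) - 1L))
  }, 0L)
  terminals <- unique(c(0L, masks))  # root vertex is the origin
  steiner_min_hypercube(terminals, k)
}

# Dreyfus-Wagner on the k-cube with unit Hamming edges.
steiner_min_hypercube <- function(terminals, k) {
  V <- bitwShiftL(1L, k)
  t <- length(terminals)
  if (t == 1L) return(0L)
  verts <- 0:(V - 1L)
  popcount <- integer(V)
  for (i in seq_len(k)) {
    popcount <- popcount + bitwAnd(bitwShiftR(verts, i - 1L), 1L)
  }
  # S[[X]] indexed by terminal subset bitmask (1..2^t-1), value: numeric V
  S <- vector("list", bitwShiftL(1L, t) - 1L)
  for (i in seq_len(t)) {
    S[[bitwShiftL(1L, i - 1L)]] <- popcount[bitwXor(verts, terminals[i]) + 1L]
  }
  full <- bitwShiftL(1L, t) - 1L
  subsets <- seq_len(full)
  subsets <- subsets[order(popcount_int(subsets))]
  for (X in subsets) {
    if (!is.null(S[[X]])) next
    low <- bitwAnd(X, -X)  # force the lowest terminal into one side
    Tm <- rep(Inf, V)
    sub <- bitwAnd(X - 1L, X)
    while (sub > 0L) {
      if (bitwAnd(sub, low) == low) {
        other <- bitwXor(X, sub)
        Tm <- pmin(Tm, S[[sub]] + S[[other]])
      }
      sub <- bitwAnd(sub - 1L, X)
    }
    # metric closure: propagate through the cube one dimension at a time
    for (i in seq_len(k)) {
      idx <- bitwXor(verts, bitwShiftL(1L, i - 1L)) + 1L
      Tm <- pmin(Tm, Tm[idx] + 1)
    }
    S[[X]] <- Tm
  }
  as.integer(S[[full]][1L])  # tree must reach the root vertex (origin)
}

popcount_int <- function(x) {
  out <- integer(length(x))
  while (any(x > 0L)) {
    out <- out + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  out
}
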