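# Synthetic genealogies, haplotypes and mixed databases with known truth.
#
# Two genealogy regimes bracket the demographies of interest: "star" (a
# founder expansion: every lineage radiates from the root at the TMRCA) and
# "coalescent" (a Kingman genealogy for a constant-size population, waiting
# times Exp(choose(k,2)/ne_years)). Mutations accumulate along branches as a
# Poisson process over a hotspot-weighted site spectrum; within a lineage a
# site is never hit twice, so homoplasy arises only across lineages (and can
# be switched off entirely to force a perfect phylogeny).

#' Mutation site spectrum
#'
#' Relative per-site mutability over a window of the molecule. Hotspot
#' positions (16182, 16183, 16519 and the 303-315 stretch) are heavily
#' up-weighted when included; positions can be excluded, e.g. the
#' diagnostics of a haplogroup tree when simulating private mutations, or
#' the hotspots when simulating the dating-countable mutation process.
#'
#' @param region `"hvs1"` (16024-16400) or `"whole"` (1-16569).
#' @param include_hotspots Include the hotspot positions?
#' @param hotspot_boost Relative weight of a hotspot site (default 20).
#' @param ts_tv Transition:transversion ratio (default 22).
#' @param exclude_positions Positions to drop from the spectrum.
#' @return Tibble `position`, `weight` (sums to one), with attributes
#'   `ts_tv` and `range`.
#' @export
mutation_spectrum <- function(region = c("hvs1", "whole"),
                              include_hotspots = TRUE, hotspot_boost = 20,
                              ts_tv = 22, exclude_positions = NULL) {
  region <- match.arg(region)
  rng <- if (region == "hvs1") HVS1_RANGE else c(1L, RCRS_LENGTH)
  pos <- seq.int(rng[1], rng[2])
  hot <- c(16182L, 16183L, 16519L, 303:315)
  w <- rep(1, length(pos))
  if (include_hotspots) {
    w[pos %in% hot] <- hotspot_boost
  } else {
    keep <- !pos %in% hot
    pos <- pos[keep]; w <- w[keep]
  }
  if (!is.null(exclude_positions)) {
    keep <- !pos %in% exclude_positions
    pos <- pos[keep]; w <- w[keep]
  }
  out <- tibble(position = pos, weight = w / sum(w))
  attr(out, "ts_tv") <- ts_tv
  attr(out, "range") <- rng
  out
}

#' Simulate a genealogy
#'
#' @param n Number of tips (>= 1).
#' @param model `"star"` or `"coalescent"`.
#' @param tmrca_years Star: the (exact) root-to-tip depth. Coalescent: if
#'   given, the realized tree is rescaled to this TMRCA; if `NULL`, depths
#'   come from the waiting times alone.
#' @param ne_years Coalescent scale: mean pairwise coalescence time in
#'   years.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `genealogy`: list with `edges` (tibble `parent`, `child`,
#'   `years`; tips are nodes `1..n`, the root is `0`), `n`, `model`,
#'   `tmrca_years` (realized), `seed`.
#' @export
#' @examples
#' simulate_genealogy(5, "star", tmrca_years = 1000)
simulate_genealogy <- function(n, model = c("star", "coalescent"),
                               tmrca_years = NULL, ne_years = 1000,
                               seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(n) || n < 1L) abort("invalid number of tips")
  n <- as.integer(n)
  run <- function() {
    if (model == "star") {
      tm <- tmrca_years %||% 1000
      edges <- tibble(parent = 0L, child = seq_len(n), years = rep(tm, n))
      list(edges = edges, tmrca = tm)
    } else {
      if (n == 1L) {
        return(list(edges = tibble(parent = 0L, child = 1L,
                                   years = tmrca_years %||% 0),
                    tmrca = tmrca_years %||% 0))
      }
      # Kingman coalescent: heights of internal nodes
      active <- seq_len(n)
      height <- setNames(rep(0, n), active)
      edges <- list()
      next_node <- n + 1L
      h <- 0
      k <- n
      while (k > 1L) {
        h <- h + rexp(1, rate = choose(k, 2) / ne_years)
        pair <- sample(active, 2L)
        node <- next_node; next_node <- next_node + 1L
        for (ch in pair) {
          edges[[length(edges) + 1L]] <-
            tibble(parent = node, child = ch, years = h - height[[as.character(ch)]])
        }
        active <- c(setdiff(active, pair), node)
        height[[as.character(node)]] <- h
        k <- k - 1L
      }
      edges <- bind_rows(edges)
      root <- active
      edges$parent[edges$parent == root] <- 0L
      if (!is.null(tmrca_years) && h > 0) {
        edges$years <- edges$years * tmrca_years / h
        h <- tmrca_years
      }
      list(edges = edges, tmrca = h)
    }
  }
  res <- if (is.null(seed)) run() else with_preserved_rng(seed, run())
  structure(list(edges = res$edges, n = n, model = model,
                 tmrca_years = res$tmrca, seed = seed),
            class = "genealogy")
}

#' Total branch length of a genealogy (years)
#' @param g A `genealogy`.
#' @return Numeric.
#' @export
total_branch_length <- function(g) sum(g$edges$years)

#' Root-to-tip depths of a genealogy
#' @param g A `genealogy`.
#' @return Named numeric vector over tips.
#' @export
tip_depths <- function(g) {
  depth_of <- function(node) {
    d <- 0
    while (node != 0L) {
      k <- match(node, g$edges$child)
      d <- d + g$edges$years[k]
      node <- g$edges$parent[k]
    }
    d
  }
  setNames(vapply(seq_len(g$n), depth_of, 0), paste0("tip", seq_len(g$n)))
}

#' Drop Poisson mutations onto a genealogy
#'
#' Per-branch mutation counts are Poisson(rate x branch years); sites are
#' drawn from the spectrum, never twice within a lineage; the same site may
#' recur across lineages unless `perfect = TRUE`. Derived states are
#' transitions of the reference base with probability ts_tv/(ts_tv+1),
#' transversions otherwise.
#'
#' @param g A `genealogy`.
#' @param rate Mutations per molecule per year (over the spectrum's sites).
#' @param spectrum [mutation_spectrum()].
#' @param reference Full-length reference (default [synthetic_reference()]).
#' @param root_variants Basal motif carried by the root (variant tibble or
#'   motif string).
#' @param perfect Force a perfect phylogeny (each site used at most once in
#'   the whole tree).
#' @param seed Optional integer seed.
#' @param ids Tip identifiers (default `tip1..tipn`).
#' @return List: `haplotypes` (haplotype tibble with ranges set to the
#'   spectrum window), `events` (tibble `parent`, `child`, `tokens`
#'   list-column: the true mutation-labelled tree), `genealogy`.
#' @export
sprinkle_mutations <- function(g, rate, spectrum = mutation_spectrum(),
                               reference = synthetic_reference(),
                               root_variants = empty_variants(),
                               perfect = FALSE, seed = NULL, ids = NULL) {
  stopifnot(inherits(g, "genealogy"), rate >= 0)
  if (is.character(root_variants)) root_variants <- parse_motif(root_variants)
  ts_tv <- attr(spectrum, "ts_tv") %||% 22
  rng <- attr(spectrum, "range") %||% range(spectrum$position)
  ids <- ids %||% paste0("tip", seq_len(g$n))
  stopifnot(length(ids) == g$n)

  run <- function() {
    used_global <- integer(0)
    # children-of lists for a root-down walk
    kids <- split(seq_len(nrow(g$edges)), g$edges$parent)
    edge_tokens <- vector("list", nrow(g$edges))
    draw_edge <- function(edge_i, path_positions) {
      m <- rpois(1L, rate * g$edges$years[edge_i])
      tokens <- character(0)
      taken <- path_positions
      for (j in seq_len(m)) {
        banned <- if (perfect) c(taken, used_global) else taken
        ok <- which(!spectrum$position %in% banned)
        if (!length(ok)) break
        p <- spectrum$position[ok[sample.int(length(ok), 1L,
                                             prob = spectrum$weight[ok])]]
        ref <- reference[p]
        derived <- if (runif(1) < ts_tv / (ts_tv + 1)) {
          .transition_partner[[ref]]
        } else {
          sample(setdiff(c("A", "C", "G", "T"),
                         c(ref, .transition_partner[[ref]])), 1L)
        }
        tokens <- c(tokens, paste0(ref, p, derived))
        taken <- c(taken, p)
        used_global <<- c(used_global, p)
      }
      tokens
    }
    walk <- function(node, path_positions) {
      for (edge_i in kids[[as.character(node)]]) {
        tokens <- draw_edge(edge_i, path_positions)
        edge_tokens[[edge_i]] <<- tokens
        walk(g$edges$child[edge_i],
             c(path_positions, token_position(tokens)))
      }
    }
    walk(0L, token_position(present_tokens(root_variants)))
    edge_tokens
  }
  edge_tokens <- if (is.null(seed)) run() else with_preserved_rng(seed, run())

  # accumulate per-tip variant sets
  root_tokens <- present_tokens(root_variants)
  tip_tokens <- function(tip) {
    node <- tip
    acc <- character(0)
    while (node != 0L) {
      k <- match(node, g$edges$child)
      acc <- c(acc, edge_tokens[[k]])
      node <- g$edges$parent[k]
    }
    c(root_tokens, acc)
  }
  range_str <- sprintf("%d-%d", rng[1], rng[2])
  # widen the range to cover the root motif if it falls outside the window
  root_pos <- token_position(root_tokens)
  ranges <- range_str
  if (length(root_pos) && any(root_pos < rng[1] | root_pos > rng[2])) {
    ranges <- paste(c(range_str, sprintf("%d-%d", min(root_pos), max(root_pos))),
                    collapse = ";")
  }
  haps <- bind_rows(lapply(seq_len(g$n), function(i) {
    tokens <- tip_tokens(i)
    haplotype(ids[i],
              variants = if (length(tokens)) {
                bind_rows(lapply(sort_tokens(tokens), parse_variant,
                                 ref_check = "none"))
              } else empty_variants(),
              ranges = ranges, population = "sim", group = "unknown",
              source = "sprinkle_mutations")
  }))
  list(
    haplotypes = haps,
    events = tibble(parent = g$edges$parent, child = g$edges$child,
                    tokens = edge_tokens),
    genealogy = g
  )
}

#' Simulate a mixed haplotype database with known haplogroup truth
#'
#' Draws records from a planted haplogroup composition: each record carries
#' the cumulative motif of its haplogroup plus Poisson private mutations at
#' non-diagnostic sites. Counts per haplogroup are fixed by largest-remainder
#' rounding so the planted composition is recovered exactly at private rate
#' zero.
#'
#' @param n Number of records.
#' @param composition Named numeric: haplogroup name -> fraction (sums to 1).
#' @param tree A `haplogroup_tree` containing every named node.
#' @param private_rate Mean private (non-diagnostic) mutations per record.
#' @param spectrum Spectrum for private mutations; tree diagnostic positions
#'   and hotspots are excluded automatically.
#' @param reference Full-length reference for private-site tokens.
#' @param group,population Labels stamped on records.
#' @param seed Optional integer seed.
#' @return Haplotype tibble with an extra `true_haplogroup` column.
#' @export
simulate_database <- function(n, composition, tree = mini_haplogroup_tree(),
                              private_rate = 0,
                              spectrum = NULL,
                              reference = synthetic_reference(),
                              group = "romani", population = "sim",
                              seed = NULL) {
  stopifnot(abs(sum(composition) - 1) < 1e-9, all(composition >= 0))
  for (nm in names(composition)) assert_node(tree, nm)
  motifs <- all_motifs(tree)
  diag_pos <- unique(unlist(map(tree$diagnostics, "position")))
  if (is.null(spectrum)) {
    spectrum <- mutation_spectrum("whole", include_hotspots = FALSE,
                                  exclude_positions = diag_pos)
  }
  # largest-remainder apportionment of n records over the composition
  raw <- n * composition
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(names(composition), times = counts)

  run <- function() {
    bind_rows(lapply(seq_along(labels), function(i) {
      hg <- labels[i]
      v <- motifs[[hg]]
      m <- if (private_rate > 0) rpois(1L, private_rate) else 0L
      if (m > 0L) {
        ok <- which(!spectrum$position %in% v$position)
        pos <- spectrum$position[ok[sample.int(length(ok), m,
                                               prob = spectrum$weight[ok])]]
        priv <- bind_rows(lapply(pos, function(p) {
          ref <- reference[p]
          parse_variant(paste0(ref, p, .transition_partner[[ref]]),
                        ref_check = "none")
        }))
        v <- bind_rows(v, priv)
      }
      v <- v[order(v$position, v$token), ]
      rec <- haplotype(sprintf("sim%04d", i), variants = v,
                       ranges = sprintf("1-%d", RCRS_LENGTH),
                       population = population, group = group,
                       source = "simulate_database")
      rec$true_haplogroup <- hg
      rec
    }))
  }
  if (is.null(seed)) run() else with_preserved_rng(seed, run())
}

#' Founder-age parameter-recovery experiment
#'
#' Simulates star founder expansions with a known TMRCA, drops mutations at
#' the clock's countable rate (hotspots excluded from the site spectrum so
#' the simulated process matches what the dating pipeline counts), rebuilds
#' each clade tree and re-estimates its age. Used to check that rho is an
#' unbiased estimator of the expected per-lineage mutation count and that
#' the 95% CI covers the true TMRCA at close to nominal rate.
#'
#' @param reps Number of replicate clades.
#' @param n Tips per clade.
#' @param mu_t Expected mutations per lineage (rate x TMRCA).
#' @param clock [clock_model()] used both to set the true TMRCA
#'   (`clock_convert(clock, mu_t)`) and to convert the estimates back.
#' @param seed Integer seed for the whole experiment.
#' @return Tibble, one row per replicate: `rho`, `sigma`, `t_hat`,
#'   `ci_lower`, `ci_upper`, `covered` (true TMRCA inside the CI), with the
#'   true values as attributes `tmrca_years` and `mu_t`.
#' @export
simulate_founder_recovery <- function(reps = 500, n = 20, mu_t = 2,
                                      clock = clock_model(), seed = 1L) {
  tmrca <- clock_convert(clock, mu_t)
  rate <- mu_t / tmrca
  spectrum <- mutation_spectrum("whole", include_hotspots = FALSE)
  run <- function() {
    bind_rows(lapply(seq_len(reps), function(r) {
      g <- simulate_genealogy(n, "star", tmrca_years = tmrca)
      sm <- sprinkle_mutations(g, rate = rate, spectrum = spectrum)
      t <- build_tree(sm$haplotypes)
      est <- estimate_age(t, clock)
      tibble(rep = r, rho = est$rho, sigma = est$sigma,
             t_hat = est$t_years,
             ci_lower = unname(est$ci95[1]), ci_upper = unname(est$ci95[2]),
             covered = est$ci95[1] <= tmrca && tmrca <= est$ci95[2])
    }))
  }
  out <- with_preserved_rng(seed, run())
  attr(out, "tmrca_years") <- tmrca
  attr(out, "mu_t") <- mu_t
  out
}
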