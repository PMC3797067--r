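# Shared fixture builders. Everything is generated in code; positions used
# for anonymous private mutations (16025..16060) avoid the curated catalog
# so bare-dialect tokens never collide with a known reference base.

# haplotype db from a list of motif strings (names become ids)
db_from_motifs <- function(motifs, ranges = "16024-16400", group = "unknown") {
  ids <- names(motifs) %||% paste0("h", seq_along(motifs))
  dplyr::bind_rows(lapply(seq_along(motifs), function(i) {
    haplotype(ids[i], motifs[[i]], ranges = ranges, group = group)
  }))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# star clade: n tips, each with one private mutation at a distinct
# catalog-free position
star_private_db <- function(n, start_pos = 16025L) {
  stopifnot(n <= 36L)
  db_from_motifs(setNames(
    sprintf("%dT", start_pos + seq_len(n)),
    paste0("s", seq_len(n))
  ))
}

# the six-genome founder-clade configuration: five records identical to the
# basal motif, one with a single extra transition
founder_six_db <- function(basal = "A16343G", extra = "T16356C") {
  motifs <- c(rep(basal, 5), paste(basal, extra, sep = "-"))
  db_from_motifs(setNames(motifs, paste0("u", 1:6)))
}

# random small instance drawn through the generator, kept within the
# enumeration-oracle guard; returns NULL if the draw exceeds the guard
oracle_instance <- function(seed, n_range = 4:7, ne_years = 800,
                            rate = 1.5e-3) {
  n <- n_range[1 + (seed %% length(n_range))]
  g <- simulate_genealogy(n, "coalescent", ne_years = ne_years, seed = seed)
  sp <- mutation_spectrum("hvs1", include_hotspots = FALSE, ts_tv = 1e9)
  sm <- sprinkle_mutations(g, rate = rate, spectrum = sp, seed = seed + 13L)
  sites <- length(unique(unlist(lapply(sm$haplotypes$variants,
                                       function(v) v$position))))
  if (sites > 12L || nrow(sm$haplotypes) > 7L) return(NULL)
  sm$haplotypes
}

# write a haplotype table fixture to a temp file
write_fixture_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("id\tpopulation\tgroup\trange\tvariants", lines), path)
  path
}
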