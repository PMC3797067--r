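# File-level pipeline wrappers.
#
# Thin, deterministic wrappers wiring the analysis stages together for
# scripted runs: read inputs, run the stage, write TSV reports plus a run
# log (package version, seed, config hash). The R functions themselves are
# the interface; each returns its result tibble invisibly.

#' Pipeline run configuration
#'
#' @param input Haplotype table path (TSV dialect of
#'   [read_haplotype_table()]).
#' @param tree Haplogroup tree file path (`NULL` = packaged mini-tree).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for any stochastic stage.
#' @param clock_years_per_sub Linear clock rate for dating.
#' @param ref_check Reference-base validation mode for input parsing.
#' @param ... Rejected: unknown keys error.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, tree = NULL,
                            out_dir = "mitofounder-out", seed = 1L,
                            clock_years_per_sub = 3624,
                            ref_check = "warn", ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s",
                  paste(names(extra), collapse = ", ")))
  }
  structure(list(input = input, tree = tree, out_dir = out_dir,
                 seed = as.integer(seed),
                 clock_years_per_sub = clock_years_per_sub,
                 ref_check = ref_check),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file with the keys of [pipeline_config()].
#' @param ... Overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

cfg_tree <- function(cfg) {
  if (is.null(cfg$tree)) mini_haplogroup_tree() else load_haplogroup_tree(cfg$tree)
}

cfg_db <- function(cfg) {
  if (is.null(cfg$input)) abort("config has no 'input' haplotype table")
  if (!file.exists(cfg$input)) abort(sprintf("input '%s' not found", cfg$input))
  read_haplotype_table(cfg$input, ref_check = cfg$ref_check)
}

write_run_log <- function(cfg, stage) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, paste0(stage, ".log"))
  writeLines(c(
    sprintf("stage: %s", stage),
    sprintf("mitofounder: %s", as.character(utils::packageVersion("mitofounder"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_hash: %s", rlang::hash(unclass(cfg))),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), log_path)
  invisible(log_path)
}

#' Classify a haplotype table and write the assignment report
#' @param cfg A [pipeline_config()].
#' @return Assignment tibble, invisibly.
#' @export
run_classify <- function(cfg) {
  db <- cfg_db(cfg)
  asg <- classify_db(db, cfg_tree(cfg))
  write_run_log(cfg, "classify")
  write_report(asg, file.path(cfg$out_dir, "assignments.tsv"))
  invisible(asg)
}

#' Date clades from a haplotype table and write the dating report
#' @param cfg A [pipeline_config()].
#' @param clades Named list: clade -> list(members, root); see
#'   [date_clades()].
#' @param override_scope Passed through to [estimate_age()].
#' @return Dating tibble, invisibly.
#' @export
run_date <- function(cfg, clades, override_scope = FALSE) {
  db <- cfg_db(cfg)
  clock <- clock_model(years_per_sub = cfg$clock_years_per_sub)
  rep <- date_clades(db, clades, clock = clock,
                     override_scope = override_scope)
  write_run_log(cfg, "date")
  write_report(rep, file.path(cfg$out_dir, "dating.tsv"))
  invisible(rep)
}

#' Summarise a haplotype table: frequencies, ancestry partition, diversity
#' @param cfg A [pipeline_config()].
#' @param basal_motif Basal motif for the diversity report (default rCRS).
#' @return List of the three tibbles, invisibly.
#' @export
run_summarize <- function(cfg, basal_motif = "") {
  db <- cfg_db(cfg)
  tree <- cfg_tree(cfg)
  asg <- classify_db(db, tree)
  freq <- frequency_table(db, asg, tree)
  adm <- ancestry_partition(asg, tree)
  div <- diversity_summary(db, basal_motif)
  write_run_log(cfg, "summarize")
  write_report(freq, file.path(cfg$out_dir, "frequency.tsv"))
  write_report(adm, file.path(cfg$out_dir, "admixture.tsv"))
  write_report(div, file.path(cfg$out_dir, "diversity.tsv"))
  invisible(list(frequency = freq, admixture = adm, diversity = div))
}

#' Motif search over a haplotype table, writing hit reports
#' @param cfg A [pipeline_config()].
#' @param motif Motif string or variant tibble.
#' @param exclude Clade names to disregard.
#' @return [search_motif()] result, invisibly.
#' @export
run_search <- function(cfg, motif, exclude = character()) {
  db <- cfg_db(cfg)
  res <- search_motif(db, motif, exclude = exclude, tree = cfg_tree(cfg))
  write_run_log(cfg, "search")
  write_haplotype_table(res$hits, file.path(cfg$out_dir, "hits.tsv"))
  write_report(
    tibble(id = res$not_evaluable$id, reason = res$not_evaluable$reason),
    file.path(cfg$out_dir, "not_evaluable.tsv"))
  invisible(res)
}

#' Simulate a database to disk (records + truth table)
#' @param cfg A [pipeline_config()].
#' @param n Number of records.
#' @param composition Named haplogroup fractions.
#' @param private_rate Mean private mutations per record.
#' @return Simulated haplotype tibble, invisibly.
#' @export
run_simulate <- function(cfg, n, composition, private_rate = 0) {
  db <- simulate_database(n, composition, tree = cfg_tree(cfg),
                          private_rate = private_rate, seed = cfg$seed)
  write_run_log(cfg, "simulate")
  write_haplotype_table(db, file.path(cfg$out_dir, "simulated.tsv"))
  write_report(tibble(id = db$id, true_haplogroup = db$true_haplogroup),
               file.path(cfg$out_dir, "truth.tsv"))
  invisible(db)
}
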