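# Rho-statistic founder dating.
#
# rho is the average number of mutations separating each sampled haplotype
# in a clade from the clade's root haplotype; on the branch table it is
# (1/n) sum_b m_b n_b over branches with m_b mutations and n_b descendant
# samples. Its heuristic standard error from the genealogy estimate is
# sigma = sqrt( (1/n^2) sum_b m_b n_b^2 ). Mutational distances are
# converted into years through a molecular-clock model; the default
# whole-molecule corrected rate is one substitution per 3,624 years
# (hotspots masked), and any monotone substitutions-to-years mapping can be
# plugged in for time-dependent corrections.

#' Molecular clock model
#'
#' @param id Clock identifier.
#' @param years_per_sub Linear rate (years per substitution) used when no
#'   `convert` mapping is supplied.
#' @param scope `"whole_molecule"` or `"control_region"` — the data range
#'   the rate was calibrated on.
#' @param convert Optional function mapping expected substitutions to years;
#'   must be non-negative, non-decreasing, with `convert(0) == 0`.
#' @return A `clock_model`.
#' @export
#' @examples
#' clock_model()  # whole-molecule corrected rate, 3624 yr/substitution
clock_model <- function(id = "corrected_whole_molecule",
                        years_per_sub = 3624,
                        scope = c("whole_molecule", "control_region"),
                        convert = NULL) {
  scope <- match.arg(scope)
  if (is.null(convert)) {
    stopifnot(years_per_sub > 0)
    convert <- function(subs) subs * years_per_sub
    kind <- "linear"
  } else {
    kind <- "custom"
    probe <- seq(0, 50, length.out = 101)
    vals <- vapply(probe, convert, 0)
    if (vals[1] != 0 || any(vals < 0) || any(diff(vals) < 0)) {
      abort("'convert' must be non-negative, non-decreasing, with convert(0) = 0")
    }
  }
  structure(list(id = id, kind = kind, years_per_sub = years_per_sub,
                 scope = scope, convert = convert),
            class = "clock_model")
}

#' Clock conversion of a mutational distance
#' @param clock A [clock_model()].
#' @param subs Substitution count(s).
#' @return Years.
#' @export
clock_convert <- function(clock, subs) {
  stopifnot(inherits(clock, "clock_model"))
  vapply(subs, clock$convert, 0)
}

#' The rho statistic of a clade tree
#'
#' Mean number of mutations from each sampled haplotype to the clade root:
#' `(1/n) * sum_b m_b * n_b`, identical to the direct average of per-tip
#' path mutation counts.
#'
#' @param t A `parsimony_tree` (see [build_tree()]).
#' @return Non-negative numeric.
#' @export
rho <- function(t) {
  stopifnot(inherits(t, "parsimony_tree"))
  if (t$n < 1L) abort("empty tree")
  m <- lengths(t$branches$mutations)
  sum(m * t$branches$n_tips_below) / t$n
}

#' Heuristic standard error of rho
#'
#' The genealogy-based estimator `sqrt( (1/n^2) * sum_b m_b * n_b^2 )`.
#'
#' @param t A `parsimony_tree`.
#' @return Non-negative numeric.
#' @export
sigma_rho <- function(t) {
  stopifnot(inherits(t, "parsimony_tree"))
  if (t$n < 1L) abort("empty tree")
  m <- lengths(t$branches$mutations)
  sqrt(sum(m * t$branches$n_tips_below^2)) / t$n
}

#' Founder age estimate for a clade
#'
#' Converts rho through the clock; the 95% CI converts `rho +/- 1.96 sigma`,
#' truncated at zero.
#'
#' @param t A `parsimony_tree`.
#' @param clock A [clock_model()].
#' @param clade Optional clade label carried into reports.
#' @param override_scope Allow clock scope and data scope to differ.
#' @return An `age_estimate`: list with `clade`, `rho`, `sigma`, `n`,
#'   `clock_id`, `t_years`, `ci95`.
#' @export
estimate_age <- function(t, clock = clock_model(), clade = NA_character_,
                         override_scope = FALSE) {
  stopifnot(inherits(t, "parsimony_tree"), inherits(clock, "clock_model"))
  if (!override_scope && !identical(t$scope, clock$scope)) {
    abort(sprintf(
      "data scope '%s' does not match clock scope '%s' (use override_scope = TRUE to force)",
      t$scope, clock$scope))
  }
  r <- rho(t)
  s <- sigma_rho(t)
  est <- structure(
    list(clade = clade, rho = r, sigma = s, n = t$n, clock_id = clock$id,
         t_years = clock_convert(clock, r),
         ci95 = c(lower = clock_convert(clock, max(r - 1.96 * s, 0)),
                  upper = clock_convert(clock, r + 1.96 * s))),
    class = "age_estimate"
  )
  est
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf(
    "<age_estimate%s: n = %d, rho = %.4g, sigma = %.4g, %s -> %.0f yr (95%% CI %.0f-%.0f)>\n",
    if (is.na(x$clade)) "" else paste0(" ", x$clade),
    x$n, x$rho, x$sigma, x$clock_id, x$t_years, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @rdname estimate_age
#' @param x An `age_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.age_estimate <- function(x, ...) {
  tibble(clade = x$clade, n = x$n, rho = x$rho, sigma = x$sigma,
         clock = x$clock_id, t_years = x$t_years,
         ci_lower = unname(x$ci95[1]), ci_upper = unname(x$ci95[2]))
}

#' @rdname estimate_age
#' @exportS3Method generics::glance
glance.age_estimate <- function(x, ...) tidy(x)

#' Dating report over named clades
#'
#' Builds one rooted tree per clade from its member records and estimates
#' founder ages; the tabular equivalent of a per-clade dating run.
#'
#' @param db Haplotype tibble.
#' @param clades Named list: clade label -> list(members = ids, root =
#'   motif string or variant tibble).
#' @param clock A [clock_model()].
#' @param policy [hotspot_policy()].
#' @param override_scope Passed to [estimate_age()].
#' @return Tibble with one row per clade (the [tidy()] of each estimate).
#' @export
date_clades <- function(db, clades, clock = clock_model(),
                        policy = hotspot_policy(), override_scope = FALSE) {
  stopifnot(length(names(clades)) == length(clades))
  bind_rows(imap(clades, function(spec, label) {
    members <- db[db$id %in% spec$members, , drop = FALSE]
    if (nrow(members) == 0L) abort(sprintf("clade '%s' has no members", label))
    t <- build_tree(members, root_variants = spec$root %||% empty_variants(),
                    policy = policy)
    tidy(estimate_age(t, clock, clade = label,
                      override_scope = override_scope))
  }))
}
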