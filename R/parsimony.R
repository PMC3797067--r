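# Rooted maximum-parsimony haplotype trees.
#
# Construction is rooted at a designated basal motif. Each haplotype is
# reduced to its variant set relative to the root (tokens gained, plus
# "@token" for root variants lost, i.e. back mutations relative to the basal
# motif); identical haplotypes collapse into one tip with a multiplicity.
# The tree is grown by recursive partition: at each node a candidate child
# clade is the carrier class of some variant; the clade's branch takes every
# variant shared by all its members, and the remainder recurses. Small
# instances search all candidate clades exhaustively (minimising total
# events); larger ones fall back to a greedy rule: split on the
# most-carried variant, preferring on ties to keep the less mutable site
# intact (so the event duplicated by a four-gamete conflict lands on the
# more mutable site, then on the one with fewer carriers). Compatible site
# patterns yield the perfect phylogeny exactly under either mode. An exact
# Steiner enumeration oracle (brute_force_min) guards the construction in
# the test-suite.

#' Build a rooted maximum-parsimony tree for a set of haplotypes
#'
#' @param haps Haplotype tibble.
#' @param root_variants Basal motif of the clade (variant tibble or motif
#'   string; empty = rCRS).
#' @param policy [hotspot_policy()]; in the default lenient mode hotspot
#'   variants are masked on the way in.
#' @param strict Error (rather than mask) when a haplotype still carries an
#'   unmasked hotspot variant.
#' @param mutability Optional named numeric vector (position -> relative
#'   mutability) used to break splitting ties; defaults to the package
#'   spectrum weights.
#' @return A `parsimony_tree`: list with `branches` (tibble `branch`,
#'   `parent`, `child`, `mutations` list-column of relative tokens,
#'   `n_tips_below`), `tips` (tibble `node`, `ids` list-column,
#'   `multiplicity`), `root_variants`, `n` (multiplicity-weighted sample
#'   size) and `scope`.
#' @export
#' @examples
#' db <- dplyr::bind_rows(
#'   haplotype("a", "A16343G"), haplotype("b", "A16343G"),
#'   haplotype("c", "A16343G-T16356C")
#' )
#' build_tree(db, root_variants = "A16343G")
build_tree <- function(haps, root_variants = empty_variants(),
                       policy = hotspot_policy(), strict = FALSE,
                       mutability = NULL) {
  if (nrow(haps) == 0L) abort("no haplotypes to build a tree from")
  if (is.character(root_variants)) root_variants <- parse_motif(root_variants)
  if (strict) {
    for (i in seq_len(nrow(haps))) {
      masked <- mask_hotspots(haps$variants[[i]], policy)
      if (nrow(masked) != nrow(haps$variants[[i]])) {
        abort(sprintf("record '%s' carries unmasked hotspot variant(s)",
                      haps$id[i]))
      }
    }
  } else {
    haps <- mask_db(haps, policy)
  }
  root_set <- present_tokens(mask_hotspots(root_variants, policy))
  rel <- map(haps$variants, function(v) relative_set(present_tokens(v), root_set))
  key <- map_chr(rel, function(s) paste(sort(s), collapse = "|"))
  groups <- lapply(split(seq_along(key), key), function(idx) {
    list(set = rel[[idx[1]]], ids = haps$id[idx], mult = length(idx))
  })
  groups <- unname(groups)
  if (is.null(mutability)) mutability <- default_mutability()

  nonempty <- keep(groups, function(g) length(g$set) > 0L)
  exact <- length(nonempty) <= 8L &&
    length(unique(unlist(map(nonempty, "set")))) <= 14L

  env <- new.env(parent = emptyenv())
  env$branches <- list()
  env$tips <- list()
  env$next_node <- 1L

  build_rec(groups, parent = 0L, env = env, mutability = mutability,
            exact = exact)

  branches <- bind_rows(env$branches)
  if (nrow(branches) == 0L) {
    branches <- tibble(parent = integer(), child = integer(),
                       mutations = list())
  }
  tips <- bind_rows(env$tips)
  branches$n_tips_below <- vapply(branches$child, function(nd) {
    sum(tips$multiplicity[vapply(tips$node, is_descendant, TRUE,
                                 ancestor = nd, branches = branches)])
  }, 1L)
  tree <- structure(
    list(branches = order_branches(branches, tips),
         tips = tips,
         root_variants = root_variants,
         n = sum(tips$multiplicity),
         scope = infer_scope(haps)),
    class = "parsimony_tree"
  )
  tree
}

relative_set <- function(present, root_set) {
  c(setdiff(present, root_set),
    paste0("@", setdiff(root_set, present), recycle0 = TRUE))
}

is_descendant <- function(node, ancestor, branches) {
  while (node != 0L) {
    if (node == ancestor) return(TRUE)
    node <- branches$parent[match(node, branches$child)]
  }
  ancestor == 0L
}

# position of a relative token ("@C16223T", "315+C", "16166d", "C16223T")
token_position <- function(token) {
  as.integer(str_match(token, "(\\d+)")[, 2])
}

default_mutability <- function() {
  sp <- mutation_spectrum()
  setNames(sp$weight, sp$position)
}

build_rec <- function(groups, parent, env, mutability, exact) {
  # haplotypes whose remaining set is empty are tips sitting at this node
  done <- map_lgl(groups, function(g) length(g$set) == 0L)
  for (g in groups[done]) {
    env$tips[[length(env$tips) + 1L]] <-
      tibble(node = parent, ids = list(sort(g$ids)), multiplicity = g$mult)
  }
  memo <- new.env(parent = emptyenv())
  plan <- plan_forest(groups[!done], mutability, exact, memo)
  emit_plan(plan$children, parent, env)
}

emit_plan <- function(children, parent, env) {
  for (ch in children) {
    node <- env$next_node; env$next_node <- env$next_node + 1L
    env$branches[[length(env$branches) + 1L]] <-
      tibble(parent = parent, child = node,
             mutations = list(sort_tokens(ch$shared)))
    for (g in ch$tips) {
      env$tips[[length(env$tips) + 1L]] <-
        tibble(node = node, ids = list(sort(g$ids)), multiplicity = g$mult)
    }
    emit_plan(ch$children, node, env)
  }
}

# Candidate clades at a node are carrier classes of the remaining variants,
# ordered by multiplicity-weighted carrier count (ties: less mutable site
# first, then token order). In exact mode every candidate is tried and the
# cheapest forest kept; in greedy mode only the first.
plan_forest <- function(groups, mutability, exact, memo) {
  if (!length(groups)) return(list(cost = 0L, children = list()))
  key <- paste(sort(vapply(groups, function(g) {
    paste(c(sort(g$set), "#", sort(g$ids), g$mult), collapse = "~")
  }, "")), collapse = "||")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  tokens <- unique(unlist(map(groups, "set")))
  carriers <- vapply(tokens, function(t) {
    sum(vapply(groups, function(g) if (t %in% g$set) g$mult else 0L, 0L))
  }, 0L)
  weight <- mutability[as.character(token_position(tokens))]
  weight[is.na(weight)] <- 0
  tokens <- tokens[order(-carriers, weight, tokens)]
  # distinct carrier classes, in token preference order
  classes <- list()
  seen <- character()
  for (v in tokens) {
    members <- which(map_lgl(groups, function(g) v %in% g$set))
    ckey <- paste(members, collapse = ",")
    if (!ckey %in% seen) {
      seen <- c(seen, ckey)
      classes[[length(classes) + 1L]] <- members
    }
  }
  if (!exact) classes <- classes[1]
  best <- NULL
  for (members in classes) {
    clade <- groups[members]
    shared <- Reduce(intersect, map(clade, "set"))
    clade <- lapply(clade, function(g) {
      g$set <- setdiff(g$set, shared); g
    })
    tips_here <- keep(clade, function(g) length(g$set) == 0L)
    below <- plan_forest(keep(clade, function(g) length(g$set) > 0L),
                         mutability, exact, memo)
    rest <- plan_forest(groups[-members], mutability, exact, memo)
    cost <- length(shared) + below$cost + rest$cost
    if (is.null(best) || cost < best$cost) {
      best <- list(
        cost = cost,
        children = c(list(list(shared = shared, tips = tips_here,
                               children = below$children)),
                     rest$children)
      )
    }
  }
  memo[[key]] <- best
  best
}

sort_tokens <- function(tokens) {
  tokens[order(token_position(tokens), tokens)]
}

# Deterministic output: depth-first renumbering with children ordered by
# (first mutation position, first tip id).
order_branches <- function(branches, tips) {
  first_pos <- vapply(branches$mutations, function(m) {
    if (length(m)) min(token_position(m)) else -1L
  }, 1L)
  first_tip <- vapply(branches$child, function(nd) {
    below <- tips$node[vapply(tips$node, is_descendant, TRUE,
                              ancestor = nd, branches = branches)]
    min(unlist(tips$ids[tips$node %in% below]))
  }, "")
  ord <- integer(0)
  visit <- function(parent) {
    kids <- which(branches$parent == parent)
    kids <- kids[order(first_pos[kids], first_tip[kids])]
    for (k in kids) {
      ord <<- c(ord, k)
      visit(branches$child[k])
    }
  }
  visit(0L)
  out <- branches[ord, , drop = FALSE]
  out$branch <- seq_len(nrow(out))
  out[, c("branch", "parent", "child", "mutations", "n_tips_below")]
}

infer_scope <- function(haps) {
  spans <- map_dbl(haps$ranges, function(r) sum(r$end - r$start + 1L))
  if (all(spans >= 15000)) "whole_molecule" else "control_region"
}

#' Parsimony tree length
#' @param t A `parsimony_tree`.
#' @return Total number of mutation events (sum of branch mutation counts).
#' @export
tree_length <- function(t) {
  stopifnot(inherits(t, "parsimony_tree"))
  sum(lengths(t$branches$mutations))
}

#' Recurrent mutations in a tree
#'
#' Positions whose mutation events occur on more than one branch (back
#' mutations count as events).
#'
#' @param t A `parsimony_tree`.
#' @return Tibble `position`, `events`, sorted by position.
#' @export
annotate_recurrence <- function(t) {
  pos <- token_position(unlist(t$branches$mutations))
  if (!length(pos)) return(tibble(position = integer(), events = integer()))
  tab <- table(pos)
  rec <- tab[tab > 1L]
  tibble(position = as.integer(names(rec)), events = as.integer(rec))
}

#' Flat branch table of a parsimony tree
#'
#' The dating substrate: one row per branch with its mutation count and the
#' number of sampled haplotypes below it.
#'
#' @param t A `parsimony_tree`.
#' @return Tibble `branch`, `parent`, `child`, `mutations` (dash-joined
#'   tokens), `m` (mutation count), `n_tips_below`.
#' @export
branch_table <- function(t) {
  stopifnot(inherits(t, "parsimony_tree"))
  tibble(
    branch = t$branches$branch, parent = t$branches$parent,
    child = t$branches$child,
    mutations = map_chr(t$branches$mutations, paste, collapse = "-"),
    m = lengths(t$branches$mutations),
    n_tips_below = t$branches$n_tips_below
  )
}

# Root-to-tip reconstruction: the relative token multiset accumulated along
# the path to each tip (used by the type-invariant tests and rho oracle).
reconstruct_tips <- function(t) {
  b <- t$branches
  out <- setNames(vector("list", nrow(t$tips)),
                  vapply(t$tips$ids, `[[`, "", 1))
  for (i in seq_len(nrow(t$tips))) {
    node <- t$tips$node[i]
    acc <- character()
    while (node != 0L) {
      k <- match(node, b$child)
      acc <- c(acc, b$mutations[[k]])
      node <- b$parent[k]
    }
    out[[i]] <- sort(acc)
  }
  out
}

#' Export a parsimony tree as Newick with branch mutation comments
#'
#' Branch lengths are mutation counts; each branch's mutation list rides in
#' a bracketed comment after the length.
#'
#' @param t A `parsimony_tree`.
#' @return Newick string.
#' @export
as_newick <- function(t) {
  b <- t$branches
  lab <- function(node) {
    i <- match(node, t$tips$node)
    if (!is.na(i)) {
      id <- t$tips$ids[[i]][1]
      if (t$tips$multiplicity[i] > 1L) {
        sprintf("%s_x%d", id, t$tips$multiplicity[i])
      } else id
    } else ""
  }
  render <- function(node) {
    kids <- which(b$parent == node)
    body <- if (length(kids)) {
      paste0("(", paste(vapply(kids, function(k) {
        muts <- b$mutations[[k]]
        cmt <- if (length(muts)) sprintf("[&mutations=%s]",
                                         paste(muts, collapse = "|")) else ""
        paste0(render(b$child[k]), ":", length(muts), cmt)
      }, ""), collapse = ","), ")")
    } else ""
    paste0(body, lab(node))
  }
  paste0(render(0L), "root;")
}

#' @export
print.parsimony_tree <- function(x, ...) {
  cat(sprintf("<parsimony_tree: n = %d haplotype(s), %d tip(s), length %d>\n",
              x$n, nrow(x$tips), tree_length(x)))
  invisible(x)
}
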