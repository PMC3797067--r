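# Diagnostic-variant haplogroup trees.
#
# File format: one node per line, depth given by leading tabs, then the node
# name, then space-separated diagnostic variant tokens (the mutations on the
# branch leading to the clade; back mutations allowed with '@'). Lines
# starting with '#' are comments; '#alias BAD GOOD' lines record token
# synonyms applied during loading (used e.g. where the literature prints two
# spellings of the same landmark variant). The root may carry no
# diagnostics, and scaffold nodes with untranscribed diagnostics may be
# empty.

#' Load a haplogroup tree from an indented text file
#'
#' @param path Tree file path.
#' @param version Version tag stored on the tree (default the file name).
#' @return A `haplogroup_tree`: list with `nodes` (tibble `name`, `parent`,
#'   `depth`), `diagnostics` (named list of variant tibbles), `aliases`
#'   (tibble `alias`, `canonical`) and `version`.
#' @export
load_haplogroup_tree <- function(path, version = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  aliases <- empty_alias_table()
  nodes <- list()
  stack <- character()   # names along the current root path, by depth
  for (ln in lines) {
    if (str_detect(ln, "^\\s*$")) next
    if (str_detect(str_trim(ln), "^#")) {
      m <- str_match(str_trim(ln), "^#alias\\s+(\\S+)\\s+(\\S+)\\s*$")
      if (!is.na(m[1, 1])) {
        aliases <- bind_rows(aliases, tibble(alias = m[1, 2],
                                             canonical = m[1, 3]))
      }
      next
    }
    depth <- nchar(str_match(ln, "^(\t*)")[1, 2])
    body <- str_trim(ln)
    fields <- str_split(body, "\\s+")[[1]]
    name <- fields[1]
    tokens <- fields[-1]
    tokens <- vapply(tokens, function(t) {
      hit <- match(t, aliases$alias)
      if (!is.na(hit)) aliases$canonical[hit] else t
    }, "")
    if (depth > length(stack)) {
      abort(sprintf("inconsistent indentation at node '%s'", name))
    }
    parent <- if (depth == 0L) NA_character_ else stack[depth]
    if (depth == 0L && length(nodes) > 0L) {
      abort("multiple root nodes in haplogroup tree file")
    }
    diagnostics <- if (length(tokens)) {
      bind_rows(lapply(tokens, parse_variant))
    } else {
      empty_variants()
    }
    nodes[[length(nodes) + 1L]] <-
      list(name = name, parent = parent, depth = depth,
           diagnostics = diagnostics)
    stack <- c(stack[seq_len(depth)], name)
  }
  if (!length(nodes)) abort(sprintf("no nodes in tree file '%s'", path))
  names_vec <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(names_vec)) {
    abort(sprintf("duplicate node name(s): %s",
                  paste(unique(names_vec[duplicated(names_vec)]),
                        collapse = ", ")))
  }
  tree <- structure(
    list(
      nodes = tibble(name = names_vec,
                     parent = vapply(nodes, `[[`, "", "parent"),
                     depth = vapply(nodes, function(n) as.integer(n$depth), 1L)),
      diagnostics = setNames(lapply(nodes, `[[`, "diagnostics"), names_vec),
      aliases = aliases,
      version = version
    ),
    class = "haplogroup_tree"
  )
  tree
}

empty_alias_table <- function() tibble(alias = character(), canonical = character())

#' The packaged mini haplogroup tree
#'
#' A simplified diagnostic-variant tree covering the clades analysed by the
#' package's worked examples (the M5a1b1a1 / M35b2a1 / M18 South Asian
#' branches, U3/U3b1c, the H5a2 / H24 / H88a West Eurasian branches, A2,
#' L2/L2c and M1/M1a1), with macro-haplogroup scaffolding. Not a full
#' phylogeny mirror: scaffold nodes whose defining variants are not
#' transcribed carry no diagnostics.
#'
#' @return A `haplogroup_tree`.
#' @export
mini_haplogroup_tree <- function() {
  load_haplogroup_tree(
    system.file("extdata", "haplogroups_mini.txt", package = "mitofounder",
                mustWork = TRUE),
    version = "mini-1"
  )
}

tree_root <- function(tree) tree$nodes$name[is.na(tree$nodes$parent)]

assert_node <- function(tree, name) {
  if (!name %in% tree$nodes$name) {
    abort(sprintf("unknown haplogroup '%s' (tree %s)", name, tree$version))
  }
  invisible(name)
}

#' Names along the path from the root to a node
#' @param tree A `haplogroup_tree`.
#' @param name Node name.
#' @return Character vector, root first.
#' @export
node_path <- function(tree, name) {
  assert_node(tree, name)
  parents <- setNames(tree$nodes$parent, tree$nodes$name)
  path <- name
  while (!is.na(parents[[path[1]]])) path <- c(parents[[path[1]]], path)
  path
}

#' Is a node inside a clade?
#' @param tree A `haplogroup_tree`.
#' @param name Node name.
#' @param clade Clade (ancestor) name.
#' @return Logical.
#' @export
is_under <- function(tree, name, clade) {
  assert_node(tree, clade)
  clade %in% node_path(tree, name)
}

#' Cumulative motif of a haplogroup
#'
#' Union of the diagnostic variants on the path from the root to the node. A
#' back mutation on a branch removes the earlier variant at that position;
#' a later substitution at an already-mutated position replaces it.
#'
#' @param tree A `haplogroup_tree`.
#' @param name Node name.
#' @return Variant tibble.
#' @export
#' @examples
#' cumulative_motif(mini_haplogroup_tree(), "M5a1b1a1")
cumulative_motif <- function(tree, name) {
  path <- node_path(tree, name)
  acc <- empty_variants()
  for (nd in path) {
    d <- tree$diagnostics[[nd]]
    for (i in seq_len(nrow(d))) {
      if (d$back_mutation[i]) {
        acc <- acc[acc$position != d$position[i], , drop = FALSE]
      } else {
        acc <- acc[!(acc$position == d$position[i] &
                       !acc$klass %in% "insertion"), , drop = FALSE]
        acc <- bind_rows(acc, d[i, ])
      }
    }
  }
  acc
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat(sprintf("<haplogroup_tree '%s': %d node(s), root '%s'>\n",
              x$version, nrow(x$nodes), tree_root(x)))
  invisible(x)
}

# Precompute cumulative motifs for every node (named list of variant tibbles).
all_motifs <- function(tree) {
  setNames(lapply(tree$nodes$name, cumulative_motif, tree = tree),
           tree$nodes$name)
}
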