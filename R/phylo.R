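# Faith's phylogenetic diversity on gene trees, averaged per guild.

#' Faith's phylogenetic diversity of a tip subset
#'
#' Sum of branch lengths of the minimal subtree spanning the tips; with
#' `include_root = TRUE` (the default of the reference implementation) the
#' path from the subtree to the root is included. A single tip has PD 0
#' without the root and its root-path length with it.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param tips character vector of tip labels (non-empty subset).
#' @param include_root include the path to the root.
#' @return non-negative scalar.
#' @export
faith_pd <- function(tree, tips, include_root = TRUE) {
  tree <- validate_tree(tree)
  tips <- unique(tips)
  if (!length(tips)) g_abort("tip set is empty", "bad_params")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) g_abort("unknown tip labels", "unknown_tip", tip = unknown)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_edge <- integer(max(tree$edge))  # node -> incoming edge row
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  marked <- logical(nrow(tree$edge))
  for (tip in match(tips, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      if (marked[e]) break
      marked[e] <- TRUE
      node <- tree$edge[e, 1L]
    }
  }
  pd <- sum(tree$edge.length[marked])
  if (!include_root) {
    # subtract the path from the tip set's MRCA up to the root
    mrca <- if (length(tips) == 1L) match(tips, tree$tip.label)
            else ape::getMRCA(tree, tips)
    node <- mrca
    while (node != root) {
      e <- parent_edge[node]
      pd <- pd - tree$edge.length[e]
      node <- tree$edge[e, 1L]
    }
  }
  pd
}

#' Per-guild phylogenetic diversity on one or more gene trees
#'
#' Computes Faith's PD of each guild's tip set on every supplied tree
#' (susC and susD trees are handled as separate trees) and averages per
#' guild across trees. Guilds with no tips on a tree are omitted with a
#' warning.
#'
#' @param trees a single `phylo` or a (possibly named) list of them.
#' @param tip_guild_map named vector tip label -> guild.
#' @param include_root passed to [faith_pd()].
#' @return a `pd_result`: list with `per_tree` (guild x tree table of PD
#'   and tip counts) and `per_guild` (mean PD across trees).
#' @export
guild_pd <- function(trees, tip_guild_map, include_root = TRUE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(names(trees))) names(trees) <- sprintf("tree%d", seq_along(trees))
  guilds <- sort(unique(as.character(tip_guild_map)))
  rows <- list()
  for (tn in names(trees)) {
    tr <- validate_tree(trees[[tn]])
    for (k in guilds) {
      tips <- intersect(names(tip_guild_map)[tip_guild_map == k], tr$tip.label)
      if (!length(tips)) {
        g_warn(paste0("guild '", k, "' has no tips on tree '", tn, "'; omitted"),
               "empty_guild")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tree = tn, guild = k, n_tips = length(tips),
        pd = faith_pd(tr, tips, include_root = include_root),
        stringsAsFactors = FALSE)
    }
  }
  per_tree <- do.call(rbind, rows)
  per_guild <- stats::aggregate(pd ~ guild, per_tree, mean)
  structure(list(per_tree = per_tree, per_guild = per_guild,
                 include_root = include_root),
            class = "pd_result")
}
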