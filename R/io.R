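#' Read a rooted tree with mandatory branch lengths
#'
#' Parses a Newick file (or string via `text =`), requiring a rooted tree
#' with a branch length on every edge; internal node labels are preserved as
#' node identifiers.
#'
#' @param path path to a Newick file.
#' @param text optional Newick string (overrides `path`).
#' @return an [ape::phylo] object.
#' @export
read_tree_file <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      stop("tree file not found: ", path, call. = FALSE)
    tree <- ape::read.tree(path)
  } else {
    tree <- ape::read.tree(text = text)
  }
  if (is.null(tree))
    stop("could not parse Newick input", call. = FALSE)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    miss <- if (!is.null(tree$edge.length)) {
      kids <- tree$edge[is.na(tree$edge.length), 2]
      paste(ifelse(kids <= length(tree$tip.label), tree$tip.label[kids],
                   paste0("node ", kids)), collapse = ", ")
    } else "all edges"
    stop("missing branch length(s) on: ", miss, call. = FALSE)
  }
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (binary root)", call. = FALSE)
  tree
}

#' Write a tree to Newick with full precision
#'
#' @param tree an [ape::phylo].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_file <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}

#' Read a node table CSV
#'
#' Reads the per-node summary table with mandatory header
#' `node_id,parent_id,s_median,s_lower95,s_upper95,t_median_myr,t_lower95_myr,t_upper95_myr`
#' (empty `t_*` fields mark undated nodes), or a long-format draws table with
#' header `node_id,draw_index,s` via `draws_path`. Row-level validation
#' errors name the offending row.
#'
#' @param path path to the summary CSV.
#' @param draws_path optional path to a long-format s-draws CSV; when given,
#'   raw draws replace the log-normal reconstruction from summaries.
#' @return list with `nodes` (data.frame) and `s_draws` (named list or NULL),
#'   ready for [cospeciation_dataset()].
#' @export
read_node_table <- function(path, draws_path = NULL) {
  if (!file.exists(path))
    stop("node table not found: ", path, call. = FALSE)
  nodes <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(node_id = "character",
                                          parent_id = "character"))
  need <- c("node_id", "parent_id", "t_median_myr", "t_lower95_myr",
            "t_upper95_myr")
  missing_cols <- setdiff(need, names(nodes))
  if (length(missing_cols))
    stop("node table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(nodes))) {
    r <- nodes[i, ]
    if (!is.na(r$t_median_myr)) {
      if (is.na(r$t_lower95_myr) || is.na(r$t_upper95_myr))
        stop(sprintf("row %d: dated node %s needs both interval bounds",
                     i, r$node_id), call. = FALSE)
      if (r$t_lower95_myr <= 0)
        stop(sprintf("row %d: nonpositive calibration bound", i), call. = FALSE)
      if (r$t_lower95_myr > r$t_median_myr || r$t_median_myr > r$t_upper95_myr)
        stop(sprintf("row %d: calibration interval ordering violated (node %s)",
                     i, r$node_id), call. = FALSE)
    }
    if ("s_median" %in% names(nodes) && !is.na(r$s_median)) {
      if (r$s_lower95 > r$s_median || r$s_median > r$s_upper95)
        stop(sprintf("row %d: s interval ordering violated (node %s)",
                     i, r$node_id), call. = FALSE)
      if (r$s_lower95 <= 0)
        stop(sprintf("row %d: nonpositive s bound", i), call. = FALSE)
    }
  }
  s_draws <- NULL
  if (!is.null(draws_path)) {
    if (!file.exists(draws_path))
      stop("draws table not found: ", draws_path, call. = FALSE)
    dr <- utils::read.csv(draws_path, stringsAsFactors = FALSE,
                          colClasses = c(node_id = "character"))
    if (!all(c("node_id", "draw_index", "s") %in% names(dr)))
      stop("draws table needs columns node_id,draw_index,s", call. = FALSE)
    s_draws <- split(dr$s[order(dr$node_id, dr$draw_index)],
                     dr$node_id[order(dr$node_id, dr$draw_index)])
  }
  list(nodes = nodes, s_draws = s_draws)
}

#' Write a node table CSV
#'
#' Writes the summary node table in the format [read_node_table()] reads,
#' deriving `s_median`/`s_lower95`/`s_upper95` from a dataset's draws.
#'
#' @param dataset a [cospeciation_dataset()].
#' @param path output CSV path.
#' @param draws_path optional path for a long-format s-draws CSV.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(dataset, path, draws_path = NULL) {
  stopifnot(inherits(dataset, "cospeciation_dataset"))
  nd <- dataset$nodes
  qs <- t(vapply(dataset$s_draws[nd$node_id], function(v)
    stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE), numeric(3)))
  out <- data.frame(node_id = nd$node_id, parent_id = nd$parent_id,
                    s_median = qs[, 1], s_lower95 = qs[, 2],
                    s_upper95 = qs[, 3],
                    t_median_myr = nd$t_median_myr,
                    t_lower95_myr = nd$t_lower95_myr,
                    t_upper95_myr = nd$t_upper95_myr,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(draws_path)) {
    dr <- do.call(rbind, lapply(nd$node_id, function(id) {
      v <- dataset$s_draws[[id]]
      data.frame(node_id = id, draw_index = seq_along(v), s = v,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(dr, draws_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Load a cospeciation dataset from tree + node table files
#'
#' Convenience wrapper: [read_tree_file()] + [read_node_table()] +
#' [cospeciation_dataset()].
#'
#' @param tree_path Newick file.
#' @param table_path summary node-table CSV.
#' @param draws_path optional long-format s-draws CSV.
#' @param seed seed for the log-normal reconstruction when only summaries
#'   are available.
#' @return a [cospeciation_dataset()].
#' @export
read_cospeciation_data <- function(tree_path, table_path, draws_path = NULL,
                                   seed = 1L) {
  tree <- read_tree_file(tree_path)
  tab <- read_node_table(table_path, draws_path)
  cospeciation_dataset(tree, tab$nodes, s_draws = tab$s_draws, seed = seed)
}
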