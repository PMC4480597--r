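#' Standard deviation from a 95% interval summary
#'
#' Converts a reported median and 95% interval (e.g. an HPD from a Bayesian
#' host-dating study) into a normal standard deviation, taking the wider of
#' the two half-widths: `max((median - lower)/1.96, (upper - median)/1.96)`.
#' Used to turn published calibration intervals into sampling distributions.
#'
#' @param median,lower95,upper95 interval summary, `lower95 <= median <= upper95`.
#' @return nonnegative standard deviation on the same scale.
#' @export
sigma_from_interval <- function(median, lower95, upper95) {
  stopifnot(is.numeric(median), is.numeric(lower95), is.numeric(upper95))
  if (any(lower95 > median) || any(median > upper95))
    stop("interval ordering violated: need lower95 <= median <= upper95",
         call. = FALSE)
  pmax((median - lower95) / 1.96, (upper95 - median) / 1.96)
}

#' Node-to-tip heights of a rooted ultrametric tree
#'
#' Computes, for every internal node, the node-to-tip path length (the node's
#' height). Under a strict clock with branch lengths in substitutions/site
#' this is the node-to-tip substitution count. The tree must be ultrametric:
#' within each clade the distances from the node to each descendant tip must
#' agree to within `tol * height`; the returned value is their mean.
#'
#' @param tree an [ape::phylo] object, rooted, with branch lengths.
#' @param tol relative ultrametricity tolerance (default `1e-6`).
#' @return named numeric vector of heights, one per internal node; names are
#'   the tree's node labels where present, else `"nd<number>"`.
#' @export
node_heights <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must carry branch lengths on every edge", call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)      # root-to-node distances
  # tips under each internal node
  heights <- numeric(nnode)
  for (i in seq_len(nnode)) {
    nd <- ntip + i
    tips <- tip_descendants(tree, nd)
    d <- depth[tips] - depth[nd]
    h <- mean(d)
    if (h > 0 && (max(d) - min(d)) > tol * h)
      stop(sprintf(
        "tree is not ultrametric at node %d: tip distances span [%.8g, %.8g]",
        nd, min(d), max(d)), call. = FALSE)
    heights[i] <- h
  }
  labs <- tree$node.label
  if (is.null(labs) || !length(labs)) labs <- paste0("nd", seq_len(nnode))
  labs[is.na(labs) | labs == ""] <- paste0("nd", which(is.na(labs) | labs == ""))
  names(heights) <- labs
  heights
}

# tip indices descending from (and including, if a tip) node `nd`
tip_descendants <- function(tree, nd) {
  ntip <- length(tree$tip.label)
  if (nd <= ntip) return(nd)
  children <- tree$edge[tree$edge[, 1] == nd, 2]
  unlist(lapply(children, tip_descendants, tree = tree))
}

#' Assemble a cospeciation analysis dataset
#'
#' Bundles a rooted ultrametric tree (branch lengths in substitutions/site)
#' with per-node substitution samples and host-derived calibration-time
#' priors into the object the downstream analyses consume. Nodes with a
#' calibration prior are "dated"; nodes with substitution samples but no
#' prior (mismatched cospeciation events) can later have their dates
#' inferred.
#'
#' Substitution samples may be supplied as raw posterior draws (via
#' `s_draws`) or reconstructed from `(s_median, s_lower95, s_upper95)`
#' summaries as log-normal draws matching the median and 95% interval; the
#' reconstruction is flagged in the object since real posterior draws are
#' preferable.
#'
#' @param tree an [ape::phylo], rooted, ultrametric, with internal node
#'   labels naming the nodes in `nodes`.
#' @param nodes a data.frame with columns `node_id`, `parent_id` (`NA` for
#'   the root), and either calibration columns
#'   `t_median_myr`, `t_lower95_myr`, `t_upper95_myr` (all `NA` for undated
#'   nodes) plus, when `s_draws` is absent, summary columns
#'   `s_median`, `s_lower95`, `s_upper95`.
#' @param s_draws optional named list of numeric vectors of raw substitution
#'   draws per `node_id` (overrides the summary columns).
#' @param n_reconstruct number of log-normal draws generated per node when
#'   reconstructing from summaries (default 1000).
#' @param seed optional seed for the summary reconstruction.
#' @return an object of class `cospeciation_dataset` with elements `tree`,
#'   `nodes` (augmented with `dated`, `t_sd_myr`, `s_reconstructed`), and
#'   `s_draws` (named list).
#' @export
cospeciation_dataset <- function(tree, nodes, s_draws = NULL,
                                 n_reconstruct = 1000, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(nodes))
  req <- c("node_id", "parent_id")
  if (!all(req %in% names(nodes)))
    stop("'nodes' must have columns node_id and parent_id", call. = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id in node table", call. = FALSE)
  n_root <- sum(is.na(nodes$parent_id) | nodes$parent_id == "")
  if (n_root != 1L)
    stop(sprintf("exactly one root (empty parent_id) required, found %d", n_root),
         call. = FALSE)
  nodes$parent_id[nodes$parent_id == ""] <- NA_character_
  known <- stats::na.omit(nodes$parent_id)
  if (!all(known %in% nodes$node_id))
    stop("parent_id values must reference node_id values", call. = FALSE)

  tcols <- c("t_median_myr", "t_lower95_myr", "t_upper95_myr")
  for (cc in tcols) if (!cc %in% names(nodes)) nodes[[cc]] <- NA_real_
  nodes$dated <- !is.na(nodes$t_median_myr)
  if (any(nodes$dated)) {
    d <- nodes[nodes$dated, ]
    if (anyNA(d$t_lower95_myr) || anyNA(d$t_upper95_myr))
      stop("dated nodes need t_lower95_myr and t_upper95_myr", call. = FALSE)
    if (any(d$t_lower95_myr <= 0))
      stop("calibration times must be positive (Myr)", call. = FALSE)
    bad <- d$t_lower95_myr > d$t_median_myr | d$t_median_myr > d$t_upper95_myr
    if (any(bad))
      stop(sprintf("calibration interval ordering violated for node(s): %s",
                   paste(d$node_id[bad], collapse = ", ")), call. = FALSE)
  }
  nodes$t_sd_myr <- NA_real_
  nodes$t_sd_myr[nodes$dated] <- sigma_from_interval(
    nodes$t_median_myr[nodes$dated],
    nodes$t_lower95_myr[nodes$dated],
    nodes$t_upper95_myr[nodes$dated])

  # substitution draws: raw or reconstructed from summaries
  nodes$s_reconstructed <- FALSE
  if (is.null(s_draws)) {
    scols <- c("s_median", "s_lower95", "s_upper95")
    if (!all(scols %in% names(nodes)))
      stop("need either 's_draws' or summary columns s_median/s_lower95/s_upper95",
           call. = FALSE)
    if (any(nodes$s_lower95 > nodes$s_median | nodes$s_median > nodes$s_upper95))
      stop("s interval ordering violated", call. = FALSE)
    if (any(nodes$s_lower95 <= 0))
      stop("s summaries must be positive", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    s_draws <- lapply(seq_len(nrow(nodes)), function(i) {
      m <- nodes$s_median[i]
      sdlog <- max((log(m) - log(nodes$s_lower95[i])) / 1.96,
                   (log(nodes$s_upper95[i]) - log(m)) / 1.96)
      if (sdlog == 0) rep(m, n_reconstruct)
      else stats::rlnorm(n_reconstruct, meanlog = log(m), sdlog = sdlog)
    })
    names(s_draws) <- nodes$node_id
    nodes$s_reconstructed <- TRUE
  } else {
    if (is.null(names(s_draws)) || !all(nodes$node_id %in% names(s_draws)))
      stop("'s_draws' must be a named list covering every node_id", call. = FALSE)
    s_draws <- s_draws[nodes$node_id]
    ok <- vapply(s_draws, function(v) length(v) > 0 && all(is.finite(v)) && all(v > 0),
                 logical(1))
    if (!all(ok))
      stop("every node needs nonempty, positive, finite s draws", call. = FALSE)
  }

  obj <- structure(
    list(tree = tree, nodes = nodes, s_draws = s_draws),
    class = "cospeciation_dataset"
  )
  validate_cospeciation_dataset(obj)
  obj
}

# invariants: tree ultrametric; dated child's median < nearest dated
# ancestor's median; median s non-decreasing child -> parent.
validate_cospeciation_dataset <- function(x) {
  node_heights(x$tree)  # errors if non-ultrametric / lengths missing
  nd <- x$nodes
  med_s <- vapply(x$s_draws, stats::median, numeric(1))
  for (i in seq_len(nrow(nd))) {
    pid <- nd$parent_id[i]
    if (is.na(pid)) next
    if (med_s[nd$node_id[i]] > med_s[pid] * (1 + 1e-9))
      stop(sprintf("median s of node %s exceeds its parent %s",
                   nd$node_id[i], pid), call. = FALSE)
    if (nd$dated[i]) {
      anc <- nearest_dated_ancestor(nd, nd$node_id[i])
      if (!is.na(anc)) {
        tm <- nd$t_median_myr[match(anc, nd$node_id)]
        if (nd$t_median_myr[i] >= tm)
          stop(sprintf(
            "calibration median of node %s (%.4g Myr) must be below its dated ancestor %s (%.4g Myr)",
            nd$node_id[i], nd$t_median_myr[i], anc, tm), call. = FALSE)
      }
    }
  }
  invisible(x)
}

# id of the nearest dated ancestor of `id`, or NA
nearest_dated_ancestor <- function(nodes, id) {
  cur <- nodes$parent_id[match(id, nodes$node_id)]
  while (!is.na(cur)) {
    j <- match(cur, nodes$node_id)
    if (nodes$dated[j]) return(cur)
    cur <- nodes$parent_id[j]
  }
  NA_character_
}

#' @export
print.cospeciation_dataset <- function(x, ...) {
  cat(sprintf("Cospeciation dataset: %d tips, %d internal nodes (%d dated)\n",
              length(x$tree$tip.label), nrow(x$nodes), sum(x$nodes$dated)))
  cat(sprintf("  s draws per node: %s%s\n",
              paste(range(lengths(x$s_draws)), collapse = "-"),
              if (any(x$nodes$s_reconstructed)) " (reconstructed from summaries)" else ""))
  invisible(x)
}

#' Simulate calibration times respecting tree ordering
#'
#' Draws `n_sets` joint samples of the dated nodes' ages from normal
#' distributions centred on each calibration median with the prior's standard
#' deviation, constrained so that within every draw each child node is
#' younger than its nearest dated ancestor. Sampling is top-down: ancestors
#' are drawn first and each descendant is drawn from its normal truncated
#' above at the ancestor's realised age (and below at `1e-6` Myr, so no
#' non-positive ages occur). Truncation uses the inverse-CDF, so every row is
#' feasible by construction; an error is raised only when the truncation
#' window carries essentially no probability mass (e.g. a child median far
#' above its parent's).
#'
#' @param dataset a [cospeciation_dataset()].
#' @param n_sets number of joint draws.
#' @param seed optional integer seed.
#' @return matrix `n_sets x n_dated`, columns named by dated `node_id`, ages
#'   in Myr.
#' @export
simulate_calibration_times <- function(dataset, n_sets, seed = NULL) {
  stopifnot(inherits(dataset, "cospeciation_dataset"))
  if (!is.numeric(n_sets) || n_sets < 1)
    stop("'n_sets' must be a positive count", call. = FALSE)
  n_sets <- as.integer(n_sets)
  if (!is.null(seed)) set.seed(seed)
  nd <- dataset$nodes
  dated <- nd[nd$dated, ]
  if (nrow(dated) == 0L) stop("no dated nodes to simulate", call. = FALSE)
  # ancestors before descendants: sort by decreasing median age
  ord <- order(-dated$t_median_myr)
  dated <- dated[ord, ]
  draws <- matrix(NA_real_, n_sets, nrow(dated),
                  dimnames = list(NULL, dated$node_id))
  t_floor <- 1e-6
  for (j in seq_len(nrow(dated))) {
    mu <- dated$t_median_myr[j]; sd <- dated$t_sd_myr[j]
    anc <- nearest_dated_ancestor(nd, dated$node_id[j])
    upper <- if (is.na(anc)) rep(Inf, n_sets) else draws[, anc]
    if (sd == 0) {
      if (any(mu >= upper))
        stop(sprintf("degenerate prior of node %s conflicts with ancestor draws",
                     dated$node_id[j]), call. = FALSE)
      draws[, j] <- mu
    } else {
      p_lo <- stats::pnorm(t_floor, mu, sd)
      p_hi <- stats::pnorm(upper, mu, sd)
      if (any(p_hi - p_lo < 1e-12))
        stop(sprintf(
          "calibration ordering infeasible for node %s: child age distribution lies above its ancestor's",
          dated$node_id[j]), call. = FALSE)
      u <- p_lo + stats::runif(n_sets) * (p_hi - p_lo)
      draws[, j] <- stats::qnorm(u, mu, sd)
    }
  }
  # restore table order of dated nodes
  draws[, nd$node_id[nd$dated], drop = FALSE]
}

#' Resample (t, s, average-rate) sets with full uncertainty propagation
#'
#' Builds `n_sets` resampled datasets, each pairing one simulated calibration
#' age and one uniformly drawn substitution sample per dated node, and
#' deriving the node-to-tip average rate `rbar = s / t` (reported in
#' substitutions/site/year; `t` is in Myr, so `rbar = s / (t * 1e6)`).
#' Random pairing of `s` and `t` draws propagates both sources of
#' uncertainty without assuming any dependence between them. Substitution
#' draws for undated nodes are co-sampled by replicate index, so later
#' date inference stays coherent within a replicate.
#'
#' @inheritParams simulate_calibration_times
#' @return object of class `rate_sample_sets`: a list with `sets` (list of
#'   `n_sets` data.frames with columns `node_id`, `t_myr`, `s`, `rbar`),
#'   `undated_s` (matrix `n_sets x n_undated` of co-sampled draws, or NULL),
#'   and `node_ids` (dated ids).
#' @export
assemble_rate_sets <- function(dataset, n_sets, seed = NULL) {
  stopifnot(inherits(dataset, "cospeciation_dataset"))
  if (!is.numeric(n_sets) || n_sets < 1)
    stop("'n_sets' must be a positive count", call. = FALSE)
  n_sets <- as.integer(n_sets)
  if (!is.null(seed)) set.seed(seed)
  t_draws <- simulate_calibration_times(dataset, n_sets, seed = NULL)
  nd <- dataset$nodes
  dated_ids <- colnames(t_draws)
  s_mat <- vapply(dated_ids, function(id) {
    v <- dataset$s_draws[[id]]
    v[sample.int(length(v), n_sets, replace = TRUE)]
  }, numeric(n_sets))
  if (n_sets == 1L) s_mat <- matrix(s_mat, nrow = 1, dimnames = list(NULL, dated_ids))
  undated_ids <- nd$node_id[!nd$dated]
  undated_s <- NULL
  if (length(undated_ids)) {
    undated_s <- vapply(undated_ids, function(id) {
      v <- dataset$s_draws[[id]]
      v[sample.int(length(v), n_sets, replace = TRUE)]
    }, numeric(n_sets))
    if (n_sets == 1L)
      undated_s <- matrix(undated_s, nrow = 1, dimnames = list(NULL, undated_ids))
  }
  sets <- lapply(seq_len(n_sets), function(i) {
    data.frame(node_id = dated_ids,
               t_myr = unname(t_draws[i, ]),
               s = unname(s_mat[i, ]),
               rbar = unname(s_mat[i, ] / (t_draws[i, ] * 1e6)),
               stringsAsFactors = FALSE)
  })
  structure(list(sets = sets, undated_s = undated_s, node_ids = dated_ids),
            class = "rate_sample_sets")
}

#' @export
print.rate_sample_sets <- function(x, ...) {
  cat(sprintf("Resampled rate sets: %d replicates x %d dated nodes\n",
              length(x$sets), length(x$node_ids)))
  invisible(x)
}
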