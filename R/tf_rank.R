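#' Rank transcription factors by heat diffusion into a target gene set
#'
#' Each target gene starts with unit heat; heat propagates backward along
#' regulation edges, discounted by the diffusion coefficient \code{d} per
#' extra layer of the regulatory hierarchy. A regulator's weight is the sum
#' over targets of \eqn{d^{k-1}}, where \eqn{k} is the length of the
#' shortest directed path from the regulator to that target (each target
#' counted once, at its nearest layer, and only within \code{max_depth}
#' layers). A TF with four direct targets therefore weighs exactly twice
#' one with two; purely indirect regulation is discounted geometrically.
#'
#' @param network a \code{"reg_network"} edge list (columns
#'   \code{regulator}, \code{target}); TF-to-TF edges participate in
#'   propagation.
#' @param targets character vector of target gene ids; ids absent from the
#'   network are dropped with a warning.
#' @param d diffusion coefficient in (0, 1].
#' @param max_depth maximum number of propagation layers.
#' @return Data frame of class \code{"tf_scores"}, ordered by decreasing
#'   weight (ties by id): \code{tf_id}, \code{weight}, \code{rank} (ties
#'   share the smallest rank), \code{pct_regulated} (percent of targets
#'   reachable within \code{max_depth}), \code{pct_direct} (percent
#'   directly regulated), \code{n_targets_reached}.
#' @export
#' @examples
#' net <- data.frame(regulator = c("TF1", "TF1", "TF2"),
#'                   target = c("g1", "g2", "g1"))
#' rank_tfs(net, targets = c("g1", "g2"))
rank_tfs <- function(network, targets, d = 0.25, max_depth = 10) {
  stopifnot(is.data.frame(network),
            all(c("regulator", "target") %in% names(network)))
  if (d <= 0 || d > 1) stop("`d` must be in (0, 1]", call. = FALSE)
  stopifnot(max_depth >= 1)
  tfs <- attr(network, "tfs")
  if (is.null(tfs)) tfs <- sort(unique(network$regulator))
  # TFs without any recorded edge still get scored (weight 0)
  nodes <- unique(c(network$regulator, network$target, tfs))
  missing <- setdiff(targets, nodes)
  if (length(missing) > 0) {
    warning(length(missing), " target id(s) absent from the network dropped",
            call. = FALSE)
    targets <- intersect(targets, nodes)
  }
  targets <- unique(targets)
  if (length(targets) == 0) {
    stop("no targets left after filtering against the network",
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    network[c("regulator", "target")], directed = TRUE,
    vertices = data.frame(name = nodes))
  dist <- igraph::distances(g, v = tfs, to = targets, mode = "out")
  reach <- is.finite(dist) & dist >= 1 & dist <= max_depth
  contrib <- ifelse(reach, d^(dist - 1), 0)
  weight <- rowSums(contrib)
  scores <- data.frame(
    tf_id = tfs,
    weight = unname(weight),
    pct_regulated = 100 * rowSums(reach) / length(targets),
    pct_direct = 100 * rowSums(is.finite(dist) & dist == 1) /
      length(targets),
    n_targets_reached = unname(rowSums(reach)),
    stringsAsFactors = FALSE
  )
  scores <- scores[order(-scores$weight, scores$tf_id), , drop = FALSE]
  scores$rank <- rank(-scores$weight, ties.method = "min")
  scores <- scores[c("tf_id", "weight", "rank", "pct_regulated",
                     "pct_direct", "n_targets_reached")]
  rownames(scores) <- NULL
  structure(scores, d = d, max_depth = max_depth, n_targets = length(targets),
            class = c("tf_scores", "data.frame"))
}

#' Percent of a target set regulated by one transcription factor
#'
#' @param network a \code{"reg_network"} edge list.
#' @param tf a single TF id.
#' @param targets target gene ids (non-empty after filtering).
#' @param max_depth maximum path length counted as regulation.
#' @return Percent of targets reachable from \code{tf} within
#'   \code{max_depth} directed steps.
#' @export
pct_regulated <- function(network, tf, targets, max_depth = 10) {
  stopifnot(length(tf) == 1)
  nodes <- unique(c(network$regulator, network$target))
  targets <- unique(intersect(targets, nodes))
  if (length(targets) == 0) stop("empty target set", call. = FALSE)
  if (!tf %in% nodes) return(0)
  g <- igraph::graph_from_data_frame(
    network[c("regulator", "target")], directed = TRUE,
    vertices = data.frame(name = nodes))
  dist <- igraph::distances(g, v = tf, to = targets, mode = "out")
  100 * sum(is.finite(dist) & dist >= 1 & dist <= max_depth) /
    length(targets)
}

#' Compare diffusion ranks between two TF groups
#'
#' Reports the mean rank of each (disjoint) TF group and a Wilcoxon
#' rank-sum test of their rank distributions -- exact when group sizes are
#' small and tie-free, the normal approximation otherwise. Used to ask
#' whether regulators with a lifespan phenotype rank higher than those
#' without.
#'
#' @param scores a \code{"tf_scores"} table from [rank_tfs()].
#' @param group_a,group_b disjoint TF id sets, >= 3 members each present in
#'   `scores`.
#' @param alternative test direction for group_a vs group_b ranks (ranks
#'   are smaller-is-better, so \code{"less"} asks whether group_a ranks
#'   higher).
#' @return List: \code{mean_rank_a}, \code{mean_rank_b}, \code{p_value},
#'   \code{statistic}, \code{alternative}.
#' @export
compare_rank_groups <- function(scores, group_a, group_b,
                                alternative = c("two.sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("TF groups must be disjoint", call. = FALSE)
  }
  rk <- setNames(scores$rank, scores$tf_id)
  ra <- rk[intersect(group_a, names(rk))]
  rb <- rk[intersect(group_b, names(rk))]
  if (length(ra) < 3 || length(rb) < 3) {
    stop("need >= 3 scored TFs per group", call. = FALSE)
  }
  wt <- suppressWarnings(
    wilcox.test(unname(ra), unname(rb), alternative = alternative))
  list(mean_rank_a = mean(ra), mean_rank_b = mean(rb),
       p_value = wt$p.value, statistic = unname(wt$statistic),
       alternative = alternative)
}
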