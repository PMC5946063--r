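#' Cohen's kappa between two binary annotation vectors
#'
#' Chance-corrected agreement: observed agreement
#' \eqn{P_a = (n_{11} + n_{00})/n} (terms both genes share, plus terms
#' neither has, over all terms) against the chance agreement
#' \eqn{P_e = p_a p_b + (1-p_a)(1-p_b)};
#' \eqn{\kappa = (P_a - P_e)/(1 - P_e)}. When \eqn{P_e = 1} (both vectors
#' constant with the same composition) kappa is defined as 0 with a
#' warning.
#'
#' @param vec_a,vec_b equal-length binary (0/1) vectors.
#' @return Kappa in \eqn{[-1, 1]}.
#' @export
#' @examples
#' cohen_kappa(c(1,1,1,1,0,0,0,0,0,0), c(1,1,0,0,1,1,0,0,0,0))  # 0.1667
cohen_kappa <- function(vec_a, vec_b) {
  stopifnot(length(vec_a) == length(vec_b), length(vec_a) >= 1)
  if (!all(vec_a %in% c(0, 1)) || !all(vec_b %in% c(0, 1))) {
    stop("annotation vectors must be binary (0/1)", call. = FALSE)
  }
  n <- length(vec_a)
  po <- sum(vec_a == vec_b) / n
  pa <- mean(vec_a)
  pb <- mean(vec_b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) {
    warning("chance agreement is 1 (constant vectors); kappa set to 0",
            call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Pairwise kappa network over an annotation matrix
#'
#' Evaluates Cohen's kappa for every unordered gene pair of a binary
#' gene-by-term matrix (vectorised via the pairwise agreement-table counts)
#' and keeps edges strictly above the threshold. A kappa above ~0.35 is the
#' usual cut for calling two genes functionally similar in large annotation
#' sets.
#'
#' @param m binary matrix, genes in rows (rownames required), terms in
#'   columns.
#' @param threshold minimum kappa (exclusive) for an edge.
#' @return Data frame of class \code{"kappa_edges"}: \code{gene_a},
#'   \code{gene_b}, \code{kappa} (each unordered pair once,
#'   \code{gene_a < gene_b}); attribute \code{"threshold"}.
#' @export
build_kappa_network <- function(m, threshold = 0.35) {
  stopifnot(is.matrix(m), nrow(m) >= 2, !is.null(rownames(m)))
  if (length(m) > 0 && !all(m %in% c(0, 1))) {
    stop("annotation matrix must be binary", call. = FALSE)
  }
  storage.mode(m) <- "double"
  n <- ncol(m)
  n11 <- tcrossprod(m)
  n00 <- tcrossprod(1 - m)
  po <- (n11 + n00) / n
  p <- rowMeans(m)
  pe <- outer(p, p) + outer(1 - p, 1 - p)
  k <- (po - pe) / (1 - pe)
  k[pe >= 1] <- 0
  ut <- upper.tri(k)
  idx <- which(ut & k > threshold, arr.ind = TRUE)
  genes <- rownames(m)
  a <- genes[idx[, 1]]
  b <- genes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(gene_a = a, gene_b = b,
                      kappa = k[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, threshold = threshold,
            class = c("kappa_edges", "data.frame"))
}

# overlap fraction between two member sets
group_overlap <- function(a, b, denominator) {
  inter <- length(intersect(a, b))
  if (denominator == "min") inter / min(length(a), length(b))
  else inter / length(union(a, b))
}

#' Merge kappa seed pairs into functional clusters
#'
#' Starting from the gene pairs of a kappa network as seeds, iteratively
#' merges any two groups sharing at least an \code{overlap} fraction of
#' their members (denominator: the smaller group by default, configurable
#' to the union/Jaccard), repeating until only dissimilar groups remain;
#' groups with fewer than \code{min_size} members are then dropped. Each
#' iteration processes groups in lexicographic order of their sorted member
#' ids and merges the first qualifying pair, which makes the fixpoint
#' deterministic.
#'
#' @param edges a \code{"kappa_edges"} data frame (or any data frame with
#'   \code{gene_a}, \code{gene_b}).
#' @param overlap merge threshold on the shared-member fraction.
#' @param min_size minimum final cluster size.
#' @param denominator \code{"min"} (smaller group) or \code{"union"}
#'   (Jaccard).
#' @return Object of class \code{"kappa_clusters"}: \code{clusters} (list
#'   of member-id character vectors, largest first), \code{table} (data
#'   frame \code{gene_id}, \code{cluster_id}, \code{cluster_label}).
#' @export
#' @examples
#' e <- data.frame(gene_a = c("A","B","A","C"), gene_b = c("B","C","C","D"))
#' merge_clusters(e)$clusters   # one cluster {A,B,C,D}
merge_clusters <- function(edges, overlap = 0.5, min_size = 4,
                           denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  stopifnot(overlap > 0, overlap <= 1, min_size >= 1)
  groups <- unique(lapply(seq_len(nrow(edges)), function(i) {
    sort(c(edges$gene_a[i], edges$gene_b[i]))
  }))
  if (length(groups) > 0) {
    repeat {
      # deterministic processing order: lexicographic on sorted members
      keys <- vapply(groups, paste, character(1), collapse = "\r")
      groups <- groups[order(keys)]
      merged <- FALSE
      ng <- length(groups)
      for (i in seq_len(ng - 1)) {
        for (j in (i + 1):ng) {
          if (group_overlap(groups[[i]], groups[[j]], denominator) >=
              overlap) {
            newg <- sort(union(groups[[i]], groups[[j]]))
            groups <- c(groups[-c(i, j)], list(newg))
            groups <- unique(groups)
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  groups <- groups[vapply(groups, length, integer(1)) >= min_size]
  groups <- groups[order(-vapply(groups, length, integer(1)),
                         vapply(groups, `[`, character(1), 1))]
  tab <- if (length(groups) > 0) {
    do.call(rbind, lapply(seq_along(groups), function(k) {
      data.frame(gene_id = groups[[k]], cluster_id = k,
                 cluster_label = sprintf("cluster_%02d", k),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(), cluster_id = integer(),
               cluster_label = character(), stringsAsFactors = FALSE)
  }
  structure(list(clusters = groups, table = tab),
            class = "kappa_clusters")
}

#' @export
print.kappa_clusters <- function(x, ...) {
  cat("Kappa clusters:", length(x$clusters), "cluster(s),",
      nrow(x$table), "gene assignments\n")
  for (k in seq_along(x$clusters)) {
    mem <- x$clusters[[k]]
    cat(sprintf("  %2d (n=%d): %s%s\n", k, length(mem),
                paste(head(mem, 6), collapse = ", "),
                if (length(mem) > 6) ", ..." else ""))
  }
  invisible(x)
}

#' Export a kappa cluster network
#'
#' Writes the edge list as SIF-style three-column text
#' (\code{gene  kappa  gene}), as a weighted TSV (\code{gene_a},
#' \code{gene_b}, \code{kappa}), and a node table
#' (\code{gene_id}, \code{cluster_id}, \code{cluster_label}) optionally
#' annotated with each cluster's mean-LE rank for colouring.
#'
#' @param edges \code{"kappa_edges"} data frame.
#' @param clusters \code{"kappa_clusters"} object.
#' @param prefix output path prefix; files are \code{<prefix>.sif},
#'   \code{<prefix>_edges.tsv}, \code{<prefix>_nodes.tsv}.
#' @param le optional named numeric vector of LE values per gene; adds
#'   \code{mean_le} and \code{le_rank} columns per cluster.
#' @return Character vector of the written paths, invisibly.
#' @export
export_cluster_network <- function(edges, clusters, prefix, le = NULL) {
  sif_path <- paste0(prefix, ".sif")
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  sif <- data.frame(gene_a = edges$gene_a,
                    interaction = rep("kappa", nrow(edges)),
                    gene_b = edges$gene_b)
  write.table(sif, sif_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(edges)[c("gene_a", "gene_b", "kappa")],
              edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- clusters$table
  if (!is.null(le) && nrow(nodes) > 0) {
    mean_le <- tapply(le[nodes$gene_id], nodes$cluster_id,
                      function(v) mean(v, na.rm = TRUE))
    nodes$mean_le <- as.numeric(mean_le[as.character(nodes$cluster_id)])
    rk <- rank(-mean_le, ties.method = "min")
    nodes$le_rank <- as.integer(rk[as.character(nodes$cluster_id)])
  }
  write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif = sif_path, edges = edge_path, nodes = node_path))
}
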