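# Shared fixtures and independent oracles, built in code at test time.

# fully deterministic generator settings (no noise of any kind)
noiseless_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, noise_cv = 0, outlier_rate = 0, well_sd = 0,
             od_sd = 0, ...)
}

# a clean exponential outgrowth curve: od = od0 * 2^(t/dt), saturating never
exp_curve <- function(dt_hr = 2, od0 = 0.05, times = seq(0, 12, 0.5),
                      age_days = 0, strain_id = "S1", condition = "NR") {
  outgrowth_curve(times, od600 = od0 * 2^(times / dt_hr),
                  strain_id = strain_id, condition = condition,
                  age_days = age_days)
}

# brute-force fixpoint oracle for kappa cluster merging: naive full rescan,
# lexicographic processing order, plain list-of-character-vector state
oracle_merge <- function(pairs, overlap = 0.5, min_size = 4,
                         denominator = "min") {
  gs <- unique(lapply(pairs, sort))
  ov_fun <- function(a, b) {
    inter <- length(intersect(a, b))
    if (denominator == "min") inter / min(length(a), length(b))
    else inter / length(union(a, b))
  }
  repeat {
    gs <- gs[order(vapply(gs, paste, "", collapse = "\r"))]
    done <- TRUE
    for (i in seq_along(gs)) {
      if (!done) break
      for (j in seq_along(gs)) {
        if (j <= i) next
        if (ov_fun(gs[[i]], gs[[j]]) >= overlap) {
          merged <- sort(union(gs[[i]], gs[[j]]))
          gs <- unique(c(gs[-c(i, j)], list(merged)))
          done <- FALSE
          break
        }
      }
    }
    if (done) break
  }
  gs <- gs[vapply(gs, length, 0L) >= min_size]
  # canonical order for comparison
  gs[order(vapply(gs, paste, "", collapse = "\r"))]
}

canon_clusters <- function(cl) {
  gs <- lapply(cl, sort)
  gs[order(vapply(gs, paste, "", collapse = "\r"))]
}

# exhaustive shortest-backward-path enumeration oracle for diffusion weights:
# plain frontier-expansion BFS on a logical adjacency matrix, no igraph
oracle_tf_weights <- function(edges, tfs, targets, d = 0.25, max_depth = 10) {
  nodes <- unique(c(edges$regulator, edges$target, tfs, targets))
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) A[cbind(edges$regulator, edges$target)] <- TRUE
  sapply(tfs, function(tf) {
    w <- 0
    for (tg in targets) {
      frontier <- nodes == tf
      found <- NA_integer_
      for (k in seq_len(max_depth)) {
        frontier <- as.logical(frontier %*% A)   # nodes reachable in k steps
        if (frontier[match(tg, nodes)]) { found <- k; break }
        if (!any(frontier)) break
      }
      if (!is.na(found)) w <- w + d^(found - 1)
    }
    w
  })
}

# Jaccard index between two member sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
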