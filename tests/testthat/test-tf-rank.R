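test_that("diffusion weights follow hand path enumeration", {
  net <- data.frame(
    regulator = c("TF1", "TF2", "TF3", "TF3", "TF3", "TF3", "TF4", "TF4",
                  "TF5"),
    target = c("g1", "TF1", "g1", "g2", "g3", "g4", "g1", "g2", "g9"))
  targets <- c("g1", "g2", "g3", "g4")
  sc <- rank_tfs(net, targets, d = 0.25)
  w <- setNames(sc$weight, sc$tf_id)
  expect_equal(unname(w["TF1"]), 1.0)      # one direct target
  expect_equal(unname(w["TF2"]), 0.25)     # only indirect via TF1
  expect_equal(unname(w["TF3"]), 4.0)      # four direct targets
  expect_equal(unname(w["TF4"]), 2.0)      # two direct: exactly half of TF3
  expect_equal(unname(w["TF5"]), 0)        # no path into the target set
  expect_equal(sc$rank[sc$tf_id == "TF5"], max(sc$rank))
  # weight is monotone non-increasing with rank
  expect_true(all(diff(sc$weight[order(sc$rank)]) <= 1e-12))
  pr <- setNames(sc$pct_regulated, sc$tf_id)
  expect_equal(unname(pr["TF3"]), 100)
  expect_equal(unname(pr["TF4"]), 50)
  expect_equal(unname(pr["TF5"]), 0)
})

test_that("each target counts once, at its nearest layer", {
  # TF regulates g1 directly AND via an intermediate: only the direct counts
  net <- data.frame(regulator = c("TF1", "TF1", "TF2"),
                    target = c("g1", "TF2", "g1"))
  sc <- rank_tfs(net, "g1", d = 0.25)
  expect_equal(sc$weight[sc$tf_id == "TF1"], 1.0)
})

test_that("missing targets are dropped with a warning; empty set errors", {
  net <- data.frame(regulator = "TF1", target = "g1")
  expect_warning(sc <- rank_tfs(net, c("g1", "nope")), "dropped")
  expect_equal(attr(sc, "n_targets"), 1L)
  expect_error(suppressWarnings(rank_tfs(net, "nope")), "no targets")
  expect_error(rank_tfs(net, "g1", d = 0), "d")
})

test_that("adding a direct edge to an unreached target never lowers weight", {
  set.seed(12)
  for (i in 1:20) {
    reg <- simulate_regnet(n_tfs = 8, n_genes = 20, target_set_size = 8,
                           seed = i)
    sc <- suppressWarnings(rank_tfs(reg$network, reg$targets))
    tf <- sample(attr(reg$network, "tfs"), 1)
    w0 <- sc$weight[sc$tf_id == tf]
    reached <- reg$network$target[reg$network$regulator == tf]
    unreached <- setdiff(reg$targets, reached)
    if (length(unreached) == 0) next
    net2 <- rbind(as.data.frame(reg$network),
                  data.frame(regulator = tf, target = unreached[1]))
    attr(net2, "tfs") <- attr(reg$network, "tfs")
    w1 <- rank_tfs(net2, reg$targets)
    expect_gte(w1$weight[w1$tf_id == tf], w0)
  }
})

test_that("weights match exhaustive path enumeration on small networks", {
  set.seed(201)
  for (i in 1:100) {
    n_tf <- sample(2:5, 1)
    n_g <- sample(3:10, 1)
    tfs <- sprintf("TF%d", seq_len(n_tf))
    genes <- sprintf("g%d", seq_len(n_g))
    nodes <- c(tfs, genes)                 # <= 15 nodes
    n_e <- sample(3:20, 1)
    edges <- unique(data.frame(
      regulator = sample(tfs, n_e, replace = TRUE),
      target = sample(nodes, n_e, replace = TRUE)))
    edges <- edges[edges$regulator != edges$target, , drop = FALSE]
    if (nrow(edges) == 0) next
    targets <- sample(genes, sample(1:min(4, n_g), 1))
    if (!any(targets %in% c(edges$regulator, edges$target))) next
    sc <- suppressWarnings(rank_tfs(edges, targets, d = 0.25,
                                    max_depth = 10))
    want <- oracle_tf_weights(edges, tfs = sc$tf_id,
                              targets = intersect(targets,
                                                  c(edges$regulator,
                                                    edges$target)),
                              d = 0.25, max_depth = 10)
    expect_equal(setNames(sc$weight, sc$tf_id), want[sc$tf_id],
                 tolerance = 1e-12)
  }
})

test_that("truncating the propagation depth obeys the geometric tail bound", {
  reg <- simulate_regnet(n_tfs = 10, n_genes = 40, target_set_size = 15,
                         seed = 6)
  d <- 0.25
  w10 <- suppressWarnings(rank_tfs(reg$network, reg$targets, d = d,
                                   max_depth = 10))
  w6 <- suppressWarnings(rank_tfs(reg$network, reg$targets, d = d,
                                  max_depth = 6))
  diff_w <- abs(setNames(w10$weight, w10$tf_id)[w6$tf_id] - w6$weight)
  bound <- d^6 / (1 - d) * w10$n_targets_reached[match(w6$tf_id, w10$tf_id)]
  expect_true(all(diff_w <= pmax(bound, 1e-12)))
})

test_that("pct_regulated reports reachability fractions", {
  net <- data.frame(regulator = c("TF1", "TF1", "TF1", "TF2", "TF3",
                                  "TF3", "TF3"),
                    target = c("g1", "g2", "g3", "TF1", "g4", "g5", "g6"))
  expect_equal(pct_regulated(net, "TF1", c("g1", "g2", "g3", "g4", "g5",
                                           "g6")), 50)
  expect_equal(pct_regulated(net, "TF2", c("g1", "g2", "g3")), 100)
  expect_equal(pct_regulated(net, "TF9", c("g1")), 0)
  expect_error(pct_regulated(net, "TF1", "absent"), "empty")
})

test_that("rank-group comparison reproduces the exact rank-sum p-value", {
  sc <- structure(data.frame(tf_id = sprintf("TF%d", 1:6),
                             weight = 6:1, rank = 1:6),
                  class = c("tf_scores", "data.frame"))
  res <- compare_rank_groups(sc, sprintf("TF%d", 1:3), sprintf("TF%d", 4:6),
                             alternative = "less")
  expect_equal(res$p_value, 0.05)          # 1 / choose(6, 3)
  expect_equal(res$mean_rank_a, 2)
  expect_equal(res$mean_rank_b, 5)

  sc2 <- structure(data.frame(tf_id = sprintf("TF%d", 1:6),
                              weight = rep(3:1, 2), rank = rep(1:3, 2)),
                   class = c("tf_scores", "data.frame"))
  res2 <- compare_rank_groups(sc2, sprintf("TF%d", 1:3), sprintf("TF%d", 4:6))
  expect_equal(res2$p_value, 1)
  expect_error(compare_rank_groups(sc, c("TF1", "TF2", "TF3"),
                                   c("TF3", "TF4", "TF5")), "disjoint")
})

test_that("planted regulators out-rank decoys across seeds", {
  wins <- vapply(1:20, function(i) {
    reg <- simulate_regnet(n_tfs = 20, n_genes = 80, target_set_size = 25,
                           seed = 300 + i)
    sc <- suppressWarnings(rank_tfs(reg$network, reg$targets))
    rk <- setNames(sc$rank, sc$tf_id)
    mean(rk[reg$planted]) < mean(rk[reg$decoys])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
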