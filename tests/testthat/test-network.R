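gradient_network <- function(n = 8, extra = 6, seed = 2) {
  # edges are exact node-value differences: every cycle closes to zero
  make_noisy_network(n, n - 1 + extra, dg_spread = 4, edge_sigma = 0, seed = seed)
}

test_that("star maps connect every ligand to the reference", {
  net <- build_star_map(sprintf("L%02d", 1:16), "L01",
    extra_edges = data.frame(
      from = sprintf("L%02d", 2:16), to = sprintf("L%02d", c(3:16, 2))
    )
  )
  expect_equal(nrow(net$edges), 30)
  expect_equal(sum(net$edges$from == "L01" | net$edges$to == "L01"), 15)
  small <- build_star_map(c("a", "b", "c"), "a")
  expect_equal(nrow(small$edges), 2)
  expect_length(enumerate_cycles(small), 0)
  expect_warning(
    dup <- build_star_map(c("a", "b", "c"), "a", data.frame(from = "b", to = "a")),
    "duplicate"
  )
  expect_equal(nrow(dup$edges), 2)
  expect_error(build_star_map(c("a", "b"), "z"), "reference")
})

test_that("series maps generate intra and inter transformations", {
  series <- list(sprintf("A%d", 1:6), sprintf("B%d", 1:6), sprintf("C%d", 1:6))
  net <- build_series_map(series, intra_edges = 10, inter_edges = 5)
  expect_equal(nrow(net$edges), 3 * 10 + 3 * 5)
  one <- build_series_map(list(sprintf("A%d", 1:6)), intra_edges = 10, inter_edges = 5)
  expect_equal(nrow(one$edges), 10)
  two <- build_series_map(list(c("a1", "a2"), c("b1", "b2")), intra_edges = 0, inter_edges = 1)
  expect_equal(nrow(two$edges), 1)
  expect_error(
    build_series_map(list(c("a1", "a2")), intra_edges = 5, inter_edges = 0),
    "exceeds"
  )
})

test_that("cycle enumeration matches hand counts on canonical graphs", {
  tri <- fe_network(c("a", "b", "c"), data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
  expect_length(enumerate_cycles(tri), 1)
  k4 <- fe_network(
    letters[1:4],
    data.frame(
      from = c("a", "a", "a", "b", "b", "c"),
      to = c("b", "c", "d", "c", "d", "d")
    )
  )
  cyc <- enumerate_cycles(k4)
  expect_length(cyc, 7) # 4 triangles + 3 four-cycles
  expect_equal(sum(lengths(cyc) == 3), 4)
  expect_equal(sum(lengths(cyc) == 4), 3)
  # deterministic lexicographic order
  expect_identical(cyc, enumerate_cycles(k4))
  expect_equal(cyc[[1]][1], "a")
  tree <- fe_network(letters[1:5], data.frame(from = c("a", "a", "b", "b"), to = c("b", "c", "d", "e")))
  expect_length(enumerate_cycles(tree), 0)
  # length cap
  expect_length(enumerate_cycles(k4, max_length = 3), 4)
})

test_that("gradient networks close exactly; a perturbed edge carries its defect", {
  g <- gradient_network()
  cyc <- enumerate_cycles(g$network)
  expect_gt(length(cyc), 0)
  for (cy in cyc) {
    expect_lt(cycle_closure(cy, g$network)$closure, 1e-12)
  }
  # perturb one edge by +delta: every containing cycle reads exactly delta
  net <- g$network
  delta <- 0.8
  victim <- nrow(net$edges) # a non-tree edge, guaranteed on a cycle
  net$edges$ddg[victim] <- net$edges$ddg[victim] + delta
  vid <- paste(net$edges$from[victim], net$edges$to[victim], sep = "->")
  for (cy in cyc) {
    rep <- cycle_closure(cy, net)
    nodes <- cy
    onpath <- any(vapply(seq_along(nodes), function(i) {
      a <- nodes[i]
      b <- nodes[(i %% length(nodes)) + 1]
      paste(a, b, sep = "->") == vid || paste(b, a, sep = "->") == vid
    }, TRUE))
    expect_equal(rep$closure, if (onpath) delta else 0, tolerance = 1e-10)
  }
})

test_that("triangle closure arithmetic matches the hand example", {
  net <- fe_network(
    c("a", "b", "c"),
    data.frame(
      from = c("a", "b", "c"), to = c("b", "c", "a"),
      ddg = c(1.0, 1.0, -1.5)
    )
  )
  rep <- cycle_closure(c("a", "b", "c"), net)
  expect_equal(rep$closure, 0.5)
  expect_equal(rep$normalized, 0.5 / sqrt(3))
  expect_equal(cycle_closure(c("a", "b", "c"), net, normalization = "n")$normalized, 0.5 / 3)
  expect_error(cycle_closure(c("a", "b"), net), "at least 3")
  expect_error(
    cycle_closure(c("a", "b", "z"), fe_network(c("a", "b", "z"), net$edges[1, ])),
    "missing"
  )
})

test_that("voting singles out a planted bad edge", {
  g <- make_noisy_network(6, 9, edge_sigma = 0.1, bad_edges = 1, delta = 2, seed = 21)
  tally <- vote_edges(enumerate_cycles(g$network), g$network)
  expect_equal(tally$edge[1], g$bad_edges)
  expect_gt(tally$votes[1], tally$votes[2])
  # fully consistent network: every edge collects only positive (-1) votes
  cons <- gradient_network()
  t2 <- vote_edges(enumerate_cycles(cons$network), cons$network)
  expect_true(all(t2$votes == -t2$n_cycles))
  expect_error(vote_edges(list(), cons$network, hi = 0.3, lo = 0.3), "exceed")
})

test_that("hysteresis combines opposite directions as printed", {
  expect_equal(hysteresis(0.8, 1.1), 1.9)
  expect_equal(hysteresis(1.1, 0.8), 1.9)
  expect_equal(hysteresis(2.3, -2.3), 0)
})

test_that("absolute free energies solve exactly on trees and respect the gauge", {
  net <- fe_network(
    c("a", "b", "c"),
    data.frame(
      from = c("a", "b"), to = c("b", "c"),
      ddg = c(1, 2), sigma = c(0.1, 0.1)
    )
  )
  exp_dg <- c(a = -10, b = -9, c = -7)
  sol <- solve_absolute_dg(net, experimental = exp_dg)
  expect_equal(setNames(sol$dg, sol$id), exp_dg, tolerance = 1e-10)
  # adding a constant to all experimental values shifts all predictions
  sol2 <- solve_absolute_dg(net, experimental = exp_dg + 5)
  expect_equal(sol2$dg, sol$dg + 5, tolerance = 1e-10)
  # residuals invariant to reversing an edge with negated value
  g <- gradient_network(seed = 6)
  netr <- g$network
  netr$edges[2, c("from", "to")] <- netr$edges[2, c("to", "from")]
  netr$edges$ddg[2] <- -netr$edges$ddg[2]
  s1 <- solve_absolute_dg(g$network)
  s2 <- solve_absolute_dg(netr)
  expect_equal(s2$dg, s1$dg, tolerance = 1e-10)
})

test_that("network MLE recovers true values within the edge noise", {
  rmse <- vapply(1:50, function(seed) {
    g <- make_noisy_network(10, 30, dg_spread = 3, edge_sigma = 0.2, seed = seed)
    sol <- solve_absolute_dg(g$network)
    truth <- g$truth[sol$id]
    sqrt(mean(((sol$dg - mean(sol$dg)) - (truth - mean(truth)))^2))
  }, 1.0)
  expect_lt(median(rmse), 0.2)
})

test_that("benchmark statistics match hand computations and centering rules", {
  s <- benchmark_stats(c(1, 2, 3), c(1, 2, 3), n_boot = 50, seed = 1)
  v <- setNames(s$value, s$metric)
  expect_equal(unname(v[c("RMSE", "MUE")]), c(0, 0))
  expect_equal(unname(v["R2"]), 1)
  expect_equal(unname(v["KTAU"]), 1)
  # constant offsets vanish after centering
  s2 <- benchmark_stats(c(1, 2, 3) + 4.2, c(1, 2, 3), n_boot = 50, seed = 1)
  expect_equal(s2$value[s2$metric == "RMSE"], 0)
  # 4-point hand example
  s3 <- benchmark_stats(c(0, 1, 2, 3), c(0, 1, 2, 4), n_boot = 50, seed = 1)
  v3 <- setNames(s3$value, s3$metric)
  expect_equal(unname(v3["RMSE"]), sqrt(0.1875))
  expect_equal(unname(v3["MUE"]), 0.375)
  expect_equal(unname(v3["RAE"]), 1.5 / 5)
  expect_equal(unname(v3["KTAU"]), 1)
  # fixed seed is bit-reproducible; different seeds move the CIs
  expect_identical(
    benchmark_stats(c(0, 1, 2, 3), c(0, 1, 2, 4), n_boot = 200, seed = 7),
    benchmark_stats(c(0, 1, 2, 3), c(0, 1, 2, 4), n_boot = 200, seed = 7)
  )
  expect_error(benchmark_stats(c(1, 2), c(1, 2)), "at least 3")
})
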