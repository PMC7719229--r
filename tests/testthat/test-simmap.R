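test_that("near-zero rates give single-segment maps without transitions", {
  states <- c("0", "1")
  Q <- build_rate_matrix(mk_structure(2, "ER"), 1e-10, states)
  tr <- read_newick("((A:1,B:1):1,C:2);")
  tips <- c(A = "1", B = "1", C = "1")
  m <- stochastic_map(tr, tips, Q, seed = 1)
  expect_true(all(vapply(m$edge_maps, nrow, 1L) == 1))
  expect_true(all(vapply(m$edge_maps, function(s) s$state, "") == "1"))
  expect_equal(sum(summarize_maps(m)$mean_counts), 0)
})

test_that("sampled maps satisfy the structural invariants", {
  set.seed(41)
  sim <- simulate_mk_history(simulate_tree(25, 1), default_nhej_q(),
                             root_state = "NHEJ_minus")
  maps <- stochastic_map(sim$history$tree, sim$tip_states, default_nhej_q(),
                         seed = 2, n_maps = 10)
  for (m in maps) expect_valid_map(m)
  # forward-simulated histories satisfy the same invariants
  expect_valid_map(sim$history)
  sm <- summarize_maps(maps)
  expect_lt(abs(sum(sm$time_in_state) - sum(sim$history$tree$edge.length)),
            1e-6 * sum(sim$history$tree$edge.length))
  expect_true(all(abs(rowSums(sm$node_posteriors) - 1) < 1e-12))
})

test_that("summarize_maps does exact bookkeeping on a hand-built map", {
  tr <- stats::reorder(read_newick("(A:2,B:1);"), "postorder")
  states <- c("x", "y", "z", "w")
  m <- list(tree = tr, states = states,
            node_states = c(`1` = "y", `2` = "x", `3` = "x"),
            edge_maps = list(
              data.frame(state = c("x", "z", "y"), dwell = c(0.5, 1, 0.5),
                         stringsAsFactors = FALSE),
              data.frame(state = "x", dwell = 1, stringsAsFactors = FALSE)))
  class(m) <- "stochastic_map"
  sm <- summarize_maps(m)
  expect_equal(sum(sm$mean_counts), 2)
  expect_equal(sm$mean_counts["x", "z"], 1)
  expect_equal(sm$mean_counts["z", "y"], 1)
  expect_equal(unname(sm$time_in_state[c("x", "y", "z", "w")]),
               c(1.5, 0.5, 1, 0))
  # k = 4: twelve ordered transition types
  expect_equal(sum(row(sm$mean_counts) != col(sm$mean_counts)), 12)
  # maps on different trees are rejected
  tr2 <- stats::reorder(read_newick("(A:2,B:3);"), "postorder")
  m2 <- m; m2$tree <- tr2
  expect_error(summarize_maps(list(m, m2)), "same tree")
})

test_that("branch transition counts match the analytic expected jump count", {
  # nearly-degenerate second branch pins the root state to tip B's state
  states <- c("0", "1")
  Q <- build_rate_matrix(mk_structure(2, "ER"), 0.8, states)
  t_len <- 1.5
  tr <- read_newick(sprintf("(A:%g,B:1e-9);", t_len))
  tips <- c(A = "1", B = "0")
  n <- 4000
  maps <- stochastic_map(tr, tips, Q, root_prior = "flat", seed = 3,
                         n_maps = n)
  edge_A <- which(maps[[1]]$tree$edge[, 2] ==
                    match("A", maps[[1]]$tree$tip.label))
  n01 <- vapply(maps, function(m) {
    s <- m$edge_maps[[edge_A]]$state
    if (length(s) < 2) 0 else sum(s[-length(s)] == "0" & s[-1] == "1")
  }, numeric(1))
  expected <- expected_jumps_conditional(Q, t_len, a = 1, b = 2, i = 1,
                                         j = 2)
  se <- sd(n01) / sqrt(n)
  expect_lt(abs(mean(n01) - expected), 3 * se + 1e-3)
})

test_that("node calls require strict majority above the threshold", {
  post <- rbind(`9` = c(0.8, 0.1, 0.05, 0.05),
                `10` = c(0.5, 0.5, 0, 0),
                `11` = c(0.7, 0.3, 0, 0))
  colnames(post) <- NHEJ_STATES4
  calls <- call_node_states(post, threshold = 0.7)
  expect_equal(unname(calls["9"]), "NHEJ_minus")
  expect_true(is.na(calls["10"]))
  expect_true(is.na(calls["11"]))  # exactly 0.7 is not > 0.7
})

test_that("primary-gain caller enforces all four criteria", {
  tr <- read_newick(paste0("(((a1:1,a2:1):1,(a3:1,a4:1):1):1,",
                           "((b1:1,b2:1):1,(b3:1,b4:1):1):1);"))
  ntip <- 8
  nodes <- as.character((ntip + 1):(ntip + tr$Nnode))
  states <- NHEJ_STATES4
  base <- matrix(0, length(nodes), 4, dimnames = list(nodes, states))
  base[, "NHEJ_minus"] <- 1
  X <- ape::getMRCA(tr, c("b1", "b4"))

  # gain of NHEJ_plus at X with 4 descendant tips: reported
  post <- base
  post[as.character(X), ] <- c(0.1, 0.025, 0.025, 0.85)
  calls <- call_node_states(post)
  g <- find_primary_gains(tr, calls, post)
  expect_equal(g$node, X)
  expect_equal(g$gained_state, "NHEJ_plus")
  expect_equal(g$n_descendant_tips, 4)
  expect_equal(g$pp, 0.85)

  # same gain but only 2 descendant tips: rejected
  X2 <- ape::getMRCA(tr, c("b1", "b2"))
  post2 <- base
  post2[as.character(X2), ] <- c(0.1, 0.025, 0.025, 0.85)
  g2 <- find_primary_gains(tr, call_node_states(post2), post2)
  expect_equal(nrow(g2), 0)

  # LigD_only gain with no NHEJ_plus anywhere below: rejected ...
  post3 <- base
  post3[as.character(X), ] <- c(0.05, 0.025, 0.9, 0.025)
  g3 <- find_primary_gains(tr, call_node_states(post3), post3)
  expect_equal(nrow(g3), 0)
  # ... but accepted once a descendant node is called NHEJ_plus
  post4 <- post3
  post4[as.character(X2), ] <- c(0.05, 0.025, 0.025, 0.9)
  g4 <- find_primary_gains(tr, call_node_states(post4), post4)
  expect_equal(g4$node, X)
  expect_equal(g4$gained_state, "LigD_only")

  # an ancestor that is not called NHEJ_minus blocks the gain
  post5 <- post
  post5[as.character(ntip + 1), ] <- c(0.6, 0.1, 0.1, 0.2)  # uncalled root
  g5 <- find_primary_gains(tr, call_node_states(post5), post5)
  expect_equal(nrow(g5), 0)
})

test_that("pp threshold for gains is inclusive at 0.7", {
  tr <- read_newick("((a1:1,a2:1):1,(b1:1,(b2:1,b3:1):1):1);")
  ntip <- 5
  nodes <- as.character((ntip + 1):(ntip + tr$Nnode))
  post <- matrix(0, length(nodes), 4,
                 dimnames = list(nodes, NHEJ_STATES4))
  post[, "NHEJ_minus"] <- 1
  X <- ape::getMRCA(tr, c("b1", "b3"))
  post[as.character(X), ] <- c(0.3, 0, 0, 0.7)  # exactly 0.7
  calls <- call_node_states(post)           # strict: X stays uncalled
  expect_true(is.na(calls[as.character(X)]))
  g <- find_primary_gains(tr, calls, post)  # inclusive: gain reported
  expect_equal(g$node, X)
})
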