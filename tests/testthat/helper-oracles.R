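# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: path sums by breadth-first search, likelihoods by
# exhaustive enumeration with Matrix::expm, closed forms for the 2-state
# symmetric chain.

# brute-force patristic distances: BFS over the (undirected) edge graph
brute_patristic <- function(tree) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  adj <- vector("list", ntot)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(ntip)) {
    dist <- rep(NA_real_, ntot)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][r, 2]
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist[seq_len(ntip)]
  }
  D
}

# sum-over-histories Mk likelihood: enumerate every internal-node state
# combination; transition probabilities from Matrix::expm
enum_loglik <- function(tree, tip_states, Q, prior) {
  states <- colnames(Q)
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  tipidx <- match(tip_states[tree$tip.label], states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    ns <- c(tipidx, combos[r, ])
    pr <- prior[ns[ntip + 1]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][ns[tree$edge[e, 1]], ns[tree$edge[e, 2]]]
    tot <- tot + pr
  }
  log(tot)
}

# 2-state symmetric (ER) chain: P(stay) over time t at rate q
p_stay_er2 <- function(q, t) 0.5 + 0.5 * exp(-2 * q * t)

# random non-ultrametric test tree with positive branch lengths
rand_tree <- function(n, min_len = 0.05) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + min_len
  tr
}

# expected count of i -> j transitions of a CTMC over [0, t], conditional on
# the endpoints: q_ij * int_0^t P_ai(s) P_jb(t - s) ds / P_ab(t)
expected_jumps_conditional <- function(Q, t, a, b, i, j) {
  Pt <- function(s) as.matrix(Matrix::expm(Q * s))
  f <- Vectorize(function(s) Pt(s)[a, i] * Pt(t - s)[j, b])
  Q[i, j] * stats::integrate(f, 0, t, rel.tol = 1e-9)$value / Pt(t)[a, b]
}

# checks the structural invariants of one stochastic map
expect_valid_map <- function(m) {
  el <- m$tree$edge.length
  for (e in seq_along(m$edge_maps)) {
    seg <- m$edge_maps[[e]]
    expect_lt(abs(sum(seg$dwell) - el[e]), 1e-9)
    if (nrow(seg) > 1)
      expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
    # first state of the branch equals the parent node's state
    expect_identical(seg$state[1],
                     unname(m$node_states[as.character(m$tree$edge[e, 1])]))
    expect_identical(seg$state[nrow(seg)],
                     unname(m$node_states[as.character(m$tree$edge[e, 2])]))
  }
}
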