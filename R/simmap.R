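# endpoint-conditioned CTMC path on one branch, by uniformization
# (exact sampling; robust for very short branches where rejection fails)
#   a, b  : 1-based start/end states
#   t     : branch length
#   Rmat  : uniformized jump matrix I + Q/Omega
#   Pab   : transition probability P(a -> b over t)
sample_branch_path <- function(a, b, t, Q, Omega, Rmat, Pab, states) {
  k <- length(states)
  if (Omega <= 0 || t <= 0) {
    return(data.frame(state = states[a], dwell = t,
                      stringsAsFactors = FALSE))
  }
  # number of uniformized events N | endpoints
  u <- runif(1)
  Rpow <- list(diag(k))  # Rpow[[n + 1]] = Rmat^n
  n <- 0L
  cum <- dpois(0, Omega * t) * (a == b) / Pab
  max_n <- 10000L
  while (cum < u && n < max_n) {
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% Rmat
    cum <- cum + dpois(n, Omega * t) * Rpow[[n + 1L]][a, b] / Pab
  }
  if (n == 0L) {
    return(data.frame(state = states[a], dwell = t,
                      stringsAsFactors = FALSE))
  }
  # state sequence at the n event times (bridge sampling through R powers)
  seq_states <- integer(n + 1L)
  seq_states[1L] <- a
  for (i in seq_len(n)) {
    rem <- n - i
    w <- Rmat[seq_states[i], ] * Rpow[[rem + 1L]][, b]
    seq_states[i + 1L] <- sample.int(k, 1L, prob = w)
  }
  times <- sort(runif(n, 0, t))
  bounds <- c(0, times, t)
  # collapse virtual (self) jumps into dwell segments
  st <- seq_states[1L]
  segs_state <- integer(0); segs_dwell <- numeric(0)
  seg_start <- 0
  for (i in seq_len(n)) {
    if (seq_states[i + 1L] != st) {
      segs_state <- c(segs_state, st)
      segs_dwell <- c(segs_dwell, bounds[i + 1L] - seg_start)
      seg_start <- bounds[i + 1L]
      st <- seq_states[i + 1L]
    }
  }
  segs_state <- c(segs_state, st)
  segs_dwell <- c(segs_dwell, t - seg_start)
  data.frame(state = states[segs_state], dwell = segs_dwell,
             stringsAsFactors = FALSE)
}

#' Stochastic character mapping
#'
#' Samples full character histories conditional on the tip data and a
#' generator `Q`: internal node states are drawn from their joint posterior
#' (pre-order pass over the pruning conditionals), then each branch is filled
#' in with an endpoint-conditioned CTMC path sampled exactly by
#' uniformization. Segment dwell times on a branch sum to the branch length
#' and a child branch starts in its parent node's state.
#'
#' @inheritParams mk_loglik
#' @param seed RNG seed.
#' @param n_maps number of independent maps to draw (sharing one pruning
#'   pass).
#' @return A single object of class `"stochastic_map"` when `n_maps = 1`,
#'   else a list of them. Each holds the (postorder) tree, the sampled node
#'   states, and one `data.frame` of `(state, dwell)` segments per edge.
#' @export
stochastic_map <- function(tree, tip_states, Q, root_prior = "fitzjohn",
                           seed = NULL, n_maps = 1) {
  if (!is.null(seed)) set.seed(seed)
  check_generator(Q)
  pr <- mk_prune(tree, tip_states, Q, return_P = TRUE)
  po <- pr$po
  states <- pr$states
  k <- length(states)
  ntot <- po$ntip + po$nnode
  root <- po$ntip + 1L
  pi0 <- root_prior_vec(root_prior, pr$partials[root, ], Q, states)
  Omega <- max(-diag(Q)) * 1.05 + 1e-12
  Rmat <- diag(k) + Q / Omega
  ne <- length(po$child)
  one_map <- function() {
    node_state <- integer(ntot)
    w <- pi0 * pr$partials[root, ]
    node_state[root] <- sample.int(k, 1L, prob = w)
    # pre-order: reverse of the postorder edge list
    for (e in rev(seq_len(ne))) {
      p <- po$parent[e]; ch <- po$child[e]
      w <- pr$P[[e]][node_state[p], ] * pr$partials[ch, ]
      node_state[ch] <- sample.int(k, 1L, prob = w)
    }
    edge_maps <- vector("list", ne)
    for (e in seq_len(ne)) {
      a <- node_state[po$parent[e]]; b <- node_state[po$child[e]]
      edge_maps[[e]] <- sample_branch_path(
        a, b, po$elen[e], Q, Omega, Rmat, pr$P[[e]][a, b], states)
    }
    out <- list(tree = po$tree, states = states,
                node_states = setNames(states[node_state],
                                       as.character(seq_len(ntot))),
                edge_maps = edge_maps)
    class(out) <- "stochastic_map"
    out
  }
  if (n_maps == 1) one_map() else replicate(n_maps, one_map(),
                                            simplify = FALSE)
}

#' Marginal ancestral-state posteriors under an Mk model
#'
#' Direct computation (down pass + up pass over the tree), used both on its
#' own and as the reference the stochastic-map node frequencies must agree
#' with.
#'
#' @inheritParams mk_loglik
#' @return Matrix of posterior probabilities, one row per internal node
#'   (rownames = node numbers), columns = states.
#' @export
marginal_ancestral <- function(tree, tip_states, Q,
                               root_prior = "fitzjohn") {
  check_generator(Q)
  pr <- mk_prune(tree, tip_states, Q, return_P = TRUE)
  po <- pr$po
  states <- pr$states
  k <- length(states)
  ntot <- po$ntip + po$nnode
  root <- po$ntip + 1L
  pi0 <- root_prior_vec(root_prior, pr$partials[root, ], Q, states)
  ne <- length(po$child)
  # per-edge message from child into parent: (P_e %*% L_child)
  edge_msg <- lapply(seq_len(ne), function(e)
    as.vector(pr$P[[e]] %*% pr$partials[po$child[e], ]))
  up <- matrix(NA_real_, ntot, k)   # prior-side partials per node
  up[root, ] <- pi0
  for (e in rev(seq_len(ne))) {
    p <- po$parent[e]; ch <- po$child[e]
    sib <- which(po$parent == p & po$child != ch)
    msg <- up[p, ]
    for (s in sib) msg <- msg * edge_msg[[s]]
    v <- as.vector(msg %*% pr$P[[e]])
    up[ch, ] <- v / max(v)  # rescale; posteriors are normalized per node
  }
  nodes <- seq.int(root, ntot)
  post <- up[nodes, , drop = FALSE] * pr$partials[nodes, , drop = FALSE]
  post <- post / rowSums(post)
  dimnames(post) <- list(as.character(nodes), states)
  post
}

#' Summarize a set of stochastic maps
#'
#' Computes, across maps on a common tree: the mean count of each ordered
#' state transition (12 types for the four NHEJ states) and its relative
#' frequency, the expected total time spent in each state (summing to the
#' total tree length), and per-internal-node state posteriors (node-state
#' frequencies across maps).
#'
#' @param maps list of `"stochastic_map"` objects on the same tree (a single
#'   map is accepted).
#' @return An object of class `"map_summary"`.
#' @export
summarize_maps <- function(maps) {
  if (inherits(maps, "stochastic_map")) maps <- list(maps)
  if (!length(maps)) stop("no maps to summarize")
  tr <- maps[[1]]$tree
  states <- maps[[1]]$states
  for (m in maps) {
    if (!identical(m$tree$edge, tr$edge) ||
        !isTRUE(all.equal(m$tree$edge.length, tr$edge.length)) ||
        !identical(m$tree$tip.label, tr$tip.label))
      stop("all maps must be on the same tree")
  }
  k <- length(states)
  n_maps <- length(maps)
  counts <- matrix(0, k, k, dimnames = list(states, states))
  time_in <- setNames(numeric(k), states)
  ntip <- ape::Ntip(tr)
  ntot <- ntip + tr$Nnode
  node_freq <- matrix(0, tr$Nnode, k,
                      dimnames = list(as.character((ntip + 1):ntot), states))
  for (m in maps) {
    for (em in m$edge_maps) {
      si <- match(em$state, states)
      tw <- tapply(em$dwell, factor(si, levels = seq_len(k)), sum,
                   default = 0)
      time_in <- time_in + as.vector(tw)
      if (length(si) > 1) {
        from <- si[-length(si)]; to <- si[-1]
        for (i in seq_along(from))
          counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
      }
    }
    ns <- match(m$node_states[(ntip + 1):ntot], states)
    node_freq[cbind(seq_len(tr$Nnode), ns)] <-
      node_freq[cbind(seq_len(tr$Nnode), ns)] + 1
  }
  mean_counts <- counts / n_maps
  tot <- sum(mean_counts)
  out <- list(tree = tr, states = states, n_maps = n_maps,
              mean_counts = mean_counts,
              rel_freq = if (tot > 0) mean_counts / tot else mean_counts,
              time_in_state = time_in / n_maps,
              node_posteriors = node_freq / n_maps)
  class(out) <- "map_summary"
  out
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Summary of", x$n_maps, "stochastic map(s),", length(x$states),
      "states\n")
  cat("mean transition counts:\n")
  print(round(x$mean_counts, 3))
  cat("expected time in state:\n")
  print(round(x$time_in_state, 4))
  invisible(x)
}

#' Call node states from posterior probabilities
#'
#' A node is assigned its argmax state only when that state's posterior
#' probability strictly exceeds `threshold` (the display rule "support
#' > 70%"); otherwise it is left uncalled (`NA`).
#'
#' @param summary a `"map_summary"` (or a bare matrix of node posteriors).
#' @param threshold posterior-probability cutoff (strict; default 0.7).
#' @return Named character vector over internal nodes; `NA` = uncalled.
#' @export
call_node_states <- function(summary, threshold = 0.7) {
  post <- if (inherits(summary, "map_summary")) summary$node_posteriors
  else summary
  states <- colnames(post)
  idx <- max.col(post, ties.method = "first")
  pp <- post[cbind(seq_len(nrow(post)), idx)]
  out <- ifelse(pp > threshold, states[idx], NA_character_)
  setNames(out, rownames(post))
}

# internal: vector of ancestor node numbers (root first) for a node
node_ancestors <- function(tree, node) {
  root <- ape::Ntip(tree) + 1L
  anc <- integer(0)
  cur <- node
  while (cur != root) {
    cur <- tree$edge[tree$edge[, 2] == cur, 1]
    anc <- c(cur, anc)
  }
  anc
}

#' Identify major primary gains of NHEJ on the tree
#'
#' An internal node is reported as a major primary gain when (1) every node
#' on the path from the root to its parent is called `NHEJ_minus`; (2) the
#' posterior probability of `NHEJ_plus`, `LigD_only` or `Ku_only` at the node
#' is at least `pp_threshold`; (3) a gain of `LigD_only` or `Ku_only` is
#' followed somewhere among its descendants by a transition to `NHEJ_plus`
#' (a called descendant node, or -- when `tip_states` is supplied -- a
#' descendant tip in the `NHEJ_plus` state); and (4) the node has at least
#' `min_desc` descendant tips.
#'
#' @param tree rooted `"phylo"` object (postorder tree from the map summary).
#' @param calls node calls from [call_node_states()].
#' @param posteriors matrix of node posteriors (rownames = node numbers).
#' @param min_desc minimum number of descendant tips (default 3).
#' @param pp_threshold inclusive posterior threshold for the gain (default
#'   0.7).
#' @param tip_states optional named tip-state vector used for criterion (3).
#' @param minus_state,plus_state,component_states state labels; defaults
#'   match the four-state NHEJ alphabet.
#' @return `data.frame` with columns `node`, `gained_state`,
#'   `n_descendant_tips`, `pp`.
#' @export
find_primary_gains <- function(tree, calls, posteriors, min_desc = 3,
                               pp_threshold = 0.7, tip_states = NULL,
                               minus_state = "NHEJ_minus",
                               plus_state = "NHEJ_plus",
                               component_states = c("Ku_only", "LigD_only")) {
  if (!ape::is.rooted(tree)) stop("find_primary_gains() needs a rooted tree")
  ntip <- ape::Ntip(tree)
  gain_states <- c(plus_state, component_states)
  rows <- list()
  for (nd_chr in rownames(posteriors)) {
    nd <- as.integer(nd_chr)
    pps <- posteriors[nd_chr, intersect(gain_states, colnames(posteriors))]
    ok <- pps[pps >= pp_threshold]
    if (!length(ok)) next
    gained <- names(ok)[which.max(ok)]
    anc <- node_ancestors(tree, nd)
    anc_calls <- calls[as.character(anc)]
    if (length(anc) &&
        !all(!is.na(anc_calls) & anc_calls == minus_state)) next
    desc_tips <- phangorn::Descendants(tree, nd, type = "tips")[[1]]
    if (length(desc_tips) < min_desc) next
    if (gained %in% component_states) {
      desc_nodes <- setdiff(phangorn::Descendants(tree, nd, type = "all"),
                            seq_len(ntip))
      node_hit <- any(!is.na(calls[as.character(desc_nodes)]) &
                        calls[as.character(desc_nodes)] == plus_state)
      tip_hit <- if (!is.null(tip_states))
        any(tip_states[tree$tip.label[desc_tips]] == plus_state,
            na.rm = TRUE) else FALSE
      if (!node_hit && !tip_hit) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      node = nd, gained_state = gained,
      n_descendant_tips = length(desc_tips),
      pp = unname(ok[which.max(ok)]), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(node = integer(0), gained_state = character(0),
                      n_descendant_tips = integer(0), pp = numeric(0)))
  do.call(rbind, rows)
}
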