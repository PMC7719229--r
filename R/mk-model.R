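#' Free-rate structure of an Mk rate matrix
#'
#' Returns the k x k integer index matrix defining which off-diagonal entries
#' of the generator share a free rate: `ER` ties all transitions to a single
#' rate, `SYM` gives one rate per unordered state pair (k(k-1)/2 rates) and
#' `ARD` one rate per ordered pair (k(k-1) rates; 12 transition types for the
#' four NHEJ states). Zero entries (the diagonal, or forbidden transitions in
#' custom structures) carry no free rate.
#'
#' @param k number of states.
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @return Integer k x k matrix with groups `1..m` off the diagonal.
#' @export
mk_structure <- function(k, structure = c("ER", "SYM", "ARD")) {
  structure <- match.arg(structure)
  idx <- matrix(0L, k, k)
  if (structure == "ER") {
    idx[row(idx) != col(idx)] <- 1L
  } else if (structure == "SYM") {
    g <- 0L
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      g <- g + 1L
      idx[i, j] <- g
      idx[j, i] <- g
    }
  } else {
    idx[row(idx) != col(idx)] <- seq_len(k * (k - 1))
  }
  idx
}

#' Build a generator from a structure index and free rates
#'
#' @param index integer k x k structure matrix (see [mk_structure()]); entry
#'   `g > 0` means "free rate number g", entry 0 off the diagonal means the
#'   transition is forbidden (rate 0).
#' @param rates numeric vector of free rates, length `max(index)`.
#' @param states optional state names used as dimnames.
#' @return A k x k generator with zero row sums.
#' @export
build_rate_matrix <- function(index, rates, states = NULL) {
  k <- nrow(index)
  m <- max(index)
  stopifnot(ncol(index) == k, length(rates) == m, all(rates >= 0))
  Q <- matrix(0, k, k)
  off <- index > 0
  Q[off] <- rates[index[off]]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (!is.null(states)) dimnames(Q) <- list(states, states)
  Q
}

# validate that Q is a CTMC generator
check_generator <- function(Q) {
  k <- nrow(Q)
  if (ncol(Q) != k) stop("Q must be square")
  off <- Q[row(Q) != col(Q)]
  if (any(off < -1e-12)) stop("Q has negative off-diagonal entries")
  if (any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))))
    stop("Q rows must sum to zero (not a generator)")
  invisible(TRUE)
}

# edge bookkeeping: tree in postorder with 1-based child/parent vectors
postorder_edges <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  list(tree = tr,
       child = tr$edge[, 2], parent = tr$edge[, 1],
       elen = tr$edge.length,
       ntip = ape::Ntip(tr), nnode = tr$Nnode)
}

# tip conditional-likelihood matrix; NA states are fully ambiguous
tip_partials <- function(tip_states, tip_labels, states) {
  miss <- setdiff(tip_labels, names(tip_states))
  if (length(miss))
    stop("tip(s) without an assigned state: ", paste(miss, collapse = ", "))
  x <- tip_states[tip_labels]
  bad <- !is.na(x) & !(x %in% states)
  if (any(bad))
    stop("tip state(s) outside the state set: ",
         paste(unique(x[bad]), collapse = ", "))
  L <- matrix(0, length(x), length(states))
  for (i in seq_along(x)) {
    if (is.na(x[i])) L[i, ] <- 1 else L[i, match(x[i], states)] <- 1
  }
  L
}

# resolve a root prior specification to a probability vector
root_prior_vec <- function(root_prior, root_L, Q, states) {
  k <- length(states)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k)
    if (abs(sum(root_prior) - 1) > 1e-8)
      stop("numeric root prior must sum to 1")
    return(root_prior)
  }
  switch(match.arg(root_prior, c("fitzjohn", "flat", "stationary")),
    fitzjohn = {
      s <- sum(root_L)
      if (s <= 0) rep(1 / k, k) else root_L / s
    },
    flat = rep(1 / k, k),
    stationary = {
      ev <- eigen(t(Q))
      i <- which.min(abs(ev$values))
      v <- abs(Re(ev$vectors[, i]))
      v / sum(v)
    })
}

# internal: run the C++ pruning pass; states taken from Q dimnames
mk_prune <- function(tree, tip_states, Q, return_P = FALSE) {
  states <- colnames(Q)
  if (is.null(states)) stop("Q must carry state names as dimnames")
  po <- postorder_edges(tree)
  if (any(po$elen < 0)) stop("negative branch lengths")
  tipL <- tip_partials(tip_states, po$tree$tip.label, states)
  res <- mk_pruning_cpp(po$child, po$parent, po$elen, tipL, unname(Q),
                        po$nnode, return_P)
  res$po <- po
  res$states <- states
  res
}

#' Mk log-likelihood of tip states on a phylogeny
#'
#' Felsenstein pruning likelihood of a discrete character under a
#' continuous-time Markov generator `Q`, with transition matrices
#' `expm(Q * t)` per branch and the root handled by the chosen prior.
#' `"fitzjohn"` (default) weighs root states by their normalized conditional
#' likelihoods; `"flat"` and `"stationary"` are also available, or a numeric
#' probability vector.
#'
#' @param tree a `"phylo"` object with nonnegative branch lengths.
#' @param tip_states named vector of states (names = tip labels); `NA` marks
#'   an ambiguous tip.
#' @param Q generator with state names as dimnames.
#' @param root_prior `"fitzjohn"`, `"flat"`, `"stationary"` or a probability
#'   vector over the states.
#' @return The log-likelihood (finite for valid inputs).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "fitzjohn") {
  check_generator(Q)
  pr <- mk_prune(tree, tip_states, Q)
  root_row <- pr$po$ntip + 1L
  root_L <- pr$partials[root_row, ]
  pi0 <- root_prior_vec(root_prior, root_L, Q, pr$states)
  ll <- log(sum(pi0 * root_L)) + pr$logscale
  if (!is.finite(ll)) stop("non-finite Mk log-likelihood")
  ll
}

#' Maximum-likelihood fit of an Mk model
#'
#' Maximizes the pruning likelihood over the free rates of an `ER`, `SYM`,
#' `ARD` or custom structure, by box-constrained quasi-Newton optimization on
#' log-rates with a deterministic multi-start schedule (no RNG). Rates are
#' bounded in `rate_bounds` per unit branch length.
#'
#' @inheritParams mk_loglik
#' @param structure `"ER"`, `"SYM"`, `"ARD"`, or a custom integer index
#'   matrix as in [build_rate_matrix()].
#' @param states state alphabet; defaults to the sorted unique tip states
#'   (required explicitly if some states are unobserved).
#' @param n_starts number of optimizer starts (deterministic schedule).
#' @param init optional list of extra starting rate vectors tried first.
#' @param rate_bounds lower/upper bounds on each rate.
#' @param control passed to [stats::optim()] (`factr` trades accuracy for
#'   speed).
#' @return An object of class `"mk_fit"`: rate matrix, rates, structure
#'   index, log-likelihood, number of free parameters, AIC and the resolved
#'   root prior.
#' @export
fit_mk <- function(tree, tip_states, structure = "ARD", states = NULL,
                   root_prior = "fitzjohn", n_starts = 5, init = NULL,
                   rate_bounds = c(1e-8, 1e3),
                   control = list(maxit = 500, factr = 1e8)) {
  if (is.null(states))
    states <- sort(unique(stats::na.omit(as.character(tip_states))))
  k <- length(states)
  if (k < 2) stop("need at least 2 states to fit an Mk model")
  index <- if (is.matrix(structure)) structure else mk_structure(k, structure)
  m <- max(index)
  po <- postorder_edges(tree)
  tipL <- tip_partials(tip_states, po$tree$tip.label, states)

  nll <- function(logr) {
    Q <- build_rate_matrix(index, exp(logr))
    res <- mk_pruning_cpp(po$child, po$parent, po$elen, tipL, Q, po$nnode,
                          FALSE)
    root_L <- res$partials[po$ntip + 1L, ]
    pi0 <- root_prior_vec(root_prior, root_L, Q, states)
    ll <- log(sum(pi0 * root_L)) + res$logscale
    if (!is.finite(ll)) 1e10 else -ll
  }

  r0 <- max(rate_bounds[1] * 10, min(rate_bounds[2] / 10,
                                     po$ntip / sum(po$elen)))
  mults <- c(0.1, 0.5, 0.02, 1, 5, 0.005, 20)
  starts <- c(init,
              if (n_starts > 0)
                lapply(mults[seq_len(min(n_starts, length(mults)))],
                       function(f) rep(r0 * f, m)))
  if (!length(starts)) stop("no starting values (n_starts = 0 needs init)")
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  best <- NULL
  for (s in starts) {
    p0 <- pmin(pmax(log(s), lb), ub)
    fit <- tryCatch(
      optim(p0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = control),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("Mk optimization failed to produce a finite likelihood from any start")
  if (best$convergence != 0)
    warning("Mk optimizer did not report clean convergence (code ",
            best$convergence, "); returning best solution found")
  rates <- exp(best$par)
  Q <- build_rate_matrix(index, rates, states)
  res <- mk_pruning_cpp(po$child, po$parent, po$elen, tipL, unname(Q),
                        po$nnode, FALSE)
  root_L <- res$partials[po$ntip + 1L, ]
  pi0 <- root_prior_vec(root_prior, root_L, Q, states)
  ll <- log(sum(pi0 * root_L)) + res$logscale
  structure_name <- if (is.matrix(structure)) "custom" else structure
  out <- list(rate_matrix = Q, rates = rates, index = index, states = states,
              loglik = ll, n_params = m, aic = 2 * m - 2 * ll,
              root_prior = pi0, structure = structure_name,
              convergence = best$convergence, n_tips = po$ntip)
  class(out) <- "mk_fit"
  out
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$structure, "), k = ", length(x$states),
      " states, ", x$n_params, " free rate(s)\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 6),
      "  AIC:", format(x$aic, digits = 6), "\n")
  cat("  rates:", paste(format(x$rates, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Akaike weights for a set of model fits
#'
#' `w_i = exp(-(AIC_i - min AIC)/2)`, normalized to sum to 1.
#'
#' @param fits list of `"mk_fit"` objects (or anything with an `aic` field),
#'   or a numeric vector of AIC values.
#' @return Numeric vector of weights (named like the input).
#' @export
aic_weights <- function(fits) {
  aic <- if (is.numeric(fits)) fits
  else vapply(fits, function(f) f$aic, numeric(1))
  if (length(aic) < 2) stop("need at least 2 fits to compare")
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}
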