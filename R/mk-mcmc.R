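#' Posterior sampling of the Mk rate matrix
#'
#' Metropolis--Hastings over the free log-rates of an Mk structure, with the
#' pruning likelihood as target and independent exponential priors on the
#' natural-scale rates (mean defaulting to the ML estimate of each rate
#' group). Proposals are joint Gaussian random walks on log-rates whose scale
#' is adapted toward ~30% acceptance during burn-in; after burn-in the chain
#' is thinned to `n_samples` draws. Fully reproducible given `seed`.
#'
#' @inheritParams fit_mk
#' @param n_samples number of retained posterior draws.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param burnin fraction of the total chain discarded as burn-in.
#' @param seed RNG seed (required for reproducibility).
#' @param prior_mean exponential prior mean per rate group; default: the ML
#'   estimate (floored at 1e-4).
#' @param mle optional precomputed `"mk_fit"` used for the prior and the
#'   chain start.
#' @return An object of class `"mk_posterior"`: `samples` (n x m matrix of
#'   rates), `Q` (list of generators), the structure index, states, and the
#'   realized acceptance rate.
#' @export
sample_q_posterior <- function(tree, tip_states, structure = "ARD",
                               states = NULL, root_prior = "fitzjohn",
                               n_samples = 1000, thin = 5, burnin = 0.1,
                               seed = NULL, prior_mean = NULL, mle = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(states))
    states <- sort(unique(stats::na.omit(as.character(tip_states))))
  k <- length(states)
  index <- if (is.matrix(structure)) structure else mk_structure(k, structure)
  m <- max(index)
  po <- postorder_edges(tree)
  tipL <- tip_partials(tip_states, po$tree$tip.label, states)

  loglik <- function(logr) {
    Q <- build_rate_matrix(index, exp(logr))
    res <- mk_pruning_cpp(po$child, po$parent, po$elen, tipL, Q, po$nnode,
                          FALSE)
    root_L <- res$partials[po$ntip + 1L, ]
    pi0 <- root_prior_vec(root_prior, root_L, Q, states)
    ll <- log(sum(pi0 * root_L)) + res$logscale
    if (!is.finite(ll)) -Inf else ll
  }

  if (is.null(prior_mean)) {
    if (is.null(mle))
      mle <- fit_mk(tree, tip_states, structure = index, states = states,
                    root_prior = root_prior, n_starts = 3)
    prior_mean <- pmax(mle$rates, 1e-4)
  }
  prior_mean <- rep_len(prior_mean, m)
  # log posterior on the log-rate scale (includes the Jacobian sum(log r))
  lpost <- function(logr) {
    r <- exp(logr)
    loglik(logr) + sum(dexp(r, rate = 1 / prior_mean, log = TRUE)) + sum(logr)
  }

  cur <- log(if (!is.null(mle)) pmax(mle$rates, 1e-8) else prior_mean)
  cur_lp <- lpost(cur)
  n_iter <- n_samples * thin
  n_burn <- ceiling(burnin * n_iter / (1 - burnin))
  total <- n_burn + n_iter
  scale <- 0.3
  samples <- matrix(NA_real_, n_samples, m)
  acc <- 0L; acc_win <- 0L; kept <- 0L
  for (it in seq_len(total)) {
    prop <- cur + rnorm(m, 0, scale)
    prop_lp <- lpost(prop)
    if (is.finite(prop_lp) && log(runif(1)) < prop_lp - cur_lp) {
      cur <- prop; cur_lp <- prop_lp
      acc <- acc + 1L; acc_win <- acc_win + 1L
    }
    if (it <= n_burn && it %% 50 == 0) {  # adapt during burn-in only
      rate <- acc_win / 50
      if (rate > 0.45) scale <- scale * 1.4
      if (rate < 0.15) scale <- scale / 1.4
      acc_win <- 0L
    }
    if (it > n_burn && (it - n_burn) %% thin == 0) {
      kept <- kept + 1L
      samples[kept, ] <- exp(cur)
    }
  }
  acc_rate <- acc / total
  if (acc_rate < 0.05 || acc_rate > 0.8)
    warning("MCMC acceptance rate ", round(acc_rate, 3),
            " outside [0.05, 0.8] after adaptation")
  Qs <- lapply(seq_len(n_samples), function(i)
    build_rate_matrix(index, samples[i, ], states))
  out <- list(samples = samples, Q = Qs, index = index, states = states,
              acceptance = acc_rate, prior_mean = prior_mean,
              n_samples = n_samples, thin = thin, n_burn = n_burn)
  class(out) <- "mk_posterior"
  out
}

#' @export
print.mk_posterior <- function(x, ...) {
  cat("Mk posterior:", x$n_samples, "draws of", ncol(x$samples),
      "rate(s); acceptance", round(x$acceptance, 3), "\n")
  invisible(x)
}
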