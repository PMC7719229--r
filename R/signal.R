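# profile Gaussian log-likelihood of tip values under covariance sigma2 * C,
# with the mean and sigma2 profiled out analytically
bm_profile_loglik <- function(x, C) {
  n <- length(x)
  U <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-10, n)))
  logdet <- 2 * sum(log(diag(U)))
  one <- rep(1, n)
  Ci_x <- backsolve(U, forwardsolve(t(U), x))
  Ci_1 <- backsolve(U, forwardsolve(t(U), one))
  mu <- sum(Ci_x) / sum(Ci_1)
  r <- x - mu
  q <- sum(r * backsolve(U, forwardsolve(t(U), r)))
  s2 <- q / n
  list(loglik = -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n),
       mu = mu, sigma2 = s2)
}

#' Pagel's lambda for a continuous trait
#'
#' Maximum-likelihood estimate of the branch-length transformation
#' `lambda` under Brownian motion (internal shared paths scaled by lambda,
#' tip depths untouched), with a likelihood-ratio test against `lambda = 0`
#' (no phylogenetic signal).
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param x named numeric tip values.
#' @param lambda_max upper bound of the search; default is the largest value
#'   keeping the transformed covariance positive definite (at least 1).
#' @return List with `lambda`, `loglik`, `loglik0` (at lambda = 0), `p_value`
#'   (chi-square, 1 df) and `sigma2`.
#' @export
pagel_lambda <- function(tree, x, lambda_max = NULL) {
  ntip <- ape::Ntip(tree)
  if (is.null(names(x))) {
    stopifnot(length(x) == ntip)
    names(x) <- tree$tip.label
  }
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("missing tip values")
  if (var(x) == 0) stop("constant trait: phylogenetic signal is undefined")
  C <- bm_vcv(tree)
  off <- C[row(C) != col(C)]
  if (max(off) <= 0) {
    warning("star tree: lambda is unidentifiable (flat likelihood)")
  }
  if (is.null(lambda_max)) {
    lambda_max <- if (max(off) > 0)
      max(1, min(diag(C)) / max(off)) else 1
  }
  obj <- function(lam) bm_profile_loglik(x, bm_vcv(tree, lam))$loglik
  opt <- optimize(obj, c(0, lambda_max), maximum = TRUE, tol = 1e-8)
  # guard the boundaries (optimize never evaluates the endpoints)
  cands <- c(opt$maximum, 0, lambda_max)
  lls <- c(opt$objective, obj(0), obj(lambda_max))
  best <- which.max(lls)
  lam <- cands[best]
  fit <- bm_profile_loglik(x, bm_vcv(tree, lam))
  ll0 <- obj(0)
  lr <- max(0, 2 * (fit$loglik - ll0))
  list(lambda = lam, loglik = fit$loglik, loglik0 = ll0,
       p_value = pchisq(lr, df = 1, lower.tail = FALSE),
       sigma2 = fit$sigma2)
}

#' Blomberg's K for a continuous trait
#'
#' `K` is the observed ratio of the non-phylogenetic to the phylogenetic mean
#' squared error (both about the GLS phylogenetic mean), divided by its
#' Brownian-motion expectation on the same tree; `K = 1` is the Brownian
#' calibration point. The p-value is from tip-label permutations of the
#' variance ratio, with the `(1 + exceedances) / (1 + n_perm)` estimator.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param x named numeric tip values.
#' @param n_perm number of permutations for the significance test (0 skips
#'   it).
#' @param seed RNG seed for the permutations.
#' @return List with `K`, `p_value`, `n_perm`.
#' @export
blomberg_k <- function(tree, x, n_perm = 1000, seed = NULL) {
  ntip <- ape::Ntip(tree)
  if (is.null(names(x))) {
    stopifnot(length(x) == ntip)
    names(x) <- tree$tip.label
  }
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("missing tip values")
  if (var(x) == 0) stop("constant trait: phylogenetic signal is undefined")
  C <- bm_vcv(tree)
  n <- ntip
  U <- chol(C)
  Ci <- chol2inv(U)
  one <- rep(1, n)
  denom_exp <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  ratio <- function(v) {
    mu <- sum(Ci %*% v) / sum(Ci)
    r <- v - mu
    mse0 <- sum(r^2) / (n - 1)
    mse <- as.numeric(t(r) %*% Ci %*% r) / (n - 1)
    mse0 / mse
  }
  obs <- ratio(x)
  K <- obs / denom_exp
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm))
      if (ratio(sample(x)) >= obs) exceed <- exceed + 1L
    p <- (1 + exceed) / (1 + n_perm)
  }
  list(K = K, p_value = p, n_perm = n_perm)
}
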