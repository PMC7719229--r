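# Brownian-motion covariance of tip values, optionally lambda-transformed
# (off-diagonal shared path lengths scaled by lambda, tip depths untouched)
bm_vcv <- function(tree, lambda = NULL) {
  C <- ape::vcv(tree)
  if (!is.null(lambda)) {
    d <- diag(C)
    C <- lambda * C
    diag(C) <- d
  }
  C
}

#' Ancestral reconstruction of a continuous trait under Brownian motion
#'
#' Maximum-likelihood (generalized least squares) estimates of internal-node
#' values: the joint-ML solution minimizes the sum of squared per-branch
#' changes weighted by inverse branch length, so the root estimate equals the
#' GLS phylogenetic mean. Variances are the conditional variances of the node
#' values given the tips, scaled by the ML estimate of the Brownian rate
#' (computed from phylogenetically independent contrasts).
#'
#' @param tree a `"phylo"` object with positive branch lengths.
#' @param x named numeric vector of tip values (names = tip labels).
#' @return A list with `estimates` and `variances` (named by node number,
#'   root = Ntip + 1) and `sigma2` (ML Brownian rate).
#' @export
brownian_ancestral <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (is.null(names(x))) {
    stopifnot(length(x) == ntip)
    names(x) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop("tip(s) without a value: ", paste(miss, collapse = ", "))
  x <- x[tree$tip.label]
  ntot <- ntip + tree$Nnode
  nodes <- (ntip + 1):ntot
  w <- 1 / tree$edge.length
  if (any(!is.finite(w))) stop("branch lengths must be strictly positive")
  # weighted-Laplacian linear system over internal nodes:
  # minimize sum_e (x_child - x_parent)^2 / t_e
  ii <- jj <- integer(0); vv <- numeric(0)
  b <- numeric(tree$Nnode)
  deg <- numeric(tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - ntip
    ch <- tree$edge[e, 2]
    deg[p] <- deg[p] + w[e]
    if (ch <= ntip) {
      b[p] <- b[p] + w[e] * x[ch]
    } else {
      chn <- ch - ntip
      deg[chn] <- deg[chn] + w[e]
      ii <- c(ii, p, chn); jj <- c(jj, chn, p); vv <- c(vv, -w[e], -w[e])
    }
  }
  ii <- c(ii, seq_len(tree$Nnode)); jj <- c(jj, seq_len(tree$Nnode))
  vv <- c(vv, deg)
  Lap <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                              dims = c(tree$Nnode, tree$Nnode))
  est <- as.vector(Matrix::solve(Lap, b))
  # contrasts need a binary tree; eps-resolve polytomies for the rate only
  btree <- if (tree$Nnode == ntip - 1) tree
  else resolve_polytomies(tree, 1e-8)
  pic <- ape::pic(x, btree, scaled = TRUE)
  sigma2 <- sum(pic^2) / ntip  # ML rate
  Vc <- sigma2 * diag(as.matrix(Matrix::solve(Lap)))
  list(estimates = setNames(est, as.character(nodes)),
       variances = setNames(Vc, as.character(nodes)),
       sigma2 = sigma2)
}

#' Simulate a continuous trait under (lambda-scaled) Brownian motion
#'
#' Without `lambda` the trait is evolved branch-by-branch (preorder, pure
#' recursion, no covariance matrix). With `lambda` the tips are drawn from
#' the multivariate normal with the lambda-transformed Brownian covariance
#' (internal shared paths scaled, tip depths untouched), so `lambda = 0`
#' yields i.i.d. normals with variance `sigma2 * depth`.
#'
#' @param tree a `"phylo"` object.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param root root value (default 0).
#' @param seed RNG seed.
#' @param lambda optional Pagel's lambda in `[0, 1]`.
#' @return Named numeric vector of tip values.
#' @export
simulate_brownian <- function(tree, sigma2, root = 0, seed = NULL,
                              lambda = NULL) {
  stopifnot(sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  if (!is.null(lambda)) {
    stopifnot(lambda >= 0, lambda <= 1)
    C <- bm_vcv(tree, lambda) * sigma2
    U <- chol(C + diag(1e-12, ntip))
    x <- root + as.vector(t(U) %*% rnorm(ntip))
    return(setNames(x, rownames(C)))
  }
  tr <- stats::reorder(tree, "postorder")
  ntot <- ntip + tr$Nnode
  val <- numeric(ntot)
  val[ntip + 1L] <- root
  ne <- nrow(tr$edge)
  steps <- rnorm(ne, 0, sqrt(sigma2 * tr$edge.length))
  for (e in rev(seq_len(ne)))  # preorder
    val[tr$edge[e, 2]] <- val[tr$edge[e, 1]] + steps[e]
  setNames(val[seq_len(ntip)], tr$tip.label)
}
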