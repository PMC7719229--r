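#' Mantel test between two distance matrices
#'
#' Pearson correlation between the lower triangles, with significance from
#' joint row/column permutations of the second matrix. The one-tailed
#' (greater) p-value uses the `(1 + exceedances) / (1 + n_perm)` estimator;
#' with `exact = TRUE` all `n!` permutations are enumerated instead and the
#' p-value is the exact fraction of permutations (identity included) with
#' `r >= r_obs`. Labels are intersected between the matrices (the shared
#' count is reported via a message).
#'
#' @param D1,D2 symmetric, zero-diagonal distance matrices with dimnames.
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed.
#' @param exact enumerate all permutations (shared labels <= 8 only).
#' @param quiet suppress the shared-label message.
#' @return List with `r`, `p_value`, `n_shared`, `n_perm`, `exact`.
#' @export
mantel_test <- function(D1, D2, n_perm = 10000, seed = NULL, exact = FALSE,
                        quiet = FALSE) {
  if (is.null(dimnames(D1)) || is.null(dimnames(D2)))
    stop("distance matrices need dimnames")
  shared <- intersect(rownames(D1), rownames(D2))
  if (length(shared) < 4)
    stop("fewer than 4 shared labels between the matrices")
  if (!quiet)
    message("Mantel test on ", length(shared), " shared labels")
  A <- D1[shared, shared]
  B <- D2[shared, shared]
  if (max(abs(A - t(A))) > 1e-8 || max(abs(B - t(B))) > 1e-8)
    stop("distance matrices must be symmetric")
  n <- length(shared)
  lt <- lower.tri(A)
  a <- A[lt]
  r_obs <- cor(a, B[lt])
  if (exact) {
    if (n > 8) stop("exact enumeration limited to 8 labels")
    perms <- all_permutations(n)
    rs <- vapply(perms, function(p) cor(a, B[p, p][lt]), numeric(1))
    return(list(r = r_obs, p_value = mean(rs >= r_obs - 1e-12),
                n_shared = n, n_perm = length(perms), exact = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (cor(a, B[p, p][lt]) >= r_obs - 1e-12) exceed <- exceed + 1L
  }
  list(r = r_obs, p_value = (1 + exceed) / (1 + n_perm), n_shared = n,
       n_perm = n_perm, exact = FALSE)
}

# all permutations of 1..n (n small), in lexicographic order
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  i <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[s])
    }
  }
  out
}

#' Gene-pool genome-size randomization null
#'
#' Emulates drawing `n_pick` genes uniformly at random from the pool of all
#' genes across genomes (so a genome is sampled with probability
#' proportional to its gene count), recording a per-genome value for each
#' drawn gene and taking the median; repeated `n_iter` times to give a null
#' distribution of medians. When an observed sample is supplied, it is
#' compared against the null medians with a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param cds_counts named integer vector: genes per genome (the pool
#'   weights).
#' @param n_pick genes drawn per iteration.
#' @param n_iter iterations (default 100).
#' @param seed RNG seed.
#' @param genome_values value recorded per draw (named like `cds_counts`);
#'   defaults to `cds_counts` itself (CDS count as the genome-size proxy).
#' @param observed optional observed sample (e.g. genome sizes of
#'   conventional-NHEJ genomes) to compare against the null medians.
#' @param replace sample genes with replacement within an iteration
#'   (default `FALSE`: distinct genes, as in drawing real genes).
#' @return List with `medians` (length `n_iter`), and when `observed` is
#'   given, `wilcoxon` (from [wilcoxon_compare()]).
#' @export
gs_randomization <- function(cds_counts, n_pick, n_iter = 100, seed = NULL,
                             genome_values = NULL, observed = NULL,
                             replace = FALSE) {
  stopifnot(n_pick >= 1, all(cds_counts >= 0))
  if (sum(cds_counts) == 0) stop("empty gene pool")
  if (is.null(genome_values)) genome_values <- cds_counts
  stopifnot(length(genome_values) == length(cds_counts))
  if (!replace && n_pick > sum(cds_counts))
    stop("n_pick exceeds the pool size")
  if (!is.null(seed)) set.seed(seed)
  pool <- rep(seq_along(cds_counts), cds_counts)
  med <- numeric(n_iter)
  for (b in seq_len(n_iter)) {
    idx <- sample(pool, n_pick, replace = replace)
    med[b] <- median(genome_values[idx])
  }
  out <- list(medians = med, n_pick = n_pick, n_iter = n_iter)
  if (!is.null(observed)) {
    out$observed_median <- median(observed)
    out$wilcoxon <- wilcoxon_compare(med, observed)
  }
  out
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided rank-sum test: exact when the smaller sample has at most 10
#' observations and there are no ties, otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param a,b numeric samples (non-empty).
#' @return List with `W`, `p_value`, `exact`.
#' @export
wilcoxon_compare <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= 10 && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = use_exact,
                                     correct = TRUE))
  list(W = unname(ht$statistic), p_value = ht$p.value, exact = use_exact)
}
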