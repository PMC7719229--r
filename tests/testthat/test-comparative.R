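test_that("binarize applies the mean and median_le rules", {
  b1 <- binarize(c(1, 2, 3, 10), "mean")
  expect_equal(b1$bits, c(0L, 0L, 0L, 1L))
  expect_equal(b1$threshold, 4)
  # rRNA copies: slow iff <= median
  b2 <- binarize(c(2, 3, 3, 8), "median_le")
  expect_equal(b2$bits, c(0L, 0L, 0L, 1L))
  # all equal under the mean rule: none strictly below the mean
  expect_equal(binarize(rep(2, 5), "mean")$bits, rep(1L, 5))
})

test_that("VIF follows 1/(1 - R^2) and flags collinearity", {
  X <- data.frame(a = c(1, -1, 1, -1, 1, -1, 1, -1),
                  b = c(1, 1, -1, -1, 1, 1, -1, -1))
  expect_equal(unname(vif(X)), c(1, 1))  # orthogonal predictors
  set.seed(61)
  X3 <- data.frame(matrix(rnorm(300), 100, 3))
  skip_if_not_installed("car")
  cv <- car::vif(lm(rnorm(100) ~ ., data = X3))
  expect_lt(max(abs(vif(X3) - cv)), 1e-8)
  expect_error(vif(data.frame(a = rnorm(5), z = rep(1, 5))),
               "zero-variance")
  Xd <- data.frame(a = rnorm(20))
  Xd$b <- 2 * Xd$a
  expect_true(is.infinite(vif(Xd)["a"]))
})

test_that("correlated-evolution models have the stated free-rate structure", {
  st <- pagel_structures()
  expect_equal(max(st$dependent), 8)
  expect_equal(max(st$independent), 4)
  expect_equal(sum(st$dependent > 0), 8)
  # double transitions forbidden in both structures
  forb <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2))
  expect_true(all(st$dependent[forb] == 0))
  expect_true(all(st$independent[forb] == 0))
  set.seed(62)
  tr <- simulate_tree(150, 1)
  pair <- simulate_correlated_pair(tr, simulation_config()$dependent_Q,
                                   seed = 5)
  ce <- correlated_evolution(tr, pair$trait_a, pair$trait_b)
  expect_equal(ce$df, 4)
  expect_equal(ce$dependent$n_params - ce$independent$n_params, 4)
  expect_gte(ce$dependent$loglik, ce$independent$loglik - 1e-6)
  expect_error(correlated_evolution(
    tr, setNames(rep(1L, 150), tr$tip.label), pair$trait_b), "constant")
})

test_that("phylogenetic ANOVA reduces to ordinary ANOVA on a star tree", {
  set.seed(63)
  n <- 60
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, n)
  x <- setNames(rnorm(n) + rep(c(0, 0.4), each = n / 2), star$tip.label)
  grp <- setNames(rep(c("a", "b"), each = n / 2), star$tip.label)
  pa <- phylo_anova(star, x, grp, n_sim = 2000, seed = 1)
  expect_lt(abs(pa$p_value - pa$p_anova), 0.04)
  # huge separation: p bottoms out at the permutation floor
  x2 <- setNames(c(rep(0, n / 2), rep(100, n / 2)), star$tip.label)
  x2 <- x2 + rnorm(n, 0, 1e-3)
  pa2 <- phylo_anova(star, x2, grp, n_sim = 500, seed = 2, posthoc = FALSE)
  expect_equal(pa2$p_value, 1 / 501)
  expect_error(phylo_anova(star, x, setNames(c("a", rep("b", n - 1)),
                                             star$tip.label)), "2 members")
})

test_that("phylo ANOVA post-hoc comparisons are Holm-adjusted", {
  set.seed(64)
  sim <- simulate_all(simulation_config(n_tips = 80), seed = 3)
  tr <- sim$tree
  lsz <- setNames(log10(sim$traits$genome_size_bp), sim$traits$genome_id)
  grp <- collapse_states(sim$states5)[names(lsz)]
  keep <- names(lsz)[grp %in% names(which(table(grp) >= 2))]
  pa <- phylo_anova(prune_to_taxa(tr, keep), lsz[keep], grp[keep],
                    n_sim = 300, seed = 4)
  expect_true(all(pa$posthoc$p_holm >= pa$posthoc$p_value - 1e-12))
  expect_true(all(pa$posthoc$p_holm <= 1))
})

test_that("phylogenetic logistic regression hits the ordinary-GLM limit", {
  set.seed(65)
  n <- 60
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, n)
  X <- data.frame(gs = rnorm(n), gr = rnorm(n),
                  row.names = star$tip.label)
  y <- setNames(rbinom(n, 1, plogis(-0.2 + X$gs)), star$tip.label)
  pf <- phylo_logistic_regression(star, y, X)
  g <- glm(y ~ gs + gr, data = X, family = binomial)
  expect_lt(max(abs(pf$coefficients - coef(g))), 1e-4)
  # duplicated predictor flagged before fitting
  Xd <- X; Xd$gs2 <- X$gs
  expect_error(phylo_logistic_regression(star, y, Xd), "collinear")
  # perfect separation diagnosed
  ysep <- setNames(as.integer(X$gs > 0), star$tip.label)
  expect_error(phylo_logistic_regression(star, ysep, X), "separation")
})

test_that("phyloglm recovers the sign of a strong effect on a real tree", {
  set.seed(66)
  tr <- simulate_tree(150, 1)
  X <- data.frame(gs = as.numeric(scale(simulate_brownian(tr, 1))),
                  row.names = tr$tip.label)
  y <- setNames(rbinom(150, 1, plogis(-0.5 + 1.5 * X$gs)), tr$tip.label)
  pf <- phylo_logistic_regression(tr, y, X)
  expect_gt(pf$coefficients["gs"], 0)
  expect_gt(pf$alpha, 0)
})

test_that("Wilcoxon comparisons match exhaustive enumeration", {
  w <- wilcoxon_compare(c(1, 2, 3), c(10, 11, 12))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1)  # 2/20 arrangements as extreme, two-sided

  # brute-force oracle: all C(n1+n2, n1) rank assignments
  brute_p <- function(a, b) {
    n1 <- length(a); N <- n1 + length(b)
    r <- rank(c(a, b))
    w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ws <- apply(utils::combn(N, n1), 2, function(ix)
      sum(sort(r)[ix]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  }
  set.seed(67)
  for (i in 1:8) {
    a <- sample(1:50, sample(3:6, 1))
    b <- sample(51:100, sample(3:6, 1)) - 50.5  # distinct, no ties
    expect_equal(wilcoxon_compare(a, b)$p_value, brute_p(a, b),
                 tolerance = 1e-12)
  }
  # identical samples sit at the null center
  expect_gt(wilcoxon_compare(c(1, 2, 3), c(1.1, 2.1, 2.9))$p_value, 0.5)
})
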