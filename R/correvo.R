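#' Rate structures of the correlated-evolution (Pagel) test
#'
#' On the product space `{00, 01, 10, 11}` of two binary traits, both models
#' forbid simultaneous double transitions (`00 <-> 11`, `01 <-> 10`). The
#' independent model ties each trait's gain/loss rate across the other
#' trait's background (4 free rates); the dependent model frees all eight
#' single-step transitions.
#'
#' @return List with integer index matrices `independent` (max group 4) and
#'   `dependent` (max group 8), and the `states` vector.
#' @export
pagel_structures <- function() {
  states <- c("00", "01", "10", "11")
  dep <- matrix(0L, 4, 4, dimnames = list(states, states))
  # allowed single-step transitions, in a fixed order
  steps <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 4),
                 c(3, 1), c(3, 4), c(4, 2), c(4, 3))
  dep[steps] <- seq_len(8)
  ind <- matrix(0L, 4, 4, dimnames = list(states, states))
  ind[1, 3] <- ind[2, 4] <- 1L  # trait A gain
  ind[3, 1] <- ind[4, 2] <- 2L  # trait A loss
  ind[1, 2] <- ind[3, 4] <- 3L  # trait B gain
  ind[2, 1] <- ind[4, 3] <- 4L  # trait B loss
  list(independent = ind, dependent = dep, states = states)
}

#' Pagel's test of correlated evolution of two binary traits
#'
#' Fits the independent (4-rate) and dependent (8-rate) continuous-time
#' Markov models on the product state space by maximum likelihood (the
#' dependent fit is warm-started from the independent solution, which
#' guarantees the nesting `loglik_dep >= loglik_indep`), and compares them
#' with a chi-square likelihood-ratio test on 4 degrees of freedom.
#'
#' @param tree a `"phylo"` object.
#' @param trait_a,trait_b named 0/1 vectors on the tree's tips.
#' @param root_prior root prior mode (see [mk_loglik()]).
#' @param n_starts optimizer starts for the independent model (the dependent
#'   model is always warm-started from the independent solution, plus
#'   `n_starts - 1` generic starts).
#' @return An object of class `"correvo"`: both fits, `lr`, `df = 4` and
#'   `p_value`.
#' @export
correlated_evolution <- function(tree, trait_a, trait_b,
                                 root_prior = "fitzjohn", n_starts = 2) {
  labs <- tree$tip.label
  a <- trait_a[labs]; b <- trait_b[labs]
  if (anyNA(a) || anyNA(b)) stop("both traits must cover all tips")
  if (!all(a %in% 0:1) || !all(b %in% 0:1)) stop("traits must be binary 0/1")
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("constant trait: transition rates are unidentifiable")
  st <- pagel_structures()
  tip_states <- setNames(paste0(a, b), labs)
  fit_ind <- fit_mk(tree, tip_states, structure = st$independent,
                    states = st$states, root_prior = root_prior,
                    n_starts = n_starts)
  # map the independent solution into the dependent parameterization
  warm <- numeric(8)
  off <- st$dependent > 0
  warm[st$dependent[off]] <- fit_ind$rates[st$independent[off]]
  fit_dep <- fit_mk(tree, tip_states, structure = st$dependent,
                    states = st$states, root_prior = root_prior,
                    n_starts = n_starts - 1, init = list(pmax(warm, 1e-8)))
  lr <- 2 * (fit_dep$loglik - fit_ind$loglik)
  if (lr < -1e-6)
    warning("dependent likelihood below independent (optimization noise)")
  lr <- max(0, lr)
  out <- list(independent = fit_ind, dependent = fit_dep, lr = lr, df = 4,
              p_value = pchisq(lr, df = 4, lower.tail = FALSE))
  class(out) <- "correvo"
  out
}

#' @export
print.correvo <- function(x, ...) {
  cat("Correlated evolution (Pagel) test\n")
  cat("  independent (4 rates) logLik:", format(x$independent$loglik), "\n")
  cat("  dependent   (8 rates) logLik:", format(x$dependent$loglik), "\n")
  cat("  LR =", format(x$lr, digits = 5), " df =", x$df,
      " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Binarize a continuous trait
#'
#' `rule = "mean"`: state 0 iff the value is strictly below the mean (all
#' equal values therefore map to 1). `rule = "median_le"`: state 0 ("slow")
#' iff the value is less than or equal to the median -- the rule used for
#' rRNA-copy growth-rate classes.
#'
#' @param values numeric vector (length >= 2).
#' @param rule `"mean"` or `"median_le"`.
#' @return List with `bits` (0/1 vector, names preserved), `threshold`,
#'   `rule`.
#' @export
binarize <- function(values, rule = c("mean", "median_le")) {
  rule <- match.arg(rule)
  stopifnot(length(values) >= 2)
  thr <- if (rule == "mean") mean(values) else median(values)
  bits <- if (rule == "mean") as.integer(values >= thr)
  else as.integer(values > thr)
  names(bits) <- names(values)
  list(bits = bits, threshold = thr, rule = rule)
}
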