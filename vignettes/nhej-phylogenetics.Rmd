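---
title: "Methods: phylogenetics of bacterial NHEJ presence, loss and genome-size association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetics of bacterial NHEJ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhejphylo)
```

This vignette is the package's own account of its models and the choices
behind them. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The classification model

A genome's NHEJ status is decided purely from its complement of four
protein-domain hits (Ku; and LigD's LIG, POL, PE), after filtering hits to
an E-value at or below a reporting threshold (default `1e-4`, the
conventional HMMER reporting cutoff for these searches). The decision
procedure in `assign_state()` is total and deterministic:

1. *conventional NHEJ+*: Ku present **and** at least one protein carries
   all of LIG, POL and PE;
2. *nonconventional NHEJ+*: Ku and LIG present, but no single protein has
   all three LigD domains;
3. *Ku only*: Ku present, no LIG anywhere;
4. *LigD only*: LIG present, no Ku;
5. *NHEJ−*: everything else — in particular POL and/or PE **without** LIG
   never confer LigD status, because LIG is the diagnostic ligase domain.

Two deliberate choices: *conventional takes precedence* when a genome has
both a three-domain LigD and extra fragmented copies (the conventional
definition is existential), and the enumerated nonconventional
sub-architectures are all subsumed by the single predicate
"Ku ∧ LIG ∧ ¬conventional", which is what the classifier tests; any finer
sub-typing would use the same predicates.

**Neighborhood.** *ku*–*ligD* proximity is measured in gene ranks
(annotation order), not base pairs, with a 10-gene window inclusive at the
boundary. Replicons are treated as circular by default (bacterial
chromosomes are; `circular = FALSE` is available), so the rank distance is
the shorter arc. With multiple gene copies the minimum-distance pair
decides, and a same-strand pair wins ties — the conservative reading of
"operonic". The category is only meaningful for conventional-NHEJ genomes
(a single intact LigD), and `neighborhood_table()` only accepts those.

**Enrichment.** Per-phylum 2×2 tables are tested with the exact
hypergeometric (Fisher) test, two-sided by default since no direction is
assumed a priori; the raw odds ratio `ad/bc` is reported alongside a
Haldane (+0.5) corrected version when a cell is zero. The background is all
genomes by default; `background = "nhej_plus"` restricts it to
NHEJ-positive genomes, since either convention is defensible.

## 2. The Mk engine

The four-state character {`NHEJ_minus`, `Ku_only`, `LigD_only`,
`NHEJ_plus`} (conventional and nonconventional collapsed) evolves under a
generator $Q$; the tip likelihood is computed by Felsenstein pruning with
per-branch transition matrices $e^{Qt}$.

* **Transition matrices.** $Q$ is eigendecomposed once per likelihood
  evaluation and $e^{Qt}$ reconstructed per branch when the eigenvector
  matrix is well-conditioned (condition number < 1e8); otherwise the code
  falls back to scaling-and-squaring per branch. This keeps the engine
  robust for the `1e-6` branches introduced by polytomy resolution while
  making optimization loops fast.
* **Root prior.** Default `"fitzjohn"`: the root state prior is the
  normalized vector of root conditional likelihoods, i.e. "estimated at the
  root of the tree"; `"flat"`, `"stationary"` and explicit vectors are
  available.
* **Fitting.** ER (1 rate), SYM ($k(k-1)/2$), ARD ($k(k-1)$; 12 transition
  types for $k=4$) or any custom index matrix, maximized by L-BFGS-B on
  log-rates bounded in $[10^{-8}, 10^3]$ per unit branch length, with a
  deterministic multi-start schedule (multiples of a tree-length-based
  heuristic rate; no RNG in fitting). Models are compared by AIC weights
  $w_i \propto e^{-\Delta_i/2}$.
* **MCMC over $Q$** (`sample_q_posterior`): joint Gaussian random-walk
  proposals on log-rates, independent exponential priors on the
  natural-scale rates with mean equal to each group's ML estimate (a
  weakly-informative, scale-respecting default; the mean can be overridden),
  the log-scale Jacobian included in the target, proposal scale adapted
  toward ~30% acceptance during a 10% burn-in, then thinning to the
  requested number of draws. Everything is reproducible from the seed.
* **Stochastic mapping.** Node states are sampled from their joint
  posterior by a pre-order pass over the pruning conditionals; each branch
  is then filled with an endpoint-conditioned CTMC path sampled *exactly*
  by uniformization (number of uniformized events by sequential inversion,
  the event-state bridge through powers of $I + Q/\Omega$, uniform order
  statistics for times). Uniformization rather than rejection sampling is
  used because rejection stalls on near-zero-length branches. One map is
  drawn per posterior $Q$ draw in the intended workflow (1,000 total at
  production scale), since "many maps per sampled $Q$" only re-weights
  within-draw noise.
* **Node calls and primary gains.** A node is *called* only when its
  posterior probability strictly exceeds 0.7 (the display convention
  "support > 70%"), whereas the primary-gain criterion uses an inclusive
  ≥ 0.7 — the two thresholds are quoted with different strictness in their
  respective rules and are implemented accordingly. A major primary gain
  requires: all root-path ancestors called `NHEJ_minus`; pp ≥ 0.7 for
  `NHEJ_plus`, `Ku_only` or `LigD_only` at the node; a `Ku_only`/`LigD_only`
  gain must be followed below by a called `NHEJ_plus` node (or an
  `NHEJ_plus` tip when tip states are supplied); and at least three
  descendant tips.

**Brownian ancestral states** for continuous traits (log10 genome size) are
the joint-ML/GLS solution: the minimizer of branch-wise squared changes
weighted by inverse branch length, solved as one sparse weighted-Laplacian
system (so the root estimate is the GLS phylogenetic mean), with
conditional variances scaled by the ML rate
$\hat\sigma^2 = \sum u_i^2 / n$ from independent contrasts. Polytomies are
fine for the estimates; contrasts use an eps-resolved copy for the rate
only.

## 3. Comparative statistics

* **Pagel's λ**: internal shared path lengths scaled by λ, tip depths
  untouched; λ profiled by ML with mean and rate analytic; LRT against
  λ = 0 on 1 df. The search interval extends slightly above 1 when the
  covariance stays positive definite. On a star tree the likelihood is flat
  in λ and the function warns rather than fails.
* **Blomberg's K**: observed MSE₀/MSE about the GLS mean over its Brownian
  expectation $[\mathrm{tr}(C) - n/\mathbf{1}'C^{-1}\mathbf{1}]/(n-1)$;
  significance by tip-label permutation with the unbiased
  $(1+\text{exceedances})/(1+n_\text{perm})$ estimator (used by every
  permutation test in the package).
* **Phylogenetic ANOVA**: ordinary F, null distribution from Brownian
  simulations on the tree at the contrast-ML rate; pairwise post-hoc t
  statistics against the same simulated nulls, Holm–Bonferroni adjusted.
  The method assumes normality of the trait; the package implements the
  method as used in the field and leaves that caveat to the analyst.
* **Correlated evolution**: independent = 4 tied rates, dependent = 8 free
  rates on {00, 01, 10, 11} with double transitions structurally forbidden
  (the standard discrete formulation); the dependent fit is warm-started
  from the independent MLE so the nesting inequality holds by construction;
  χ² LRT with df = 8 − 4 = 4. Binarization rules: "below the mean = 0" for
  continuous traits; "≤ median = slow" for rRNA copy number.
* **Phylogenetic logistic regression**: the response is Bernoulli with
  logit mean $X\beta$ and working tip–tip correlation
  $\exp(-\alpha\, d_{ij})$ in patristic distance, so larger α means less
  phylogenetic signal (the conventional orientation). β is estimated by
  GEE/Fisher scoring, α by maximizing the Gaussian working likelihood of
  the standardized residuals, alternating to convergence; bounds on α are
  $[10^{-4}, 50]/\bar d$ and the identity correlation is used exactly at
  the independence boundary, which makes the estimator collapse to ordinary
  logistic regression on star trees. The reported AIC is
  $2(p+1) - 2\ell_\text{work}$ with $\ell_\text{work}$ the Gaussian
  likelihood of the IRLS working response — comparable across predictor
  sets on the same data, which is how model choice is intended to be done.
  This is a working-likelihood formulation in the spirit of the
  estimating-equation approach, not a line-by-line reproduction of any
  particular implementation. VIF = 1/(1−R²) is checked before fitting and
  perfect separation is diagnosed from the ordinary-GLM start.
* **Mantel test**: Pearson r of lower triangles; one-tailed (greater) by
  joint row/column permutation; labels intersected and reported. An exact
  mode enumerates all $n!$ permutations for small matrices.
* **GS randomization**: genes drawn uniformly from the pooled gene set, so
  a genome is picked with probability proportional to its gene count; the
  per-draw recorded value defaults to the source genome's CDS count (the
  genome-size proxy), the medians of `n_iter` draws form the null, and the
  observed sample is compared by Wilcoxon rank-sum. Draws are without
  replacement within an iteration by default (distinct genes), with
  replacement available.
* **Wilcoxon comparisons** are exact when min(n) ≤ 10 without ties,
  otherwise normal-approximate with tie and continuity correction.

## 4. The synthetic-data generator

`simulate_all()` produces every input the pipeline consumes: a Yule tree
(`ape::rphylo`, pure birth — extinction plays no role in any analysis, so
one parameter suffices), an exact Gillespie history of the four-state
character, a conventional/nonconventional split of `NHEJ_plus` tips,
domain-hit tables strictly consistent with each five-state assignment
(including decoy hits *above* the E-value threshold so the filter path is
exercised), gene tables with *ku*/*ligD* placed at controlled circular rank
offsets and strands, and genome metadata with state-dependent shifts.

Defaults emulate the study conditions: baseline genomes around
$10^{6.46}$ bp (~2.9 Mb) with conventional-NHEJ genomes +0.27 log10 units
(~5.4 Mb), matching the reported medians; rRNA Poisson means 4 (NHEJ−)
vs 3 (conventional); 70% of NHEJ+ tips conventional (~920 of ~1,300);
neighborhood mix 45% operonic / 30% proximal / 25% distant (75% within the
window, 60% of those same-strand); trees of 200–1,000 tips mirroring the
pruned production trees (969 and 1,403 taxa) at desk scale. The default
generator has loss rates exceeding gain rates and rare direct
`Ku_only ↔ LigD_only` interconversion.

What the generator does **not** emulate: sequence-level evolution (no
alignments or HMM score distributions beyond the pass/fail filter),
horizontal transfer (tip states are strictly tree-generated), plasmids,
assembly artifacts, and taxonomic sampling bias. Passing tests therefore
demonstrate the *statistical machinery* is correct and calibrated under the
stated generative model, not that real data meet that model's assumptions.
One visible consequence: under the default (fairly fast) rates a 300-tip
history carries on the order of a hundred true transitions, deep node
posteriors are diffuse, and the four-criterion primary-gain caller — which
demands confidently `NHEJ_minus` root paths — legitimately finds nothing;
with rates scaled down several-fold it recovers the simulated gains, as the
sporadic tip pattern becomes tree-like enough to reconstruct.

## 5. Numerical and design choices

* Polytomies are resolved deterministically in input order
  (`ape::multi2di(random = FALSE)`), then every zero-length branch —
  pre-existing or introduced — is set to `eps = 1e-6`. The resolution order
  is a choice (no convention exists); it is deterministic so runs are
  reproducible without a seed.
* Midpoint rooting delegates to `phangorn::midpoint`; ties among equally
  long tip-to-tip paths follow that implementation's deterministic internal
  rule (ties are measure-zero for trees with continuous branch lengths).
* Newick internal labels are kept as opaque strings (bootstrap/SH-aLRT
  values must not become node names); `[...]` comments are stripped;
  malformed input is rejected with the character offset.
* All permutation/resampling p-values use $(1+\text{exc})/(1+n)$; all
  stochastic functions take a `seed` and are bit-reproducible given it.
* Rate bounds $[10^{-8}, 10^3]$ keep likelihoods finite on eps branches;
  degenerate data (all tips one state) drive rates to the lower bound
  rather than erroring.
* Problem sizes in the test suite (chosen to exercise each property at
  desk scale): exhaustive likelihood enumeration on 5-tip trees; simmap vs
  marginal consistency with 2,000 maps on 20 tips; correlated-evolution
  calibration with 200 null and 50 power replicates on 500-tip trees;
  independence limits on 100-tip star trees with 5,000 ANOVA simulations;
  recovery batteries at 150–300 tips.

## 6. Known limitations

* The Bayesian reversible-jump arm of model comparison (Bayes factors via
  stepping-stone) is out of scope; the ML/LRT arm is implemented.
* Only single-rate Brownian ancestral reconstruction is provided (no
  multi-rate/stable models).
* `phylo_logistic_regression` reports a working-likelihood AIC; its
  absolute value is not comparable to a true marginal-likelihood AIC from
  other software, only differences across formulas fitted here are
  meaningful.
* The classifier trusts the hit table: it does not re-score HMM matches,
  detect the ~20 accessory domains sometimes found near NHEJ loci, or call
  plasmid vs chromosome location.
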