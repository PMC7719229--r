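#' Default generator for the four-state NHEJ rate matrix
#'
#' Loss rates exceed gain rates and direct interconversion of the two
#' single-component states is rare, giving the sporadic presence/absence
#' pattern seen in real bacterial genomes.
#'
#' @return A 4 x 4 generator over [NHEJ_STATES4].
#' @export
default_nhej_q <- function() {
  Q <- matrix(c(
    0,    0.05, 0.15, 0.08,   # from NHEJ_minus
    0.40, 0,    0.02, 0.30,   # from Ku_only
    0.30, 0.02, 0,    0.25,   # from LigD_only
    0.15, 0.03, 0.15, 0),     # from NHEJ_plus
    4, 4, byrow = TRUE, dimnames = list(NHEJ_STATES4, NHEJ_STATES4))
  diag(Q) <- -rowSums(Q)
  Q
}

#' Configuration of the synthetic-data generator
#'
#' Bundles every tunable of the simulation: tree size and birth rate, the
#' Mk generator of NHEJ states, the dependent generator for correlated
#' binary pairs, the state-dependent shifts of genome size (log10), rRNA
#' copy number and G--C content, the ku--ligD neighborhood placement model,
#' and the rate of decoy (above-threshold) domain hits. Defaults emulate
#' the study conditions: ~2.9 Mb baseline genomes with conventional-NHEJ
#' genomes larger by 0.27 log10 units (5.4 vs 2.9 Mb medians), rRNA medians
#' of about 3 (NHEJ+) vs 4 (NHEJ-), 70% of NHEJ+ genomes conventional, and
#' 45/30/25% operonic/proximal/distant neighborhoods.
#'
#' @param n_tips,birth_rate Yule tree parameters.
#' @param mk_Q 4-state generator of NHEJ evolution.
#' @param root_state state at the root of the simulated history.
#' @param p_conventional probability that an `NHEJ_plus` tip is
#'   conventional.
#' @param brownian_sigma2,brownian_root Brownian-trait parameters.
#' @param dependent_Q 8-rate generator on `{00,01,10,11}` for correlated
#'   pairs.
#' @param size_log10_base,size_log10_sd baseline and noise of log10 genome
#'   size.
#' @param state_effects named list: per-five-state shifts `size_log10`,
#'   Poisson means `rrna_lambda`, means `gc_mean`.
#' @param gc_sd G--C noise.
#' @param neighborhood_params list with `p_operonic`, `p_proximal`,
#'   `max_offset`.
#' @param n_genes genes per replicon in the synthetic annotation.
#' @param domain_noise per-genome probability of one decoy hit above the
#'   E-value threshold.
#' @param cds_per_bp CDS count per bp of genome (bacterial gene density).
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(
    n_tips = 300, birth_rate = 1,
    mk_Q = default_nhej_q(), root_state = "NHEJ_minus",
    p_conventional = 0.7,
    brownian_sigma2 = 0.05, brownian_root = 0,
    dependent_Q = NULL,
    size_log10_base = 6.46, size_log10_sd = 0.12,
    state_effects = list(
      size_log10 = c(NHEJ_minus = 0, Ku_only = 0.05, LigD_only = 0.08,
                     conventional_plus = 0.27, nonconventional_plus = 0.15),
      rrna_lambda = c(NHEJ_minus = 4, Ku_only = 3.5, LigD_only = 3.5,
                      conventional_plus = 3, nonconventional_plus = 3),
      gc_mean = c(NHEJ_minus = 0.50, Ku_only = 0.55, LigD_only = 0.55,
                  conventional_plus = 0.60, nonconventional_plus = 0.58)),
    gc_sd = 0.04,
    neighborhood_params = list(p_operonic = 0.45, p_proximal = 0.30,
                               max_offset = 10),
    n_genes = 200, domain_noise = 0.2, cds_per_bp = 9e-4) {
  if (is.null(dependent_Q)) {
    st <- pagel_structures()
    dependent_Q <- build_rate_matrix(
      st$dependent, c(0.3, 0.3, 0.3, 1.5, 0.3, 1.5, 0.1, 0.1), st$states)
  }
  cfg <- list(n_tips = n_tips, birth_rate = birth_rate, mk_Q = mk_Q,
              root_state = root_state, p_conventional = p_conventional,
              brownian_sigma2 = brownian_sigma2,
              brownian_root = brownian_root, dependent_Q = dependent_Q,
              size_log10_base = size_log10_base,
              size_log10_sd = size_log10_sd, state_effects = state_effects,
              gc_sd = gc_sd, neighborhood_params = neighborhood_params,
              n_genes = n_genes, domain_noise = domain_noise,
              cds_per_bp = cds_per_bp)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed RNG seed.
#' @return An ultrametric `"phylo"` object with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Simulate a discrete character history on a tree (exact Gillespie)
#'
#' Forward simulation of a continuous-time Markov chain along every branch,
#' returning both the tip states and the full true history in the same
#' segment format as [stochastic_map()], so recovery of the truth can be
#' checked with [summarize_maps()].
#'
#' @param tree a `"phylo"` object.
#' @param Q generator with state dimnames.
#' @param root_state starting state (a state name); alternatively
#'   `root_prior` samples it.
#' @param root_prior probability vector over the states (used when
#'   `root_state` is `NULL`).
#' @param seed RNG seed.
#' @return List with `tip_states` (named vector) and `history` (a
#'   `"stochastic_map"`).
#' @export
simulate_mk_history <- function(tree, Q, root_state = NULL,
                                root_prior = NULL, seed = NULL) {
  check_generator(Q)
  states <- colnames(Q)
  if (!is.null(seed)) set.seed(seed)
  po <- postorder_edges(tree)
  tr <- po$tree
  ntot <- po$ntip + po$nnode
  root <- po$ntip + 1L
  k <- length(states)
  node_state <- integer(ntot)
  node_state[root] <- if (!is.null(root_state)) {
    i <- match(root_state, states)
    if (is.na(i)) stop("root_state not in the state set")
    i
  } else {
    pr <- if (is.null(root_prior)) rep(1 / k, k) else root_prior
    sample.int(k, 1L, prob = pr)
  }
  ne <- length(po$child)
  edge_maps <- vector("list", ne)
  for (e in rev(seq_len(ne))) {  # preorder
    s <- node_state[po$parent[e]]
    t_rem <- po$elen[e]
    seg_state <- integer(0); seg_dwell <- numeric(0)
    repeat {
      rate <- -Q[s, s]
      wait <- if (rate > 0) rexp(1, rate) else Inf
      if (wait >= t_rem) {
        seg_state <- c(seg_state, s); seg_dwell <- c(seg_dwell, t_rem)
        break
      }
      seg_state <- c(seg_state, s); seg_dwell <- c(seg_dwell, wait)
      t_rem <- t_rem - wait
      w <- Q[s, ]; w[s] <- 0
      s <- sample.int(k, 1L, prob = w)
    }
    edge_maps[[e]] <- data.frame(state = states[seg_state],
                                 dwell = seg_dwell,
                                 stringsAsFactors = FALSE)
    node_state[po$child[e]] <- s
  }
  hist <- list(tree = tr, states = states,
               node_states = setNames(states[node_state],
                                      as.character(seq_len(ntot))),
               edge_maps = edge_maps)
  class(hist) <- "stochastic_map"
  list(tip_states = setNames(states[node_state[seq_len(po$ntip)]],
                             tr$tip.label),
       history = hist)
}

#' Simulate two binary traits under a dependent 8-rate model
#'
#' Gillespie simulation on the product space `{00, 01, 10, 11}` (double
#' transitions must be forbidden in the supplied generator), projected to
#' the two binary margins.
#'
#' @param tree a `"phylo"` object.
#' @param dependent_Q 4 x 4 generator on the product states with zero rates
#'   for `00 <-> 11` and `01 <-> 10`.
#' @param seed RNG seed.
#' @param root_prior prior over the four product states (default: stationary
#'   distribution of `dependent_Q`).
#' @return List with named 0/1 vectors `trait_a`, `trait_b` and the product
#'   `tip_states`.
#' @export
simulate_correlated_pair <- function(tree, dependent_Q, seed = NULL,
                                     root_prior = NULL) {
  states <- c("00", "01", "10", "11")
  if (!identical(colnames(dependent_Q), states))
    stop("dependent_Q must have states 00, 01, 10, 11")
  forb <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2))
  if (any(dependent_Q[forb] != 0))
    stop("double transitions (00<->11, 01<->10) must have zero rate")
  if (is.null(root_prior))
    root_prior <- root_prior_vec("stationary", NULL, dependent_Q, states)
  sim <- simulate_mk_history(tree, dependent_Q, root_prior = root_prior,
                             seed = seed)
  ts <- sim$tip_states
  list(trait_a = setNames(as.integer(substr(ts, 1, 1)), names(ts)),
       trait_b = setNames(as.integer(substr(ts, 2, 2)), names(ts)),
       tip_states = ts)
}

# one genome's domain-hit rows consistent with its NHEJ state
sim_domain_hits <- function(genome, state, noise_p) {
  ev <- function() 10^runif(1, -30, -5)
  rows <- list()
  add <- function(prot, dom, from, to, evalue = ev())
    rows[[length(rows) + 1L]] <<- data.frame(
      genome_id = genome, protein_id = paste0(genome, "_", prot),
      domain = dom, evalue = evalue, ali_from = from, ali_to = to,
      stringsAsFactors = FALSE)
  full_ligd <- function(prot) {
    add(prot, "LIG", 10, 110); add(prot, "POL", 150, 250)
    add(prot, "PE", 300, 380)
  }
  if (state %in% c("Ku_only", "conventional_plus", "nonconventional_plus")) {
    add("ku1", "Ku", 5, 200)
    if (runif(1) < 0.16)  # multi-copy Ku genomes (2-4 copies)
      for (i in seq_len(sample(1:3, 1))) add(paste0("ku", i + 1), "Ku", 5, 200)
  }
  if (state == "conventional_plus") {
    full_ligd("ligd1")
    if (runif(1) < 0.3) add("ligfrag", "LIG", 1, 100)  # extra LIG copy
  } else if (state == "nonconventional_plus") {
    case <- sample(1:4, 1)
    if (case == 1) {        # all three domains, all in different proteins
      add("p1", "LIG", 1, 100); add("p2", "POL", 1, 100)
      add("p3", "PE", 1, 80)
    } else if (case == 2) { # LIG + POL in one protein
      add("p1", "LIG", 1, 100); add("p1", "POL", 150, 250)
    } else if (case == 3) { # LIG and POL in different proteins
      add("p1", "LIG", 1, 100); add("p2", "POL", 1, 100)
    } else {                # LIG with/without PE
      add("p1", "LIG", 1, 100)
      if (runif(1) < 0.5) add("p1", "PE", 150, 230)
    }
  } else if (state == "LigD_only") {
    if (runif(1) < 0.7) full_ligd("ligd1")
    else { add("p1", "LIG", 1, 100); add("p2", "POL", 1, 100) }
  } else if (state == "Ku_only") {
    if (runif(1) < 0.5) add("p1", "POL", 1, 100)
    if (runif(1) < 0.3) add("p2", "PE", 1, 80)
  } else {  # NHEJ_minus
    if (runif(1) < 0.25) add("p1", "POL", 1, 100)
    if (runif(1) < 0.25) add("p2", "PE", 1, 80)
  }
  if (runif(1) < noise_p)  # decoy above the reporting threshold
    add("decoy", sample(DOMAIN_TOKENS, 1), 1, 50, evalue = 1e-3)
  do.call(rbind, rows)
}

#' Generate domain-hit, gene and trait tables for a set of genomes
#'
#' Per genome, emits (i) domain hits strictly consistent with its five-state
#' NHEJ assignment (plus optional decoy hits above the E-value threshold, so
#' that default parsing removes them), (ii) a gene table with ku/ligD placed
#' at controlled rank offsets and strands following the neighborhood model
#' (conventional genomes draw an operonic/proximal/distant category), and
#' (iii) genome metadata with the configured state-dependent shifts of
#' genome size, rRNA copy number and G--C content.
#'
#' @param states named character vector genome -> five-state NHEJ state.
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return List of data.frames `domain_hits`, `genes`, `traits`, plus
#'   `neighborhood_truth` (the generating category per conventional genome).
#' @export
generate_genome_tables <- function(states, config = simulation_config(),
                                   seed = NULL) {
  bad <- setdiff(unique(states), NHEJ_STATES)
  if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  genomes <- names(states)
  np <- config$neighborhood_params
  n_genes <- config$n_genes
  eff <- config$state_effects

  hits <- list(); genes <- list(); traits <- list(); truth <- list()
  for (g in genomes) {
    st <- states[[g]]
    hits[[g]] <- sim_domain_hits(g, st, config$domain_noise)
    # gene table: one circular replicon, ranks 0 .. n_genes - 1
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    role <- rep("other", n_genes)
    has_ku <- st %in% c("Ku_only", "conventional_plus",
                        "nonconventional_plus")
    has_ligd <- st %in% c("LigD_only", "conventional_plus",
                          "nonconventional_plus")
    r_ku <- if (has_ku) sample.int(n_genes, 1) - 1L else NA
    if (has_ku) role[r_ku + 1L] <- "ku"
    if (has_ligd) {
      if (st == "conventional_plus") {
        u <- runif(1)
        cat_g <- if (u < np$p_operonic) "operonic"
        else if (u < np$p_operonic + np$p_proximal)
          "proximal_opposite_strand" else "distant"
        off <- if (cat_g == "distant")
          sample((np$max_offset + 5):(floor(n_genes / 2) - 1), 1)
        else sample.int(np$max_offset, 1)
        r_ligd <- (r_ku + off) %% n_genes
        if (cat_g == "operonic") strand[r_ligd + 1L] <- strand[r_ku + 1L]
        if (cat_g == "proximal_opposite_strand")
          strand[r_ligd + 1L] <- setdiff(c("+", "-"), strand[r_ku + 1L])
        truth[[g]] <- cat_g
      } else {
        free <- setdiff(seq_len(n_genes) - 1L, r_ku)
        r_ligd <- sample(free, 1)
      }
      role[r_ligd + 1L] <- "ligD"
    }
    genes[[g]] <- data.frame(
      genome_id = g, replicon_id = "chr", rank = 0:(n_genes - 1),
      start = 0:(n_genes - 1) * 1000L + 1L,
      end = 0:(n_genes - 1) * 1000L + 900L,
      strand = strand, role = role, stringsAsFactors = FALSE)
    lsz <- config$size_log10_base + eff$size_log10[[st]] +
      rnorm(1, 0, config$size_log10_sd)
    size_bp <- round(10^lsz)
    traits[[g]] <- data.frame(
      genome_id = g,
      genome_size_bp = size_bp,
      gc_content = min(0.8, max(0.2, rnorm(1, eff$gc_mean[[st]],
                                           config$gc_sd))),
      rrna_copies = max(1L, rpois(1, eff$rrna_lambda[[st]])),
      cds_count = round(size_bp * config$cds_per_bp),
      stringsAsFactors = FALSE)
  }
  list(domain_hits = do.call(rbind, unname(hits)),
       genes = do.call(rbind, unname(genes)),
       traits = do.call(rbind, unname(traits)),
       neighborhood_truth = unlist(truth))
}

#' Run the full synthetic-data generator and (optionally) write its outputs
#'
#' Simulates a Yule tree, evolves the four-state NHEJ character on it, splits
#' `NHEJ_plus` tips into conventional/nonconventional, and generates the
#' domain-hit, gene and trait tables. With `out_dir` set, writes `tree.nwk`,
#' `states.tsv`, `domain_hits.tsv`, `genes.tsv`, `traits.tsv` and
#' `truth.json` (the serialized configuration, tip states and true
#' transition counts). Two runs with the same seed produce byte-identical
#' files.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (mandatory: the run must be reproducible).
#' @param out_dir optional output directory (created if missing).
#' @return Invisibly, a list with the tree, the true history, five- and
#'   four-state tip assignments and the generated tables.
#' @export
simulate_all <- function(config = simulation_config(), seed, out_dir = NULL) {
  stopifnot(!missing(seed))
  set.seed(seed)
  tree <- simulate_tree(config$n_tips, config$birth_rate)
  sim <- simulate_mk_history(tree, config$mk_Q,
                             root_state = config$root_state)
  tips4 <- sim$tip_states
  tips5 <- tips4
  plus <- tips4 == "NHEJ_plus"
  tips5[plus] <- ifelse(runif(sum(plus)) < config$p_conventional,
                        "conventional_plus", "nonconventional_plus")
  tables <- generate_genome_tables(tips5, config)
  out <- list(tree = sim$history$tree, history = sim$history,
              states4 = tips4, states5 = tips5,
              domain_hits = tables$domain_hits, genes = tables$genes,
              traits = tables$traits,
              neighborhood_truth = tables$neighborhood_truth,
              config = config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(out$tree, file.path(out_dir, "tree.nwk"))
    wt <- function(d, f) write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(data.frame(genome_id = names(tips5), state = unname(tips5)),
       "states.tsv")
    wt(tables$domain_hits, "domain_hits.tsv")
    wt(tables$genes, "genes.tsv")
    wt(tables$traits, "traits.tsv")
    truth <- list(seed = seed, config = unclass(config),
                  tip_states4 = as.list(tips4), tip_states5 = as.list(tips5),
                  true_transition_counts =
                    summarize_maps(sim$history)$mean_counts)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
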