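#' Parse a domain-hit table
#'
#' Reads a simplified HMMER-domtblout-like TSV of per-genome protein domain
#' hits and filters it to hits at or below the E-value reporting threshold
#' (the classifier's input contract). Multi-domain proteins are allowed:
#' repeated (genome, protein, domain) triples are legitimate as long as they
#' come from distinct alignment coordinates.
#'
#' @param path TSV file with header columns `genome_id`, `protein_id`,
#'   `domain`, `evalue`, `ali_from`, `ali_to`.
#' @param evalue_threshold keep hits with `evalue <= evalue_threshold`
#'   (default `1e-4`).
#' @param quiet suppress the message reporting how many rows were dropped.
#' @return A `data.frame` of retained hits with numeric `evalue` and integer
#'   coordinates.
#' @export
parse_domain_table <- function(path, evalue_threshold = 1e-4, quiet = FALSE) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("genome_id", "protein_id", "domain", "evalue", "ali_from",
            "ali_to")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("domain table is missing column(s): ", paste(miss, collapse = ", "))
  bad_dom <- setdiff(unique(raw$domain), DOMAIN_TOKENS)
  if (length(bad_dom))
    stop("unknown domain token(s): ", paste(bad_dom, collapse = ", "),
         " (expected ", paste(DOMAIN_TOKENS, collapse = "/"), ")")
  ev <- suppressWarnings(as.numeric(raw$evalue))
  if (anyNA(ev) && nrow(raw) > 0)
    stop("non-numeric evalue in row(s): ",
         paste(which(is.na(ev)), collapse = ", "))
  raw$evalue <- ev
  raw$ali_from <- as.integer(raw$ali_from)
  raw$ali_to <- as.integer(raw$ali_to)
  keep <- raw$evalue <= evalue_threshold
  n_drop <- sum(!keep)
  if (!quiet && n_drop > 0)
    message(n_drop, " hit(s) dropped at E-value threshold ", evalue_threshold)
  out <- raw[keep, need, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the NHEJ state of a single genome
#'
#' Decision procedure over the genome's (already filtered) domain hits:
#' conventional NHEJ requires Ku plus at least one protein carrying all of
#' LIG, POL and PE; Ku together with LIG in any other arrangement is
#' nonconventional NHEJ; Ku without any LIG is `Ku_only`; LIG without Ku is
#' `LigD_only`; anything else -- including POL and/or PE hits without LIG --
#' is `NHEJ_minus`. The function is total: an empty hit set is `NHEJ_minus`.
#'
#' @param hits `data.frame` of domain hits for one genome (columns
#'   `protein_id`, `domain`); may have zero rows.
#' @return One of [NHEJ_STATES].
#' @export
assign_state <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return("NHEJ_minus")
  has_ku <- any(hits$domain == "Ku")
  has_lig <- any(hits$domain == "LIG")
  by_prot <- split(hits$domain, hits$protein_id)
  conventional <- any(vapply(by_prot, function(d)
    all(c("LIG", "POL", "PE") %in% d), logical(1)))
  if (has_ku && conventional) return("conventional_plus")
  if (has_ku && has_lig) return("nonconventional_plus")
  if (has_ku) return("Ku_only")
  if (has_lig) return("LigD_only")
  "NHEJ_minus"
}

#' Assign NHEJ states for a table of genomes
#'
#' @param hits `data.frame` of filtered domain hits (column `genome_id`).
#' @param genome_ids optional character vector of all genomes to report;
#'   genomes with no hits are `NHEJ_minus`.
#' @return `data.frame` with columns `genome_id`, `state`.
#' @export
assign_states <- function(hits, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- sort(unique(hits$genome_id))
  by_g <- split(hits, factor(hits$genome_id, levels = genome_ids))
  st <- vapply(genome_ids, function(g) assign_state(by_g[[g]]), character(1))
  data.frame(genome_id = genome_ids, state = unname(st),
             stringsAsFactors = FALSE)
}

#' Ku and LigD-domain copy numbers per genome
#'
#' The Ku copy number is the number of distinct proteins with a Ku hit;
#' LIG/POL/PE copy numbers are total hit counts (a protein with two LIG
#' alignments at disjoint coordinates counts twice).
#'
#' @param hits `data.frame` of filtered domain hits.
#' @param genome_ids optional vector of genomes to report (zero counts for
#'   genomes without hits).
#' @return `data.frame` with columns `genome_id`, `ku_copies`, `lig_copies`,
#'   `pol_copies`, `pe_copies`.
#' @export
copy_numbers <- function(hits, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- sort(unique(hits$genome_id))
  by_g <- split(hits, factor(hits$genome_id, levels = genome_ids))
  one <- function(h) {
    if (is.null(h) || nrow(h) == 0) return(c(0L, 0L, 0L, 0L))
    c(length(unique(h$protein_id[h$domain == "Ku"])),
      sum(h$domain == "LIG"), sum(h$domain == "POL"), sum(h$domain == "PE"))
  }
  m <- t(vapply(genome_ids, function(g) one(by_g[[g]]), integer(4)))
  data.frame(genome_id = genome_ids, ku_copies = m[, 1], lig_copies = m[, 2],
             pol_copies = m[, 3], pe_copies = m[, 4],
             stringsAsFactors = FALSE)
}

#' Classify the ku--ligD genomic neighborhood of one genome
#'
#' For every (ku, ligD) gene pair on a common replicon the rank distance
#' `delta` is computed (on the circle when `circular = TRUE`, the default for
#' bacterial replicons) and the pair with minimal `delta` decides -- with
#' same-strand pairs preferred on ties. The call is `operonic` when
#' `delta <= window` on the same strand, `proximal_opposite_strand` when
#' `delta <= window` on different strands, and `distant` otherwise (including
#' when the genes never share a replicon). The window boundary is inclusive.
#'
#' @param genes `data.frame` of gene records for one genome: columns
#'   `replicon_id`, `rank` (0-based order on the replicon), `strand`
#'   (`"+"`/`"-"`), `role` (`"ku"`, `"ligD"`, `"other"`).
#' @param window rank-distance window (default 10 genes).
#' @param circular compute rank distances on the circular replicon.
#' @return `data.frame` with columns `category`, `delta`, `same_strand`.
#' @export
neighborhood <- function(genes, window = 10, circular = TRUE) {
  ku <- genes[genes$role == "ku", , drop = FALSE]
  lig <- genes[genes$role == "ligD", , drop = FALSE]
  if (nrow(ku) == 0 || nrow(lig) == 0)
    stop("neighborhood() needs at least one ku and one ligD gene record")
  repl_len <- tapply(genes$rank, genes$replicon_id, function(r) max(r) + 1L)
  best <- NULL
  for (i in seq_len(nrow(ku))) for (j in seq_len(nrow(lig))) {
    if (ku$replicon_id[i] != lig$replicon_id[j]) next
    d <- abs(ku$rank[i] - lig$rank[j])
    if (circular) {
      L <- repl_len[[as.character(ku$replicon_id[i])]]
      d <- min(d, L - d)
    }
    same <- ku$strand[i] == lig$strand[j]
    if (is.null(best) || d < best$delta ||
        (d == best$delta && same && !best$same_strand))
      best <- list(delta = as.numeric(d), same_strand = same)
  }
  if (is.null(best))
    return(data.frame(category = "distant", delta = NA_real_,
                      same_strand = NA, stringsAsFactors = FALSE))
  category <- if (best$delta <= window && best$same_strand) "operonic"
  else if (best$delta <= window) "proximal_opposite_strand"
  else "distant"
  data.frame(category = category, delta = best$delta,
             same_strand = best$same_strand, stringsAsFactors = FALSE)
}

#' Neighborhood calls for all conventional-NHEJ genomes in a gene table
#'
#' @param genes gene table for many genomes (column `genome_id` plus the
#'   columns required by [neighborhood()]).
#' @param conventional_ids genomes to call (the neighborhood category is
#'   defined only for conventional-NHEJ genomes).
#' @inheritParams neighborhood
#' @return `data.frame` with one row per genome.
#' @export
neighborhood_table <- function(genes, conventional_ids, window = 10,
                               circular = TRUE) {
  out <- lapply(conventional_ids, function(g) {
    res <- neighborhood(genes[genes$genome_id == g, , drop = FALSE],
                        window = window, circular = circular)
    cbind(genome_id = g, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-phylum enrichment of an NHEJ state (Fisher's exact test)
#'
#' For each phylum P a 2x2 table is formed: genomes in P with the focal state,
#' in P without, outside P with, outside P without. The raw odds ratio
#' `ad/bc` is reported together with a Haldane continuity-corrected version
#' (+0.5 to every cell) when any cell is zero, and a two-sided (by default)
#' exact hypergeometric p-value.
#'
#' @param states `data.frame` with columns `genome_id`, `state`.
#' @param taxonomy `data.frame` with columns `genome_id`, `phylum`, or a
#'   named character vector mapping genome to phylum.
#' @param focal_state state tested for enrichment (e.g.
#'   `"conventional_plus"`).
#' @param background `"all"` (default) tests against all genomes; with
#'   `"nhej_plus"` the background is restricted to NHEJ-positive genomes.
#' @param alternative passed to [stats::fisher.test()].
#' @return `data.frame` with one row per phylum: cell counts, odds ratios and
#'   p-value.
#' @export
phylum_enrichment <- function(states, taxonomy, focal_state,
                              background = c("all", "nhej_plus"),
                              alternative = "two.sided") {
  background <- match.arg(background)
  if (!is.data.frame(taxonomy))
    taxonomy <- data.frame(genome_id = names(taxonomy),
                           phylum = unname(taxonomy),
                           stringsAsFactors = FALSE)
  d <- merge(states, taxonomy, by = "genome_id")
  if (anyNA(d$phylum) || nrow(d) < nrow(states))
    stop("every genome must have a phylum assignment")
  if (background == "nhej_plus")
    d <- d[d$state %in% c("conventional_plus", "nonconventional_plus"), ,
           drop = FALSE]
  phyla <- sort(unique(d$phylum))
  rows <- lapply(phyla, function(p) {
    in_p <- d$phylum == p
    focal <- d$state == focal_state
    a <- sum(in_p & focal); b <- sum(in_p & !focal)
    c_ <- sum(!in_p & focal); d_ <- sum(!in_p & !focal)
    if (a + b == 0) {
      warning("phylum ", p, " has no genomes in the background; skipped")
      return(NULL)
    }
    or_raw <- (a * d_) / (b * c_)
    any_zero <- any(c(a, b, c_, d_) == 0)
    or_h <- if (any_zero)
      ((a + .5) * (d_ + .5)) / ((b + .5) * (c_ + .5)) else NA_real_
    pv <- fisher.test(matrix(c(a, b, c_, d_), 2, byrow = TRUE),
                      alternative = alternative)$p.value
    data.frame(phylum = p, a = a, b = b, c = c_, d = d_,
               odds_ratio = or_raw, odds_ratio_haldane = or_h, p_value = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
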