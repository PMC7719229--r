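# writes a small in-memory hit table to a temp TSV
write_hits <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

hit_row <- function(genome, prot, dom, ev = 1e-10, from = 1, to = 100) {
  data.frame(genome_id = genome, protein_id = prot, domain = dom,
             evalue = ev, ali_from = from, ali_to = to,
             stringsAsFactors = FALSE)
}

test_that("parse_domain_table filters by E-value and validates fields", {
  df <- rbind(hit_row("g1", "p1", "Ku"), hit_row("g1", "p2", "LIG"),
              hit_row("g1", "p2", "POL", from = 150, to = 250),
              hit_row("g2", "p3", "PE"),
              hit_row("g2", "p4", "Ku", ev = 1e-3))
  expect_message(hits <- parse_domain_table(write_hits(df)), "1 hit")
  expect_equal(nrow(hits), 4)
  expect_false("p4" %in% hits$protein_id)

  empty <- df[0, ]
  expect_equal(nrow(parse_domain_table(write_hits(empty), quiet = TRUE)), 0)

  # duplicate (genome, protein, domain) at distinct coordinates both kept
  dup <- rbind(hit_row("g1", "p1", "LIG", from = 1, to = 100),
               hit_row("g1", "p1", "LIG", from = 200, to = 300))
  expect_equal(nrow(parse_domain_table(write_hits(dup), quiet = TRUE)), 2)

  bad <- hit_row("g1", "p1", "KU")
  expect_error(parse_domain_table(write_hits(bad)), "unknown domain")
  nonnum <- hit_row("g1", "p1", "Ku")
  nonnum$evalue <- "abc"
  expect_error(parse_domain_table(write_hits(nonnum)), "non-numeric")
})

test_that("assign_state implements the five-state decision procedure", {
  expect_equal(assign_state(rbind(
    hit_row("g", "p1", "Ku"), hit_row("g", "p2", "LIG"),
    hit_row("g", "p2", "POL"), hit_row("g", "p2", "PE"))),
    "conventional_plus")
  expect_equal(assign_state(rbind(
    hit_row("g", "p1", "POL"), hit_row("g", "p2", "PE"))), "NHEJ_minus")
  expect_equal(assign_state(rbind(
    hit_row("g", "p1", "Ku"), hit_row("g", "p2", "LIG"),
    hit_row("g", "p3", "POL"))), "nonconventional_plus")
  expect_equal(assign_state(NULL), "NHEJ_minus")
  expect_equal(assign_state(rbind(
    hit_row("g", "p1", "Ku"), hit_row("g", "p2", "POL"))), "Ku_only")
  expect_equal(assign_state(rbind(
    hit_row("g", "p1", "LIG"), hit_row("g", "p1", "POL"),
    hit_row("g", "p1", "PE"))), "LigD_only")
  # conventional takes precedence over extra fragmented copies
  expect_equal(assign_state(rbind(
    hit_row("g", "p1", "Ku"), hit_row("g", "p2", "LIG"),
    hit_row("g", "p2", "POL"), hit_row("g", "p2", "PE"),
    hit_row("g", "p3", "LIG"))), "conventional_plus")
})

test_that("the five states partition any genome set", {
  set.seed(3)
  states <- setNames(sample(NHEJ_STATES, 120, TRUE), paste0("g", 1:120))
  tb <- generate_genome_tables(states, simulation_config(), seed = 4)
  res <- assign_states(tb$domain_hits[tb$domain_hits$evalue <= 1e-4, ],
                       genome_ids = names(states))
  expect_equal(sum(table(factor(res$state, levels = NHEJ_STATES))), 120)
})

test_that("copy_numbers counts Ku proteins and domain hits", {
  h <- rbind(hit_row("g", "k1", "Ku"), hit_row("g", "k2", "Ku"),
             hit_row("g", "k3", "Ku"), hit_row("g", "k4", "Ku"),
             hit_row("g", "k4", "Ku", from = 150, to = 250))
  cn <- copy_numbers(h)
  expect_equal(cn$ku_copies, 4)  # distinct proteins, not hits
  cn0 <- copy_numbers(h[0, ], genome_ids = "gX")
  expect_equal(unlist(cn0[1, -1], use.names = FALSE), c(0L, 0L, 0L, 0L))
  h2 <- rbind(hit_row("g", "p1", "LIG", from = 1, to = 100),
              hit_row("g", "p1", "LIG", from = 200, to = 300))
  expect_equal(copy_numbers(h2)$lig_copies, 2)
})

gene_row <- function(rank, strand, role, genome = "g", repl = "chr") {
  data.frame(genome_id = genome, replicon_id = repl, rank = rank,
             start = rank * 1000 + 1, end = rank * 1000 + 900,
             strand = strand, role = role, stringsAsFactors = FALSE)
}

# a 100-gene replicon with ku/ligD dropped in at given ranks/strands
make_genes <- function(ku_rank, ku_strand, ligd_rank, ligd_strand, n = 100) {
  g <- do.call(rbind, lapply(0:(n - 1), function(r)
    gene_row(r, "+", "other")))
  g$role[ku_rank + 1] <- "ku"; g$strand[ku_rank + 1] <- ku_strand
  g$role[ligd_rank + 1] <- "ligD"; g$strand[ligd_rank + 1] <- ligd_strand
  g
}

test_that("neighborhood categories follow the 10-gene window rule", {
  expect_equal(neighborhood(make_genes(5, "+", 8, "+"))$category, "operonic")
  expect_equal(neighborhood(make_genes(5, "+", 12, "-"))$category,
               "proximal_opposite_strand")
  expect_equal(neighborhood(make_genes(5, "+", 40, "+"))$category, "distant")
  # inclusive boundary at delta = 10, both strand cases
  expect_equal(neighborhood(make_genes(5, "+", 15, "+"))$category,
               "operonic")
  expect_equal(neighborhood(make_genes(5, "+", 15, "-"))$category,
               "proximal_opposite_strand")
  # circular wrap: ranks 1 and 98 on a 100-gene circle are 3 apart
  expect_equal(neighborhood(make_genes(1, "+", 98, "+"))$delta, 3)
  # linear mode
  expect_equal(neighborhood(make_genes(1, "+", 98, "+"),
                            circular = FALSE)$category, "distant")
  expect_error(neighborhood(make_genes(5, "+", 8, "+")[-(9), ]), "ligD")
})

test_that("neighborhood picks the minimal pair, preferring same strand", {
  g <- make_genes(5, "+", 40, "+")
  g <- rbind(g, gene_row(9, "-", "ligD"))   # closer ligD copy, opposite
  expect_equal(neighborhood(g)$category, "proximal_opposite_strand")
  # tie at equal delta: same-strand pair wins
  g2 <- make_genes(5, "+", 9, "-")
  g2 <- rbind(g2, gene_row(1, "+", "ligD")) # delta 4 on the same strand
  expect_equal(neighborhood(g2)$category, "operonic")
})

test_that("phylum enrichment matches the exact hypergeometric oracle", {
  # [[10,5],[20,40]]: OR = ad/bc = 4; p by enumeration over fixed margins
  states <- data.frame(
    genome_id = paste0("g", 1:75),
    state = c(rep("conventional_plus", 10), rep("NHEJ_minus", 5),
              rep("conventional_plus", 20), rep("NHEJ_minus", 40)),
    stringsAsFactors = FALSE)
  tax <- setNames(c(rep("P1", 15), rep("P2", 60)), states$genome_id)
  res <- phylum_enrichment(states, tax, "conventional_plus")
  r1 <- res[res$phylum == "P1", ]
  expect_equal(r1$odds_ratio, 4)
  # exhaustive hypergeometric two-sided p (all tables with fixed margins)
  probs <- dhyper(0:15, 30, 45, 15)
  p_oracle <- sum(probs[probs <= probs[10 + 1] * (1 + 1e-7)])
  expect_lt(abs(r1$p_value - p_oracle), 1e-12)

  # symmetric table: OR 1, p 1
  st2 <- data.frame(genome_id = paste0("h", 1:40),
                    state = rep(c("conventional_plus", "NHEJ_minus"), 20),
                    stringsAsFactors = FALSE)
  tax2 <- setNames(rep(c("A", "B"), each = 20), st2$genome_id)
  res2 <- phylum_enrichment(st2, tax2, "conventional_plus")
  expect_equal(res2$odds_ratio, c(1, 1))
  expect_equal(res2$p_value, c(1, 1))

  # zero focal cell: raw OR 0, continuity-corrected version reported
  st3 <- data.frame(
    genome_id = paste0("k", 1:65),
    state = c(rep("NHEJ_minus", 5), rep("conventional_plus", 20),
              rep("NHEJ_minus", 40)), stringsAsFactors = FALSE)
  tax3 <- setNames(c(rep("Z", 5), rep("W", 60)), st3$genome_id)
  res3 <- phylum_enrichment(st3, tax3, "conventional_plus")
  rz <- res3[res3$phylum == "Z", ]
  expect_equal(rz$odds_ratio, 0)
  expect_false(is.na(rz$odds_ratio_haldane))
})
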