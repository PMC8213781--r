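# A small universe with one detected locus, built by hand: 6 in-locus
# genes and 14 background genes across two genomes/phyla.
mini_universe <- function() {
  in_pf <- list(c("PFA", "PFB"), "PFA", c("PFA", "PFC"), "PFA", "PFB", "PFA")
  bg_pf <- c(rep(list("PFA"), 2), rep(list("PFD"), 6), rep(list(character(0)), 6))
  g1 <- make_genes((1:6) * 1000, (1:6) * 1000 + 800, pfams = in_pf,
                   genome = "gen1", ids = paste0("in", 1:6))
  g2 <- make_genes((1:14) * 1000, (1:14) * 1000 + 800, pfams = bg_pf,
                   scaffold = "s9", genome = "gen2", ids = paste0("bg", 1:14))
  genes <- dplyr::bind_rows(g1, g2)
  loci <- tibble::tibble(
    locus_id = "L1", genome_id = "gen1", scaffold_id = "s1",
    start = 1000L, end = 6800L, first_gene = "in1", last_gene = "in6",
    n_genes = 6L, n_core_genes = 10L, roles = list("afp16"),
    has_specific_core = TRUE, member_gene_ids = list(paste0("in", 1:6)),
    core_roles = list(list()))
  list(genes = genes, loci = loci)
}

test_that("per-gene domain sets deduplicate repeat domains", {
  g <- make_genes(c(100, 600, 1200), c(400, 900, 1500),
                  pfams = list(c("PF00191", "PF00191", "PF00191"),
                               c("PF00191", "PF00045"), character(0)))
  sets <- gene_domain_sets(g)
  expect_equal(sets$pfams[[1]], "PF00191")
  expect_setequal(sets$pfams[[2]], c("PF00191", "PF00045"))
  expect_length(sets$pfams[[3]], 0)
})

test_that("enrichment tables match an independent brute-force count", {
  u <- mini_universe()
  res <- suppressMessages(pfam_enrichment(u$loci, u$genes))
  expect_setequal(res$pfam, c("PFA", "PFB", "PFC"))
  # brute-force scan of in-locus counts and totals
  in_ids <- unlist(u$loci$member_gene_ids)
  for (pf in res$pfam) {
    carries <- vapply(seq_len(nrow(u$genes)),
                      function(i) pf %in% u$genes$pfams[[i]], logical(1))
    a_brute <- sum(carries & u$genes$gene_id %in% in_ids)
    c_brute <- sum(carries & !u$genes$gene_id %in% in_ids)
    row <- res[res$pfam == pf, ]
    expect_equal(row$a, a_brute)
    expect_equal(row$c, c_brute)
    expect_equal(row$a + row$b + row$c + row$d, nrow(u$genes))
  }
  # PFC is in-locus only: infinite odds ratio sentinel survives
  expect_equal(res$odds_ratio[res$pfam == "PFC"], Inf)
  # oracle check of one full Fisher row
  rowA <- res[res$pfam == "PFA", ]
  or <- fisher_oracle(rowA$a, rowA$b, rowA$c, rowA$d)
  expect_equal(rowA$p, or$p, tolerance = 1e-12)
  expect_equal(rowA$odds_ratio, or$odds_ratio)
})

test_that("duplicated domains within one gene never change the tables", {
  u <- mini_universe()
  base <- suppressMessages(pfam_enrichment(u$loci, u$genes))
  dup <- u$genes
  dup$pfams[[1]] <- rep(dup$pfams[[1]], 3)
  dup$pfams[[8]] <- rep(dup$pfams[[8]], 5)
  again <- suppressMessages(pfam_enrichment(u$loci, dup))
  expect_equal(again, base)
})

test_that("phylum spread drives the core/shell/cloud classes", {
  expect_equal(pan_class(c(3, 4, 10, 11, 13)),
               c("cloud", "shell", "shell", "core", "core"))
  expect_error(pan_class(-1), "non-negative")
  u <- mini_universe()
  phyla <- tibble::tibble(genome_id = c("gen1", "gen2"),
                          phylum = c("Proteobacteria", "Bacteroidetes"))
  res <- pfam_enrichment(u$loci, u$genes, phyla)
  # all in-locus genes are from gen1: one phylum, cloud class
  expect_true(all(res$n_phyla == 1))
  expect_true(all(res$pan_class == "cloud"))
  # unmapped genomes pool into a pseudo-phylum
  res2 <- pfam_enrichment(u$loci, u$genes, phyla[0, ])
  expect_true(all(res2$n_phyla == 1))
})

test_that("q-values of zero are clamped to 1e-250 for plotting", {
  n <- 800
  in_genes <- make_genes((1:n) * 1000, (1:n) * 1000 + 800,
                         pfams = rep(list("PFZ"), n), genome = "gen1",
                         ids = paste0("in", 1:n))
  bg <- make_genes((1:n) * 1000, (1:n) * 1000 + 800,
                   pfams = rep(list("PFQ"), n), scaffold = "s9",
                   genome = "gen2", ids = paste0("bg", 1:n))
  loci <- tibble::tibble(
    locus_id = "L1", genome_id = "gen1", scaffold_id = "s1",
    start = 1L, end = 10L, first_gene = "in1", last_gene = paste0("in", n),
    n_genes = n, n_core_genes = 10L, roles = list("afp16"),
    has_specific_core = TRUE, member_gene_ids = list(paste0("in", 1:n)),
    core_roles = list(list()))
  res <- suppressMessages(pfam_enrichment(loci, dplyr::bind_rows(in_genes, bg)))
  # the p-value underflows to exactly zero at this separation
  expect_equal(res$q[res$pfam == "PFZ"], 1e-250)
  expect_equal(res$neg_log10_q[res$pfam == "PFZ"], 250)
})

test_that("an empty locus table warns and returns an empty result", {
  u <- mini_universe()
  expect_warning(res <- pfam_enrichment(u$loci[0, ], u$genes), "Empty locus")
  expect_equal(nrow(res), 0)
})
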