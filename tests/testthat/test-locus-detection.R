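# A hand-built operon whose roles come entirely from the pfam map: twelve
# genes cycling the four seed pfams, one of them also carrying DUF4255
# (PF14065 -> afp16, an eCIS-specific core).
hand_operon <- function(origin, scaffold = "s1", genome = "gA", ids = NULL) {
  seed_pfams <- c("PF06841", "PF04984", "PF04965", "PF04865")
  starts <- origin + (0:11) * 1100L
  pf <- as.list(rep(seed_pfams, 3))
  pf[[6]] <- c(pf[[6]], "PF14065")
  make_genes(starts, starts + 899L, pfams = pf, scaffold = scaffold,
             genome = genome, ids = ids %||% paste0("op", origin, "_", 1:12))
}

test_that("seed chaining respects the inclusive 12 kb linkage gap", {
  # gaps: 5,000 then 13,000
  g <- make_genes(c(1, 6002, 20003), c(1001, 7002, 21003),
                  pfams = list("PF14065", "PF06841", "PF04984"))
  grp <- chain_seed_groups(collect_seed_genes(g), 12000)
  expect_equal(vapply(grp$genes, nrow, integer(1)), c(2L, 1L))
  # a gap of exactly 12,000 bp stays in one group
  g2 <- make_genes(c(1, 13002), c(1001, 14002),
                   pfams = list("PF14065", "PF06841"))
  expect_equal(nrow(chain_seed_groups(collect_seed_genes(g2), 12000)), 1)
  g3 <- make_genes(c(1, 13003), c(1001, 14003),
                   pfams = list("PF14065", "PF06841"))
  expect_equal(nrow(chain_seed_groups(collect_seed_genes(g3), 12000)), 2)
  # different scaffolds never co-group
  g4 <- make_genes(c(1, 1200), c(1001, 2200), pfams = list("PF14065", "PF06841"),
                   scaffold = c("s1", "s2"))
  expect_equal(nrow(chain_seed_groups(collect_seed_genes(g4), 12000)), 2)
})

test_that("seed genes require eCIS pfams and protein-coding status", {
  g <- make_genes(c(1, 1200, 2400), c(1000, 2200, 3400),
                  pfams = list("PF14065", "PF99999", character(0)),
                  pc = c(TRUE, TRUE, TRUE))
  expect_equal(collect_seed_genes(g)$gene_id, "g1")
  g$is_protein_coding[1] <- FALSE
  expect_equal(nrow(collect_seed_genes(g)), 0)
})

test_that("the seed filter needs four members and three distinct pfams", {
  mk_group <- function(pfams) {
    g <- make_genes(seq_along(pfams) * 1500, seq_along(pfams) * 1500 + 900,
                    pfams = as.list(pfams))
    chain_seed_groups(collect_seed_genes(g), 12000)
  }
  ok <- seed_filter(mk_group(c("PF06841", "PF04984", "PF04965", "PF04965")))
  expect_true(ok$accept)
  same <- seed_filter(mk_group(rep("PF06841", 5)))
  expect_false(same$accept)
  expect_match(same$reason, "distinct")
  few <- seed_filter(mk_group(c("PF06841", "PF04984", "PF04965")))
  expect_false(few$accept)
  expect_match(few$reason, "seed genes")
})

test_that("the contamination screen applies the inclusive 10 kb window", {
  op <- hand_operon(30000)
  camp <- function(offset, pf = "PF03864", cg = character(0)) {
    blocker <- make_genes(30000 - offset - 901, 30000 - offset - 1,
                          pfams = list(pf), cogs = list(cg), ids = "blk")
    genes <- sort_genes_for_test(dplyr::bind_rows(op, blocker))
    grp <- seed_filter(chain_seed_groups(collect_seed_genes(genes), 12000))
    contamination_screen(grp, genes)
  }
  near <- camp(8000)
  expect_false(near$clean)
  expect_equal(near$offending_gene, "blk")
  expect_equal(near$contamination_rule, "phage_pfam")
  expect_true(camp(11000)$clean)
  expect_equal(camp(10000)$clean, FALSE)  # window is inclusive
  t6 <- camp(8000, pf = character(0), cg = "COG3523")
  expect_false(t6$clean)
  expect_equal(t6$contamination_rule, "t6ss_cog")
  # a member itself carrying a blocklisted COG contaminates the group
  op2 <- hand_operon(30000)
  op2$cogs[[3]] <- "COG3523"
  grp <- seed_filter(chain_seed_groups(collect_seed_genes(op2), 12000))
  expect_false(contamination_screen(grp, op2)$clean)
})

test_that("expansion adds protein-coding genes only and clips at scaffold ends", {
  op <- hand_operon(1)  # at scaffold start: upstream expansion empty
  down <- make_genes(14000 + (0:6) * 1100, 14000 + (0:6) * 1100 + 899,
                     ids = paste0("dn", 1:7))
  rna <- make_genes(c(13500, 15000), c(13580, 15080), pc = c(FALSE, FALSE),
                    ids = c("r1", "r2"))
  genes <- sort_genes_for_test(dplyr::bind_rows(op, down, rna))
  grp <- seed_filter(chain_seed_groups(collect_seed_genes(genes), 12000))
  cand <- expand_group(grp, genes, 10)
  exp_ids <- cand$expanded[[1]]$gene_id
  # all 7 available downstream genes taken, the 10-gene budget not consumed
  # by the interleaved non-coding genes, which are skipped entirely
  expect_true(all(paste0("dn", 1:7) %in% exp_ids))
  expect_false(any(c("r1", "r2") %in% exp_ids))
  expect_equal(length(exp_ids), 12 + 7)
})

test_that("finalization enforces the core census and the pyocin screen", {
  mk_cand <- function(genes) {
    grp <- chain_seed_groups(collect_seed_genes(genes), 12000)
    cand <- expand_group(grp, genes, 10)
    cand
  }
  roles_for <- function(genes) assign_core_roles(genes, make_hits(character(0), character(0), double(0)))
  # exactly 10 core genes including one specific core -> accepted
  op10 <- hand_operon(1)[1:10, ]
  fin <- finalize_locus(mk_cand(op10), roles_for(op10), op10)
  expect_equal(nrow(fin$loci), 1)
  expect_equal(fin$loci$n_core_genes, 10L)
  expect_true("afp16" %in% fin$loci$roles[[1]])
  # 12 cores but no specific core: a pyocin-like cassette is rejected
  pyo <- hand_operon(1)
  pyo$pfams[[6]] <- setdiff(pyo$pfams[[6]], "PF14065")
  fin2 <- finalize_locus(mk_cand(pyo), roles_for(pyo), pyo)
  expect_equal(nrow(fin2$loci), 0)
  expect_match(fin2$rejections$reason, "specific core")
  # 9 cores incl. a specific core still fails the census
  op9 <- hand_operon(1)[1:9, ]
  fin3 <- finalize_locus(mk_cand(op9), roles_for(op9), op9)
  expect_equal(nrow(fin3$loci), 0)
  expect_match(fin3$rejections$reason, "core count")
})

test_that("locus boundaries take four protein-coding flank genes, clipped", {
  op <- hand_operon(30000)
  up <- make_genes(20000 + (0:5) * 1100, 20000 + (0:5) * 1100 + 899,
                   ids = paste0("up", 1:6))
  down <- make_genes(44000 + (0:2) * 1100, 44000 + (0:2) * 1100 + 899,
                     ids = paste0("dn", 1:3))
  genes <- sort_genes_for_test(dplyr::bind_rows(up, op, down))
  loci <- detect_loci(genes, make_hits(character(0), character(0), double(0)))
  expect_equal(nrow(loci), 1)
  ids <- loci$member_gene_ids[[1]]
  # four upstream flanks, all three available downstream flanks
  expect_true(all(paste0("up", 3:6) %in% ids))
  expect_false(any(paste0("up", 1:2) %in% ids))
  expect_true(all(paste0("dn", 1:3) %in% ids))
  expect_equal(length(ids), 4 + 12 + 3)
})

test_that("detection recovers planted operons and resists nearby decoys", {
  sim <- sim_genome(list(plant_spec("ecis_valid")), seed = 11)
  loci <- detect_loci(sim$genes, sim$hmm_hits)
  expect_equal(nrow(loci), 1)
  expect_true(all(sim$manifest$planted_gene_ids[[1]] %in% loci$member_gene_ids[[1]]))
  # a capsid gene 5 kb from the operon kills it
  simd <- sim_genome(list(plant_spec("phage_decoy", contaminant_offset_bp = 5000)),
                     seed = 11)
  expect_equal(nrow(detect_loci(simd$genes, simd$hmm_hits)), 0)
  # two valid operons 200 kb apart on one scaffold, separated by ordinary
  # genes, are reported separately
  between <- make_genes(30000 + (0:39) * 4000, 30000 + (0:39) * 4000 + 899,
                        ids = paste0("mid", 1:40))
  two <- sort_genes_for_test(dplyr::bind_rows(
    hand_operon(5000, ids = paste0("a", 1:12)),
    between,
    hand_operon(205000, ids = paste0("b", 1:12))))
  loci2 <- detect_loci(two, make_hits(character(0), character(0), double(0)))
  expect_equal(nrow(loci2), 2)
  expect_true(all(paste0("a", 1:12) %in% loci2$member_gene_ids[[1]]))
  expect_true(all(paste0("b", 1:12) %in% loci2$member_gene_ids[[2]]))
  expect_false(any(paste0("a", 1:12) %in% loci2$member_gene_ids[[2]]))
})

test_that("every emitted locus satisfies its structural invariants", {
  kinds <- c("ecis_valid", "ecis_no_specific_core", "ecis_undersized",
             "phage_decoy", "t6ss_decoy", "empty")
  cfg <- core_config()
  for (sd in 1:3) {
    sim <- sim_genome(lapply(kinds, plant_spec), seed = sd)
    loci <- detect_loci(sim$genes, sim$hmm_hits, cfg)
    for (i in seq_len(nrow(loci))) {
      expect_gte(loci$n_core_genes[i], cfg$thresholds$min_core_genes)
      expect_true(any(loci$roles[[i]] %in% cfg$specific_cores))
      members <- sim$genes[match(loci$member_gene_ids[[i]], sim$genes$gene_id), ]
      expect_equal(unique(members$scaffold_id), loci$scaffold_id[i])
      expect_false(is.unsorted(members$start))
    }
  }
})

test_that("mirroring a scaffold mirrors the detected loci", {
  kinds <- c("ecis_valid", "phage_decoy", "ecis_undersized")
  sim <- sim_genome(lapply(kinds, plant_spec), seed = 21)
  loci <- detect_loci(sim$genes, sim$hmm_hits)
  L <- max(sim$genes$end) + 1000L
  mirrored <- sim$genes
  mirrored$start <- L - sim$genes$end + 1L
  mirrored$end <- L - sim$genes$start + 1L
  mirrored$strand <- ifelse(sim$genes$strand == "+", "-", "+")
  loci_m <- detect_loci(mirrored, sim$hmm_hits)
  expect_equal(nrow(loci_m), nrow(loci))
  key <- function(l, flip) {
    s <- if (flip) L - l$end + 1L else l$start
    e <- if (flip) L - l$start + 1L else l$end
    sort(paste(l$scaffold_id, s, e))
  }
  expect_equal(key(loci_m, TRUE), key(loci, FALSE))
})

test_that("lowering the core-census threshold never removes a locus", {
  kinds <- c("ecis_valid", "ecis_undersized", "ecis_no_specific_core")
  sim <- sim_genome(lapply(kinds, plant_spec), seed = 31)
  strict <- detect_loci(sim$genes, sim$hmm_hits, core_config())
  lax <- detect_loci(sim$genes, sim$hmm_hits,
                     core_config(thresholds = list(min_core_genes = 5)))
  expect_true(all(strict$scaffold_id %in% lax$scaffold_id))
  expect_gte(nrow(lax), nrow(strict))
  # the undersized plant (6 cores) is recovered once the threshold allows it
  under <- sim$manifest$scaffold_id[sim$manifest$kind == "ecis_undersized"]
  expect_false(under %in% strict$scaffold_id)
  expect_true(under %in% lax$scaffold_id)
})
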