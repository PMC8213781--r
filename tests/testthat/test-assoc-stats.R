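test_that("the sample odds ratio admits exact zero and infinity", {
  # complete fixation: every genome of the genus carries the system
  expect_equal(fisher_exact_2x2(18, 0, 1231, 63507)$odds_ratio, Inf)
  # complete absence across the depleted pathogen genera
  expect_equal(fisher_exact_2x2(0, 18355, 1249, 45152)$odds_ratio, 0)
  sym <- fisher_exact_2x2(1, 1, 1, 1)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)
  expect_true(is.na(fisher_exact_2x2(0, 3, 0, 5)$odds_ratio))  # 0/0
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "positive")
})

test_that("Fisher p-values agree with stats::fisher.test on random tables", {
  set.seed(99)
  for (i in 1:200) {
    tab <- sample(0:25, 4, replace = TRUE)
    if (sum(tab) == 0) next
    mine <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher p is transpose-invariant and the OR inverts on row swap", {
  set.seed(5)
  for (i in 1:50) {
    tab <- sample(0:20, 4, replace = TRUE) + c(1, 0, 0, 1)
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    f <- fisher_exact_2x2(a, b, c, d)
    ft <- fisher_exact_2x2(a, c, b, d)  # transpose
    expect_equal(f$p, ft$p, tolerance = 1e-12)
    fs <- fisher_exact_2x2(c, d, a, b)  # swap rows
    if (is.finite(f$odds_ratio) && f$odds_ratio > 0) {
      expect_equal(fs$odds_ratio, 1 / f$odds_ratio)
    }
  }
})

test_that("BH step-up follows the hand formula and preserves input order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.5)), c(0.10, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
    # q is monotone in p rank order
    expect_false(is.unsorted(q[order(p)]))
  }
})

test_that("genus enrichment matches the hypergeometric oracle and flags reportability", {
  presence <- tibble::tibble(genome_id = paste0("g", 1:1000),
                             ecis = c(rep(1, 10), rep(1, 10), rep(0, 980)))
  taxonomy <- tibble::tibble(genome_id = paste0("g", 1:1000),
                             genus = c(rep("Genus10", 10), rep("Other", 990)))
  res <- genus_enrichment(presence, taxonomy)
  top <- res[res$genus == "Genus10", ]
  expect_equal(c(top$a, top$b, top$c, top$d), c(10, 0, 10, 980))
  or <- fisher_oracle(10, 0, 10, 980)
  expect_equal(top$p, or$p, tolerance = 1e-12)
  expect_equal(top$odds_ratio, Inf)
  expect_true(top$reportable)
  # a genus with nine genomes is computed but not reportable
  tax9 <- taxonomy
  tax9$genus[1] <- "Other"
  tax9$genus[2:10] <- "Genus9"
  res9 <- genus_enrichment(presence, tax9)
  g9 <- res9[res9$genus == "Genus9", ]
  expect_lt(g9$q, 0.001)
  expect_false(g9$reportable)
  # genomes only in the taxonomy are skipped with a warning
  expect_warning(
    genus_enrichment(presence, dplyr::bind_rows(
      taxonomy, tibble::tibble(genome_id = "ghost", genus = "X"))),
    "skipped")
})

test_that("contrasting pairs: worked four-tip examples", {
  tr <- read_newick(text = "((A,B),(C,D));")
  tt <- tibble::tibble(genome_id = c("A", "B", "C", "D"),
                       ecis = c(1, 0, 1, 0), trait = c(1, 0, 1, 0))
  r <- max_contrasting_pairs(tt, tr)
  expect_equal(r$max_pairs, 2L)
  expect_equal(r$best_support, 2L)
  expect_equal(r$p_best, 0.25)
  # both traits follow one clade: only one independent contrast exists
  tt2 <- tibble::tibble(genome_id = c("A", "B", "C", "D"),
                        ecis = c(1, 1, 0, 0), trait = c(1, 1, 0, 0))
  expect_equal(max_contrasting_pairs(tt2, tr)$max_pairs, 1L)
  # no genotype variation: nothing to pair, p undefined
  tt3 <- tibble::tibble(genome_id = c("A", "B", "C", "D"),
                        ecis = 0, trait = c(1, 0, 1, 0))
  r3 <- max_contrasting_pairs(tt3, tr)
  expect_equal(r3$max_pairs, 0L)
  expect_true(is.na(r3$p_best))
})

test_that("contrasting pairs prune missing tips and off-tree rows with warnings", {
  tr <- read_newick(text = "((A,B),(C,D));")
  tt <- tibble::tibble(genome_id = c("A", "B", "C", "D", "E"),
                       ecis = c(1, 0, 1, NA, 1), trait = c(1, 0, 1, 0, 1))
  expect_warning(r <- max_contrasting_pairs(tt, tr), "absent from the tree")
  expect_equal(r$n_tips_used, 3L)
})

test_that("contrasting pairs match brute force on random trees", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    rt <- random_tree_traits(n, allow_polytomy = i %% 3 == 0)
    tt <- tibble::tibble(genome_id = rt$tree$tip.label,
                         ecis = unname(rt$g), trait = unname(rt$p))
    mine <- max_contrasting_pairs(tt, rt$tree)
    ref <- pairs_brute(rt$tree, rt$g, rt$p)
    expect_equal(mine$max_pairs, ref$max_pairs)
    expect_equal(mine$best_support, ref$best_support)
    expect_equal(mine$worst_support, ref$worst_support)
  }
})

test_that("clade-confounded traits collapse to one pair regardless of tip count", {
  for (n in c(8, 16, 32)) {
    st <- sim_tree_traits(n, "clade_confounded", seed = n)
    expect_equal(max_contrasting_pairs(st$traits, st$tree)$max_pairs, 1L)
  }
})

test_that("trait association pairs Fisher and pairwise statistics per trait", {
  st <- sim_tree_traits(16, "independent_assoc", seed = 4)
  traits <- st$traits
  traits$unrelated <- rep(c(0L, 1L), 8)
  res <- trait_association(traits, st$tree)
  expect_setequal(res$trait, c("trait", "unrelated"))
  strong <- res[res$trait == "trait", ]
  expect_equal(strong$max_pairs, 8L)
  expect_equal(strong$best_support, 8L)
  expect_lt(strong$p_best, 0.005)
  expect_lt(strong$q_fisher, 0.01)
  expect_true(all(c("q_fisher", "p_worst") %in% names(res)))
})
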