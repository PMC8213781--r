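# Phylogeny-aware association: the pairwise-comparison (contrasting pairs)
# test. A contrasting pair is two tips, from different clades, that differ
# in BOTH genotype and phenotype; tip pairs are vertex-disjoint and their
# connecting paths edge-disjoint (paths may share internal nodes), so each
# pair is an independent instance of the association. A pair supports the
# association when the genotype-1 tip is also phenotype-1 (and the
# genotype-0 tip phenotype-0); otherwise it opposes. Under no association
# a pair supports or opposes with equal probability, so support counts are
# sign-tested against Binomial(max_pairs, 1/2).

# Pairing arithmetic at one node. Tokens are unpaired tips classified by
# (genotype, phenotype): counts n00, n01, n10, n11. Allowed matches are
# 11-00 (supporting) and 10-01 (opposing), so at a node
# pairs = min(n11, n00) + min(n10, n01) and the support added is fixed.
pool_match <- function(n00, n01, n10, n11) {
  s <- min(n11, n00)
  c(pairs = s + min(n10, n01), sup = s)
}

# Post-order DP over the rooted tree. Each subtree reports, for every
# "exported token" state (N = none, or one unpaired tip of class 00/01/
# 10/11 still reachable edge-disjointly through the subtree's root edge),
# the maximum pair count and the min/max support attainable at that count.
# At most one tip can be exported per subtree because any pair crossing
# the subtree boundary must use its root edge.
pairs_dp <- function(tree, g, p) {
  ntip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(edge[, 2], edge[, 1])
  nodes_post <- unique(edge[, 1])
  token_names <- c("00", "01", "10", "11")
  val <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    v <- list(N = c(0, 0, 0))
    v[[paste0(g[i], p[i])]] <- c(0, 0, 0)
    val[[i]] <- v
  }
  for (nd in nodes_post) {
    pool <- list("0,0,0,0" = c(0, 0, 0))
    for (ch in children[[as.character(nd)]]) {
      cv <- val[[ch]]
      newpool <- list()
      for (k in names(pool)) {
        cnt <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
        pv <- pool[[k]]
        for (s in names(cv)) {
          e <- cv[[s]]
          nc <- cnt
          if (s != "N") {
            idx <- match(s, token_names)
            nc[idx] <- nc[idx] + 1L
          }
          nk <- paste(nc, collapse = ",")
          cand <- pv + e
          old <- newpool[[nk]]
          if (is.null(old) || cand[1] > old[1]) {
            newpool[[nk]] <- cand
          } else if (cand[1] == old[1]) {
            newpool[[nk]] <- c(old[1], min(old[2], cand[2]), max(old[3], cand[3]))
          }
        }
      }
      pool <- newpool
    }
    out <- list()
    upd <- function(s, cand) {
      old <- out[[s]]
      if (is.null(old) || cand[1] > old[1]) {
        out[[s]] <<- cand
      } else if (cand[1] == old[1]) {
        out[[s]] <<- c(old[1], min(old[2], cand[2]), max(old[3], cand[3]))
      }
    }
    for (k in names(pool)) {
      cnt <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
      pv <- pool[[k]]
      m <- pool_match(cnt[1], cnt[2], cnt[3], cnt[4])
      upd("N", pv + c(m[["pairs"]], m[["sup"]], m[["sup"]]))
      for (idx in 1:4) {
        if (cnt[idx] > 0) {
          nc <- cnt
          nc[idx] <- nc[idx] - 1L
          m2 <- pool_match(nc[1], nc[2], nc[3], nc[4])
          upd(token_names[idx], pv + c(m2[["pairs"]], m2[["sup"]], m2[["sup"]]))
        }
      }
    }
    val[[nd]] <- out
  }
  root <- val[[ntip + 1L]]
  best <- NULL
  for (s in names(root)) {
    e <- root[[s]]
    if (is.null(best) || e[1] > best[1]) {
      best <- e
    } else if (e[1] == best[1]) {
      best <- c(best[1], min(best[2], e[2]), max(best[3], e[3]))
    }
  }
  list(max_pairs = as.integer(best[1]),
       worst_support = as.integer(best[2]),
       best_support = as.integer(best[3]))
}

#' Maximum contrasting pairs on a phylogeny
#'
#' Finds the maximum number of vertex-disjoint tip pairs with edge-disjoint
#' connecting paths such that the two tips of each pair differ in both
#' genotype and phenotype, by post-order dynamic programming over the
#' rooted tree. Among all maximum pairings it reports the best and worst
#' attainable number of supporting pairs (genotype-1 tip also phenotype-1),
#' and the corresponding upper-tail binomial probabilities of at least
#' that much support in `max_pairs` tosses of a fair coin. When the two
#' traits are both determined by a single clade, `max_pairs` is 1 no
#' matter how many tips carry them: the association collapses to one
#' phylogenetically independent observation, which is the entire point of
#' the test.
#'
#' Tips with a missing state, and table rows absent from the tree, are
#' pruned per trait with a warning.
#'
#' @param traits Tibble with a `genome_id` column matching tip labels and
#'   binary (0/1) trait columns.
#' @param tree A rooted [ape::phylo] tree (polytomies allowed).
#' @param genotype,phenotype Names of the two trait columns (genotype is
#'   typically eCIS presence).
#' @return A one-row tibble: `n_tips_used`, `max_pairs`, `best_support`,
#'   `worst_support`, `p_best`, `p_worst` (p-values `NA` when
#'   `max_pairs` is 0).
#' @examples
#' tr <- read_newick(text = "((A,B),(C,D));")
#' tt <- tibble::tibble(genome_id = c("A", "B", "C", "D"),
#'                      ecis = c(1, 0, 1, 0), trait = c(1, 0, 1, 0))
#' max_contrasting_pairs(tt, tr)  # 2 pairs, both supporting, p_best 0.25
#' @export
max_contrasting_pairs <- function(traits, tree, genotype = "ecis",
                                  phenotype = "trait") {
  stopifnot(inherits(tree, "phylo"))
  if (!all(c("genome_id", genotype, phenotype) %in% names(traits))) {
    abort("`traits` must contain genome_id and the two named trait columns.")
  }
  tt <- traits[, c("genome_id", genotype, phenotype)]
  names(tt) <- c("genome_id", "g", "p")
  off_tree <- setdiff(tt$genome_id, tree$tip.label)
  if (length(off_tree)) {
    warn(paste0(length(off_tree), " trait row(s) absent from the tree pruned."))
  }
  tt <- tt[!is.na(tt$g) & !is.na(tt$p) & tt$genome_id %in% tree$tip.label, ,
           drop = FALSE]
  drop <- setdiff(tree$tip.label, tt$genome_id)
  if (length(drop) && length(drop) < length(tree$tip.label)) {
    tree <- ape::drop.tip(tree, drop)
  }
  if (is.null(tree) || length(tree$tip.label) < 2 || nrow(tt) < 2) {
    return(tibble(n_tips_used = nrow(tt), max_pairs = 0L, best_support = 0L,
                  worst_support = 0L, p_best = NA_real_, p_worst = NA_real_))
  }
  g <- setNames(tt$g, tt$genome_id)[tree$tip.label]
  p <- setNames(tt$p, tt$genome_id)[tree$tip.label]
  res <- pairs_dp(tree, g, p)
  tail_p <- function(s, m) {
    if (m == 0) NA_real_ else pbinom(s - 1, m, 0.5, lower.tail = FALSE)
  }
  tibble(n_tips_used = length(tree$tip.label),
         max_pairs = res$max_pairs,
         best_support = res$best_support,
         worst_support = res$worst_support,
         p_best = tail_p(res$best_support, res$max_pairs),
         p_worst = tail_p(res$worst_support, res$max_pairs))
}

#' Trait association: Fisher test plus contrasting pairs
#'
#' For every trait column (other than the presence column), builds the 2x2
#' table of trait vs presence over genomes, computes the two-sided Fisher
#' test with BH correction across traits, and runs the phylogeny-aware
#' contrasting-pairs test with presence as genotype and the trait as
#' phenotype. This mirrors the paired reporting of a taxonomy-blind and a
#' taxonomy-aware q-value per trait.
#'
#' @param traits Tibble with `genome_id`, the presence column and one or
#'   more binary trait columns.
#' @param tree A rooted [ape::phylo] tree.
#' @param presence Name of the presence column (default `"ecis"`).
#' @return A tibble with one row per trait: counts `a` (presence+ trait+),
#'   `b` (presence+ trait-), `c`, `d`, `odds_ratio`, `p_fisher`,
#'   `q_fisher`, and the pairwise-comparison columns of
#'   [max_contrasting_pairs()].
#' @export
trait_association <- function(traits, tree, presence = "ecis") {
  trait_cols <- setdiff(names(traits), c("genome_id", presence))
  if (!length(trait_cols)) abort("No trait columns besides the presence column.")
  rows <- lapply(trait_cols, function(tc) {
    ok <- !is.na(traits[[presence]]) & !is.na(traits[[tc]])
    pres <- traits[[presence]][ok]
    trt <- traits[[tc]][ok]
    ft <- fisher_exact_2x2(sum(pres == 1 & trt == 1), sum(pres == 1 & trt == 0),
                           sum(pres == 0 & trt == 1), sum(pres == 0 & trt == 0))
    pw <- max_contrasting_pairs(traits[ok, , drop = FALSE], tree,
                                genotype = presence, phenotype = tc)
    dplyr::bind_cols(tibble(trait = tc), ft, pw)
  })
  out <- rename(bind_rows(rows), p_fisher = "p")
  out$q_fisher <- bh_adjust(out$p_fisher)
  out <- out[, c("trait", "a", "b", "c", "d", "odds_ratio", "p_fisher", "q_fisher",
                 "n_tips_used", "max_pairs", "best_support", "worst_support",
                 "p_best", "p_worst")]
  arrange(out, .data$q_fisher, .data$trait)
}
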