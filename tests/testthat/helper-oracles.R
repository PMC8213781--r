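# Independent oracles used by property and acceptance tests. These are
# deliberately written with different machinery than the implementation:
# the Fisher oracle enumerates hypergeometric probabilities via lchoose,
# the BH oracle applies the step-up formula literally, and the pairs
# oracle searches all edge-disjoint contrasting pairings exhaustively.

fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  lp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  probs <- exp(lp)
  obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  num <- a * d; den <- b * c
  or <- if (num == 0 && den == 0) NA_real_ else if (den == 0) Inf else num / den
  list(odds_ratio = or, p = p)
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Brute-force contrasting pairs: pairs of tips differing in BOTH genotype
# and phenotype, vertex-disjoint tips, edge-disjoint paths (shared internal
# nodes allowed). Returns max pairs and the min/max supporting count over
# all maximum pairings.
pairs_brute <- function(tree, genotype, phenotype) {
  ntip <- length(tree$tip.label)
  g <- genotype[tree$tip.label]
  p <- phenotype[tree$tip.label]
  cand <- list()
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      if (g[i] != g[j] && p[i] != p[j]) {
        np <- ape::nodepath(tree, i, j)
        edges <- paste(pmin(head(np, -1), tail(np, -1)),
                       pmax(head(np, -1), tail(np, -1)))
        u <- if (g[i] == 1) i else j
        v <- if (g[i] == 1) j else i
        cand[[length(cand) + 1]] <- list(
          i = i, j = j, edges = edges,
          sup = as.integer(p[u] == 1 && p[v] == 0))
      }
    }
  }
  best <- 0L; smin <- 0L; smax <- 0L
  rec <- function(tip, used_tips, used_edges, npairs, sup) {
    if (tip > ntip) {
      if (npairs > best) {
        best <<- npairs; smin <<- sup; smax <<- sup
      } else if (npairs == best) {
        smin <<- min(smin, sup); smax <<- max(smax, sup)
      }
      return(invisible())
    }
    if (used_tips[tip]) {
      rec(tip + 1L, used_tips, used_edges, npairs, sup)
      return(invisible())
    }
    rec(tip + 1L, used_tips, used_edges, npairs, sup)  # leave tip unpaired
    for (pr in cand) {
      if (pr$i == tip && !used_tips[pr$j] && !any(pr$edges %in% used_edges)) {
        ut <- used_tips
        ut[c(pr$i, pr$j)] <- TRUE
        rec(tip + 1L, ut, c(used_edges, pr$edges), npairs + 1L, sup + pr$sup)
      }
    }
  }
  rec(1L, rep(FALSE, ntip), character(0), 0L, 0L)
  list(max_pairs = best, worst_support = smin, best_support = smax)
}

random_tree_traits <- function(n, allow_polytomy = FALSE) {
  tr <- ape::rtree(n)
  if (allow_polytomy) {
    tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.3))
  }
  list(tree = tr,
       g = stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label),
       p = stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label))
}
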