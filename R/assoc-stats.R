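# Fisher exact 2x2 machinery with Benjamini-Hochberg correction, used for
# genus, trait and pfam enrichment.

#' Two-sided Fisher exact test on 2x2 tables
#'
#' Vectorized over tables laid out as
#' \preformatted{          outcome+  outcome-
#'   group A     a         b
#'   group B     c         d}
#' The odds ratio is the unconditional sample OR, `(a*d)/(b*c)`, admitting
#' exact `0` (numerator zero) and `Inf` (denominator zero); `0/0` is `NA`.
#' This is deliberate: depletion down to complete absence prints as an
#' odds ratio of exactly 0, and complete fixation as infinity, which the
#' conditional MLE reported by [stats::fisher.test()] never produces. The
#' p-value is the usual two-sided rule: the sum of probabilities of all
#' tables with the same margins whose hypergeometric probability does not
#' exceed that of the observed table (within a 1e-7 relative tolerance).
#'
#' @param a,b,c,d Non-negative integer count vectors (recycled).
#' @return A tibble with columns `a`, `b`, `c`, `d`, `odds_ratio`, `p`.
#' @examples
#' fisher_exact_2x2(18, 0, 1231, 63507)$odds_ratio  # Inf
#' fisher_exact_2x2(0, 18355, 1249, 45152)$odds_ratio  # 0
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  tab <- tibble(a = as.numeric(a), b = as.numeric(b),
                c = as.numeric(c), d = as.numeric(d))
  with(tab, {
    if (any(is.na(a + b + c + d))) abort("Counts must be non-missing.")
    if (any(c(a, b, c, d) < 0)) abort("Counts must be non-negative.")
    if (any(c(a, b, c, d) != floor(c(a, b, c, d)))) abort("Counts must be integers.")
    if (any(a + b + c + d == 0)) abort("Table total must be positive.")
  })
  num <- tab$a * tab$d
  den <- tab$b * tab$c
  or <- ifelse(num == 0 & den == 0, NA_real_,
        ifelse(den == 0, Inf, num / den))
  p <- vapply(seq_len(nrow(tab)), function(i) {
    m <- tab$a[i] + tab$b[i]   # row 1 total
    n <- tab$c[i] + tab$d[i]   # row 2 total
    k <- tab$a[i] + tab$c[i]   # column 1 total
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    obs <- dhyper(tab$a[i], m, n, k)
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, double(1))
  tibble(a = tab$a, b = tab$b, c = tab$c, d = tab$d, odds_ratio = or, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at
#' 1, returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("`pvalues` must be numeric.")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing.")
  }
  p.adjust(pvalues, method = "BH")
}

#' Genus-level eCIS enrichment
#'
#' One Fisher 2x2 per genus: (genus & eCIS, genus & no eCIS, other &
#' eCIS, other & no eCIS), BH-corrected across all genera tested. A
#' reporting flag marks genera that pass the display rule (q below
#' `q_report` and at least `min_entries` genomes); everything is computed
#' regardless so the full table remains available.
#'
#' @param presence Tibble with columns `genome_id` and `ecis` (0/1).
#' @param taxonomy Tibble with columns `genome_id` and `genus`. Genomes
#'   without a genus label are counted under `"unclassified"`; genomes in
#'   `taxonomy` absent from `presence` are skipped with a warning.
#' @param min_entries Minimum genus size for the reporting flag (default 10).
#' @param q_report q-value cutoff for the reporting flag (default 0.001).
#' @return A tibble with one row per genus: counts, `odds_ratio`, `p`,
#'   `q`, `n_genomes`, `reportable`; sorted by `q`.
#' @export
genus_enrichment <- function(presence, taxonomy, min_entries = 10, q_report = 0.001) {
  stopifnot(all(c("genome_id", "ecis") %in% names(presence)),
            all(c("genome_id", "genus") %in% names(taxonomy)))
  skipped <- setdiff(taxonomy$genome_id, presence$genome_id)
  if (length(skipped)) {
    warn(paste0(length(skipped), " genome(s) in taxonomy absent from the presence",
                " table skipped."))
  }
  dat <- left_join(presence, taxonomy, by = "genome_id")
  dat$genus[is.na(dat$genus)] <- "unclassified"
  total_pos <- sum(dat$ecis == 1)
  total <- nrow(dat)
  per <- dat %>%
    group_by(.data$genus) %>%
    summarise(n_genomes = n(), a = sum(.data$ecis == 1), .groups = "drop") %>%
    mutate(b = .data$n_genomes - .data$a,
           c = total_pos - .data$a,
           d = total - .data$n_genomes - .data$c)
  ft <- fisher_exact_2x2(per$a, per$b, per$c, per$d)
  per$odds_ratio <- ft$odds_ratio
  per$p <- ft$p
  per$q <- bh_adjust(per$p)
  per$reportable <- per$q < q_report & per$n_genomes >= min_entries
  arrange(per, .data$q, .data$genus)
}
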