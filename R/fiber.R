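# Tail-fiber (Afp13) target classification from dual-database BLAST
# results: does a fiber look more like tailed-phage fibers (suggesting
# prokaryotic targets) or eukaryotic-virus fibers?

#' Select the high-confidence Afp13 fiber set
#'
#' Genes labelled afp13 by HMM search whose best bitscore ranks in the top
#' `ceiling(top_fraction * n)` of genes; ties at the cut are kept.
#'
#' @param afp13_hits HMM hit tibble restricted to the afp13 profile (rows
#'   for other profiles are ignored with a message).
#' @param top_fraction Fraction of genes kept (default 0.25, the top
#'   quartile).
#' @return Character vector of selected gene ids.
#' @export
select_fiber_set <- function(afp13_hits, top_fraction = 0.25) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must be in (0, 1].")
  }
  other <- afp13_hits$profile_id != "afp13"
  if (any(other)) {
    inform(paste0(sum(other), " non-afp13 hit(s) ignored."))
    afp13_hits <- afp13_hits[!other, , drop = FALSE]
  }
  if (nrow(afp13_hits) == 0) return(character(0))
  best <- afp13_hits %>%
    group_by(.data$gene_id) %>%
    summarise(bitscore = max(.data$bitscore), .groups = "drop")
  k <- ceiling(top_fraction * nrow(best))
  thr <- sort(best$bitscore, decreasing = TRUE)[k]
  best$gene_id[best$bitscore >= thr]
}

#' Classify tail fibers by dual-database bitscore difference
#'
#' For each query gene, hits with E-value at or above `evalue_cut` are
#' discarded; the remaining best (maximum) bitscore per database is
#' compared. A gene is called for a database when its best bitscore
#' exceeds the other database's by more than `delta` bits; a difference
#' within `delta` (inclusive) is inconclusive. A gene with surviving hits
#' in only one database is called for that database; with none, `no_hit`.
#'
#' @param phage_hits,virus_hits BLAST hit tibbles from [read_blast_tab()]
#'   (labels `"phage"` and `"euk_virus"`). Either may be `NULL` or empty,
#'   e.g. when only one search was run.
#' @param gene_ids Optional universe of query genes to report; defaults to
#'   all queries seen in either file. Genes without surviving hits are
#'   reported as `no_hit`.
#' @param evalue_cut E-value cutoff, exclusive (default 1e-3).
#' @param delta Bitscore margin (default 15).
#' @return A tibble of class `ecis_fibers`: `gene_id`,
#'   `best_phage_bitscore`, `best_virus_bitscore`, `call` in
#'   `{"phage", "euk_virus", "inconclusive", "no_hit"}`.
#' @examples
#' ph <- tibble::tibble(query_id = "g1", subject_id = "s", subject_db = "phage",
#'                      bitscore = 100, evalue = 1e-20)
#' vi <- tibble::tibble(query_id = "g1", subject_id = "t", subject_db = "euk_virus",
#'                      bitscore = 80, evalue = 1e-10)
#' classify_fibers(ph, vi)$call  # "phage": difference 20 > 15
#' @export
classify_fibers <- function(phage_hits = NULL, virus_hits = NULL, gene_ids = NULL,
                            evalue_cut = 1e-3, delta = 15) {
  best_of <- function(hits) {
    if (is.null(hits) || nrow(hits) == 0) {
      return(tibble(gene_id = character(), best = double()))
    }
    hits <- hits[hits$evalue < evalue_cut, , drop = FALSE]
    if (nrow(hits) == 0) {
      return(tibble(gene_id = character(), best = double()))
    }
    hits %>%
      group_by(gene_id = .data$query_id) %>%
      summarise(best = max(.data$bitscore), .groups = "drop")
  }
  bp <- best_of(phage_hits)
  bv <- best_of(virus_hits)
  universe <- gene_ids %||%
    sort(unique(c(if (!is.null(phage_hits)) phage_hits$query_id,
                  if (!is.null(virus_hits)) virus_hits$query_id)))
  out <- tibble(gene_id = universe) %>%
    left_join(rename(bp, best_phage_bitscore = "best"), by = "gene_id") %>%
    left_join(rename(bv, best_virus_bitscore = "best"), by = "gene_id")
  out$call <- dplyr::case_when(
    is.na(out$best_phage_bitscore) & is.na(out$best_virus_bitscore) ~ "no_hit",
    is.na(out$best_virus_bitscore) ~ "phage",
    is.na(out$best_phage_bitscore) ~ "euk_virus",
    out$best_phage_bitscore - out$best_virus_bitscore > delta ~ "phage",
    out$best_virus_bitscore - out$best_phage_bitscore > delta ~ "euk_virus",
    TRUE ~ "inconclusive")
  class(out) <- c("ecis_fibers", class(out))
  out
}
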