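# Per-pfam enrichment of domains inside eCIS loci versus the genomic
# background, with core/shell/cloud classification by phylum spread.

#' Deduplicated per-gene domain sets
#'
#' Repeat domains within one gene (typically tandem repeats) are collapsed
#' so each pfam contributes at most once per gene, avoiding inflation of
#' the enrichment counts. Gene tables read through this package already
#' store deduplicated sets; this helper makes the rule explicit for
#' externally built tables.
#'
#' @param genes Gene tibble.
#' @return Tibble with `gene_id` and a deduplicated `pfams` list-column.
#' @export
gene_domain_sets <- function(genes) {
  tibble(gene_id = genes$gene_id, pfams = lapply(genes$pfams, unique))
}

#' Core/shell/cloud classification by phylum spread
#'
#' Domains seen in eCIS loci from more than 10 phyla are "core", from 4-10
#' phyla "shell", from fewer than 4 "cloud" (terms borrowed from
#' pangenomics).
#'
#' @param n_phyla Non-negative integer vector.
#' @return Character vector in `{"core", "shell", "cloud"}`.
#' @examples
#' pan_class(c(3, 4, 10, 11))
#' @export
pan_class <- function(n_phyla) {
  if (any(is.na(n_phyla)) || any(n_phyla < 0)) {
    abort("`n_phyla` must be non-negative.")
  }
  dplyr::case_when(n_phyla > 10 ~ "core",
                   n_phyla >= 4 ~ "shell",
                   TRUE ~ "cloud")
}

#' Pfam enrichment in eCIS loci versus the genomic background
#'
#' For every pfam observed in at least one locus gene, builds the
#' gene-granularity 2x2 table (in-locus genes with / without the domain,
#' background genes with / without), computes the two-sided Fisher test
#' and BH-corrected q-values across pfams, counts the phyla contributing
#' the domain inside loci, and assigns the core/shell/cloud class.
#' q-values that underflow to exactly zero are clamped to 1e-250 so they
#' survive a log transform. The background is whatever gene universe is
#' supplied; at corpus scale that is all genes of all genomes in the run.
#'
#' @param loci Locus table from [detect_loci()] (rows from several genomes
#'   may be bound together).
#' @param genes Gene universe: every protein-coding gene considered,
#'   including all in-locus genes.
#' @param phyla Optional tibble with `genome_id`, `phylum`; genomes
#'   without a mapping are pooled into a pseudo-phylum `"unclassified"`
#'   (flagged with a message).
#' @return A tibble with one row per in-locus pfam: counts, `odds_ratio`,
#'   `log2_odds_ratio`, `p`, `q`, `neg_log10_q`, `n_phyla`, `pan_class`,
#'   sorted by `q`. Infinite odds ratios are preserved as `Inf`.
#' @export
pfam_enrichment <- function(loci, genes, phyla = NULL) {
  if (nrow(loci) == 0) {
    warn("Empty locus table: no enrichment computed.")
    return(tibble(pfam = character(), a = double(), b = double(), c = double(),
                  d = double(), odds_ratio = double(), log2_odds_ratio = double(),
                  p = double(), q = double(), neg_log10_q = double(),
                  n_phyla = integer(), pan_class = character()))
  }
  genes <- genes[genes$is_protein_coding, , drop = FALSE]
  in_ids <- unique(unlist(loci$member_gene_ids))
  missing_ids <- setdiff(in_ids, genes$gene_id)
  if (length(missing_ids)) {
    abort(paste0(length(missing_ids), " in-locus gene(s) missing from the gene",
                 " universe, e.g. ", missing_ids[1]))
  }
  sets <- gene_domain_sets(genes)
  in_mask <- sets$gene_id %in% in_ids
  n_in <- sum(in_mask)
  n_out <- nrow(sets) - n_in
  in_counts <- table(unlist(sets$pfams[in_mask]))
  out_counts <- table(unlist(sets$pfams[!in_mask]))
  pfams <- sort(names(in_counts))
  a <- as.numeric(in_counts[pfams])
  c_ <- as.numeric(out_counts[pfams])
  c_[is.na(c_)] <- 0
  ft <- fisher_exact_2x2(a, n_in - a, c_, n_out - c_)
  q <- bh_adjust(ft$p)
  q[q == 0] <- 1e-250
  # phylum spread of each pfam among locus-contributing genomes
  gene2genome <- setNames(genes$genome_id, genes$gene_id)
  phylum_of <- function(genomes) {
    if (is.null(phyla)) return(rep("unclassified", length(genomes)))
    ph <- setNames(phyla$phylum, phyla$genome_id)[genomes]
    ph[is.na(ph)] <- "unclassified"
    ph
  }
  if (is.null(phyla)) {
    inform("No phylum mapping supplied: all genomes pooled as 'unclassified'.")
  }
  pf_long <- tibble(
    gene_id = rep(sets$gene_id[in_mask], lengths(sets$pfams[in_mask])),
    pfam = unlist(sets$pfams[in_mask])
  )
  pf_long$phylum <- phylum_of(gene2genome[pf_long$gene_id])
  nphy <- pf_long %>%
    group_by(.data$pfam) %>%
    summarise(n_phyla = dplyr::n_distinct(.data$phylum), .groups = "drop")
  out <- tibble(pfam = pfams, a = a, b = n_in - a, c = c_, d = n_out - c_,
                odds_ratio = ft$odds_ratio,
                log2_odds_ratio = log2(ft$odds_ratio),
                p = ft$p, q = q, neg_log10_q = -log10(q))
  out <- left_join(out, nphy, by = "pfam")
  out$pan_class <- pan_class(out$n_phyla)
  arrange(out, .data$q, .data$pfam)
}
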