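# Core-role annotation: merge pfam-map annotations with bitscore
# percentile-filtered HMM hits into per-gene Afp role assignments.

#' Keep the top fraction of HMM hits by bitscore
#'
#' Within each profile (or globally, see `per_profile`), hits are ranked by
#' bitscore descending and the top `ceiling(keep_fraction * n)` are kept;
#' any hit tied with the last kept bitscore is also kept, so equal evidence
#' is never discarded and a lone hit always survives. Input order is
#' preserved. E-values are carried through untouched: this stage filters by
#' bitscore rank only.
#'
#' @param hits Hit tibble from [read_hmm_hits()].
#' @param keep_fraction Fraction in (0, 1]; 0.5 drops the bottom half.
#' @param per_profile If `TRUE` (default) the percentile is computed per
#'   profile over the whole input batch; if `FALSE`, over all hits pooled.
#' @return The filtered hit tibble.
#' @examples
#' h <- tibble::tibble(gene_id = paste0("g", 1:4), profile_id = "afp8",
#'                     bitscore = c(10, 20, 30, 40), evalue = 1e-9)
#' percentile_filter(h, 0.5)  # keeps the 40 and 30 hits
#' @export
percentile_filter <- function(hits, keep_fraction = 0.5, per_profile = TRUE) {
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
      is.na(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    abort("`keep_fraction` must be a single number in (0, 1].")
  }
  if (nrow(hits) == 0) return(hits)
  grp <- if (per_profile) hits$profile_id else rep("all", nrow(hits))
  keep <- logical(nrow(hits))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    bs <- hits$bitscore[idx]
    k <- ceiling(keep_fraction * length(bs))
    thr <- sort(bs, decreasing = TRUE)[k]
    keep[idx] <- bs >= thr
  }
  hits[keep, , drop = FALSE]
}

#' Assign eCIS core roles to genes
#'
#' A gene's role set is the union of (i) roles its pfam annotations map to
#' under `config$pfam_to_role` and (ii) the Afp profiles of its surviving
#' HMM hits (`hits` are expected to be percentile-filtered already; see
#' [percentile_filter()]). Genes with no role are absent from the output;
#' a gene may carry several roles, and the same role may come from both
#' sources. Hits referencing unknown gene ids are dropped with a warning.
#'
#' @param genes Gene tibble.
#' @param hits Filtered HMM hit tibble. Profiles that do not normalize to
#'   `afp1`..`afp16` carry no core role and are ignored here.
#' @param config An [core_config()] object.
#' @return A tibble with one row per (gene, role): columns `gene_id`,
#'   `role`, `from_pfam`, `from_hmm`.
#' @export
assign_core_roles <- function(genes, hits, config = core_config()) {
  map <- config$pfam_to_role
  pfam_part <- tibble(
    gene_id = rep(genes$gene_id, lengths(genes$pfams)),
    pfam = unlist(genes$pfams) %||% character(0)
  )
  pfam_part <- pfam_part[pfam_part$pfam %in% names(map), , drop = FALSE]
  pfam_part$role <- unname(map[pfam_part$pfam])
  pfam_part <- distinct(pfam_part[, c("gene_id", "role")])
  pfam_part$from_pfam <- TRUE

  hmm_part <- hits[hits$profile_id %in% config$roles, , drop = FALSE]
  unknown <- setdiff(unique(hmm_part$gene_id), genes$gene_id)
  if (length(unknown)) {
    warn(paste0(length(unknown), " HMM hit gene id(s) not in the gene table ignored: ",
                paste(utils::head(unknown, 5), collapse = ", ")))
    hmm_part <- hmm_part[!hmm_part$gene_id %in% unknown, , drop = FALSE]
  }
  hmm_part <- distinct(tibble(gene_id = hmm_part$gene_id, role = hmm_part$profile_id))
  hmm_part$from_hmm <- TRUE

  out <- dplyr::full_join(pfam_part, hmm_part, by = c("gene_id", "role"))
  out$from_pfam <- !is.na(out$from_pfam)
  out$from_hmm <- !is.na(out$from_hmm)
  arrange(out, .data$gene_id, .data$role)
}
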