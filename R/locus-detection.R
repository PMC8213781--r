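# eCIS operon detection: seed grouping by physical linkage, seed filters,
# phage/T6SS contamination screens, expansion, core census and boundary
# assignment. All base-pair comparisons are inclusive ("within 12,000 bp"
# keeps a gap of exactly 12,000) and distances are nearest-boundary,
# strand-ignored.

# Nearest-boundary gap between two intervals; 0 when they overlap or abut.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}

sort_genes <- function(genes) {
  genes[order(genes$scaffold_id, genes$start, genes$end, genes$gene_id), , drop = FALSE]
}

#' Select seed genes carrying eCIS-associated pfam domains
#'
#' @param genes Gene tibble for one genome.
#' @param config An [core_config()] object.
#' @return The protein-coding genes whose pfam set intersects the
#'   configured eCIS pfam vocabulary, sorted by (scaffold, start).
#' @export
collect_seed_genes <- function(genes, config = core_config()) {
  ecis_pfams <- names(config$pfam_to_role)
  keep <- genes$is_protein_coding &
    vapply(genes$pfams, function(p) any(p %in% ecis_pfams), logical(1))
  sort_genes(genes[keep, , drop = FALSE])
}

#' Group seed genes by physical linkage
#'
#' Single-linkage chaining per scaffold: walking the seeds in coordinate
#' order, a new group starts whenever the nearest-boundary gap to the
#' previous seed exceeds `max_gap_bp` (a gap of exactly `max_gap_bp` stays
#' in the same group). Seeds on different scaffolds never co-group.
#'
#' @param seeds Seed gene tibble from [collect_seed_genes()].
#' @param max_gap_bp Maximum inclusive gap in base pairs (default 12000).
#' @return A tibble with one row per group: `group_id`, `scaffold_id`,
#'   `genes` (list-column of member gene rows, ordered by start).
#' @export
chain_seed_groups <- function(seeds, max_gap_bp = 12000) {
  if (nrow(seeds) == 0) {
    return(tibble(group_id = character(), scaffold_id = character(), genes = list()))
  }
  seeds <- sort_genes(seeds)
  grp <- integer(nrow(seeds))
  gid <- 0L
  for (i in seq_len(nrow(seeds))) {
    new_group <- i == 1 ||
      seeds$scaffold_id[i] != seeds$scaffold_id[i - 1] ||
      interval_gap(seeds$start[i - 1], seeds$end[i - 1],
                   seeds$start[i], seeds$end[i]) > max_gap_bp
    if (new_group) gid <- gid + 1L
    grp[i] <- gid
  }
  out <- lapply(split(seq_len(nrow(seeds)), grp), function(idx) {
    tibble(scaffold_id = seeds$scaffold_id[idx[1]],
           genes = list(seeds[idx, , drop = FALSE]))
  })
  out <- bind_rows(out)
  out$group_id <- sprintf("grp%03d", seq_len(nrow(out)))
  out[, c("group_id", "scaffold_id", "genes")]
}

#' Apply the seed-group membership filter
#'
#' A group is accepted when it has at least `min_seed_genes` members and
#' at least `min_distinct_seed_pfams` distinct eCIS-associated pfam
#' domains among them.
#'
#' @param groups Seed-group tibble from [chain_seed_groups()].
#' @param config An [core_config()] object.
#' @return `groups` with added columns `n_members`, `n_distinct_pfams`,
#'   `accept` and `reason` (`NA` when accepted).
#' @export
seed_filter <- function(groups, config = core_config()) {
  thr <- config$thresholds
  ecis_pfams <- names(config$pfam_to_role)
  groups$n_members <- vapply(groups$genes, nrow, integer(1))
  groups$n_distinct_pfams <- vapply(groups$genes, function(g) {
    length(intersect(unique(unlist(g$pfams)), ecis_pfams))
  }, integer(1))
  groups$accept <- groups$n_members >= thr$min_seed_genes &
    groups$n_distinct_pfams >= thr$min_distinct_seed_pfams
  groups$reason <- dplyr::if_else(
    groups$accept, NA_character_,
    dplyr::if_else(groups$n_members < thr$min_seed_genes,
                   "fewer seed genes than min_seed_genes",
                   "fewer distinct eCIS pfams than min_distinct_seed_pfams"))
  groups
}

#' Screen seed groups for phage / T6SS contamination
#'
#' A group is contaminated when any gene on its scaffold (including group
#' members themselves) carries a blocklisted phage pfam or T6SS COG and
#' lies within `contamination_window_bp` (nearest-boundary, inclusive) of
#' any group member. The whole scaffold is scanned, not just the expansion
#' window, because the window is anchored on the group members.
#'
#' @param groups Seed-group tibble (rows that passed [seed_filter()]).
#' @param genes All genes of the genome (any scaffold; only the group's
#'   scaffold is consulted per group).
#' @param config An [core_config()] object.
#' @return `groups` with added columns `clean`, `offending_gene`,
#'   `contamination_rule` (`"phage_pfam"` or `"t6ss_cog"`).
#' @export
contamination_screen <- function(groups, genes, config = core_config()) {
  window <- config$thresholds$contamination_window_bp
  is_blocked_phage <- vapply(genes$pfams, function(p)
    any(p %in% config$phage_blocklist_pfams), logical(1))
  is_blocked_t6ss <- vapply(genes$cogs, function(p)
    any(p %in% config$t6ss_blocklist_cogs), logical(1))
  groups$clean <- TRUE
  groups$offending_gene <- NA_character_
  groups$contamination_rule <- NA_character_
  for (i in seq_len(nrow(groups))) {
    mem <- groups$genes[[i]]
    on_scaf <- genes$scaffold_id == groups$scaffold_id[i] &
      (is_blocked_phage | is_blocked_t6ss)
    if (!any(on_scaf)) next
    blockers <- genes[on_scaf, , drop = FALSE]
    bl_phage <- is_blocked_phage[on_scaf]
    for (b in seq_len(nrow(blockers))) {
      gaps <- interval_gap(blockers$start[b], blockers$end[b], mem$start, mem$end)
      if (any(gaps <= window)) {
        groups$clean[i] <- FALSE
        groups$offending_gene[i] <- blockers$gene_id[b]
        groups$contamination_rule[i] <- if (bl_phage[b]) "phage_pfam" else "t6ss_cog"
        break
      }
    }
  }
  groups
}

#' Expand a seed group into a candidate locus
#'
#' Adds up to `n` protein-coding genes upstream of the first member and
#' downstream of the last (plus every protein-coding gene lying between
#' members). Non-coding features are skipped and do not consume the
#' expansion budget; expansion truncates silently at scaffold ends.
#'
#' @param groups Clean seed-group tibble.
#' @param genes All genes of the genome.
#' @param n Genes to add on each side (default 10).
#' @return `groups` with added list-column `expanded` (gene tibble per
#'   candidate) and columns `span_start`, `span_end`.
#' @export
expand_group <- function(groups, genes, n = 10) {
  groups$expanded <- vector("list", nrow(groups))
  groups$span_start <- NA_integer_
  groups$span_end <- NA_integer_
  for (i in seq_len(nrow(groups))) {
    pc <- sort_genes(genes[genes$scaffold_id == groups$scaffold_id[i] &
                             genes$is_protein_coding, , drop = FALSE])
    pos <- match(groups$genes[[i]]$gene_id, pc$gene_id)
    lo <- max(1L, min(pos) - n)
    hi <- min(nrow(pc), max(pos) + n)
    exp_genes <- pc[lo:hi, , drop = FALSE]
    groups$expanded[[i]] <- exp_genes
    groups$span_start[i] <- min(exp_genes$start)
    groups$span_end[i] <- max(exp_genes$end)
  }
  groups
}

# Merge candidates on one scaffold whose expanded spans overlap, so one
# physical locus split across seed groups is reported once.
merge_candidates <- function(cands) {
  if (nrow(cands) <= 1) return(cands)
  out <- list()
  for (scaf in unique(cands$scaffold_id)) {
    cc <- cands[cands$scaffold_id == scaf, , drop = FALSE]
    cc <- cc[order(cc$span_start), , drop = FALSE]
    cur <- cc[1, , drop = FALSE]
    for (i in seq_len(nrow(cc))[-1]) {
      if (cc$span_start[i] <= cur$span_end[1]) {
        merged_exp <- distinct(bind_rows(cur$expanded[[1]], cc$expanded[[i]]),
                               .data$gene_id, .keep_all = TRUE)
        merged_seed <- distinct(bind_rows(cur$genes[[1]], cc$genes[[i]]),
                                .data$gene_id, .keep_all = TRUE)
        cur$expanded[[1]] <- sort_genes(merged_exp)
        cur$genes[[1]] <- sort_genes(merged_seed)
        cur$span_end[1] <- max(cur$span_end[1], cc$span_end[i])
        cur$span_start[1] <- min(cur$span_start[1], cc$span_start[i])
      } else {
        out[[length(out) + 1]] <- cur
        cur <- cc[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1]] <- cur
  }
  bind_rows(out)
}

empty_locus_table <- function() {
  tibble(locus_id = character(), genome_id = character(), scaffold_id = character(),
         start = integer(), end = integer(), first_gene = character(),
         last_gene = character(), n_genes = integer(), n_core_genes = integer(),
         roles = list(), has_specific_core = logical(),
         member_gene_ids = list(), core_roles = list())
}

#' Finalize candidate loci: core census, pyocin screen and boundaries
#'
#' A candidate is accepted when its expanded gene list carries at least
#' `min_core_genes` core genes (genes with at least one Afp role; counted
#' with gene multiplicity by default, see [core_config()]) and at least one
#' eCIS-specific core role (afp12/13/14/16), which removes R-type pyocins.
#' The reported locus runs from `boundary_flank_genes` protein-coding genes
#' upstream of the first core gene to the same number downstream of the
#' last, clipped at scaffold ends.
#'
#' @param cands Candidate tibble from [expand_group()] (after merging).
#' @param roles Core-role assignments from [assign_core_roles()].
#' @param genes All genes of the genome (used for boundary flanks).
#' @param config An [core_config()] object.
#' @return A list with `loci` (locus tibble, possibly empty) and
#'   `rejections` (tibble of `group_id`, `reason`).
#' @export
finalize_locus <- function(cands, roles, genes, config = core_config()) {
  thr <- config$thresholds
  role_sets <- split(roles$role, roles$gene_id)
  loci <- list()
  rej <- list()
  for (i in seq_len(nrow(cands))) {
    exp_genes <- cands$expanded[[i]]
    core_mask <- exp_genes$gene_id %in% names(role_sets)
    core_genes <- exp_genes[core_mask, , drop = FALSE]
    core_role_list <- role_sets[core_genes$gene_id]
    n_core <- if (config$count_core_as == "genes") nrow(core_genes)
      else length(unique(unlist(core_role_list)))
    if (n_core < thr$min_core_genes) {
      rej[[length(rej) + 1]] <- tibble(group_id = cands$group_id[i],
                                       reason = "core count below min_core_genes")
      next
    }
    if (!any(unlist(core_role_list) %in% config$specific_cores)) {
      rej[[length(rej) + 1]] <- tibble(group_id = cands$group_id[i],
                                       reason = "no eCIS-specific core")
      next
    }
    pc <- sort_genes(genes[genes$scaffold_id == cands$scaffold_id[i] &
                             genes$is_protein_coding, , drop = FALSE])
    pos <- match(core_genes$gene_id, pc$gene_id)
    lo <- max(1L, min(pos) - thr$boundary_flank_genes)
    hi <- min(nrow(pc), max(pos) + thr$boundary_flank_genes)
    members <- pc[lo:hi, , drop = FALSE]
    loci[[length(loci) + 1]] <- tibble(
      locus_id = NA_character_,
      genome_id = members$genome_id[1],
      scaffold_id = cands$scaffold_id[i],
      start = min(members$start),
      end = max(members$end),
      first_gene = members$gene_id[1],
      last_gene = members$gene_id[nrow(members)],
      n_genes = nrow(members),
      n_core_genes = as.integer(n_core),
      roles = list(sort(unique(unlist(core_role_list)))),
      has_specific_core = TRUE,
      member_gene_ids = list(members$gene_id),
      core_roles = list(core_role_list)
    )
  }
  list(loci = if (length(loci)) bind_rows(loci) else empty_locus_table(),
       rejections = if (length(rej)) bind_rows(rej) else
         tibble(group_id = character(), reason = character()))
}

#' Detect eCIS loci in one genome
#'
#' Runs the full detection chain: seed collection, linkage chaining, seed
#' filter, contamination screen, expansion, merging of overlapping
#' candidates, core-role census and finalization. The returned table has
#' one row per accepted locus, sorted by (scaffold, start), and carries a
#' `provenance` attribute tallying what every filter did.
#'
#' @param genes Gene tibble for one genome.
#' @param hits HMM hit tibble for the genome's proteins.
#' @param config An [core_config()] object.
#' @param filter_hits Apply [percentile_filter()] to `hits` first (default
#'   `TRUE`). Pass `FALSE` when hits were already filtered batch-wide,
#'   which is the recommended setup for multi-genome runs.
#' @return A locus tibble of class `ecis_loci` (see [finalize_locus()] for
#'   columns), with attributes `provenance` and `rejections`.
#' @export
detect_loci <- function(genes, hits, config = core_config(), filter_hits = TRUE) {
  thr <- config$thresholds
  if (filter_hits && nrow(hits)) {
    hits <- percentile_filter(hits, thr$hmm_keep_fraction,
                              per_profile = config$percentile_scope == "per_profile")
  }
  prov <- list()
  note <- function(stage, detail, n) {
    prov[[length(prov) + 1]] <<- tibble(stage = stage, detail = detail, n = as.integer(n))
  }
  seeds <- collect_seed_genes(genes, config)
  note("seeds", "eCIS-pfam seed genes", nrow(seeds))
  groups <- chain_seed_groups(seeds, thr$linkage_gap_bp)
  note("chaining", "seed groups", nrow(groups))
  groups <- seed_filter(groups, config)
  note("seed_filter", "rejected: size/diversity", sum(!groups$accept))
  groups <- groups[groups$accept, , drop = FALSE]
  groups <- contamination_screen(groups, genes, config)
  note("contamination", "rejected: phage/T6SS within window", sum(!groups$clean))
  groups <- groups[groups$clean, , drop = FALSE]
  rejections <- tibble(group_id = character(), reason = character())
  if (nrow(groups) == 0) {
    loci <- empty_locus_table()
  } else {
    cands <- expand_group(groups, genes, thr$expansion_genes)
    merged <- merge_candidates(cands)
    note("merge", "candidates after span merging", nrow(merged))
    roles <- suppressWarnings(assign_core_roles(genes, hits, config))
    fin <- finalize_locus(merged, roles, genes, config)
    loci <- fin$loci
    rejections <- fin$rejections
    note("finalize", "rejected: core census / specific core", nrow(fin$rejections))
  }
  loci <- loci[order(loci$scaffold_id, loci$start), , drop = FALSE]
  if (nrow(loci)) {
    loci$locus_id <- sprintf("%s|%s|L%02d", loci$genome_id, loci$scaffold_id,
                             seq_len(nrow(loci)))
  }
  note("final", "accepted loci", nrow(loci))
  attr(loci, "provenance") <- bind_rows(prov)
  attr(loci, "rejections") <- rejections
  class(loci) <- c("ecis_loci", class(loci))
  loci
}
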