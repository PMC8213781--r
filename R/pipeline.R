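# Orchestration over the detection and statistics modules: multi-genome
# runs, stage-level logging with per-filter rejection tallies, and stamped
# TSV outputs. All thresholds live in the configuration, never in code;
# every output file carries the package version, a configuration hash and
# the seed, so two runs with equal stamps are byte-identical.

stamp_header <- function(config, seed = NA) {
  c(paste0("# ecisfinder ", the_version()),
    paste0("# config_md5=", config_hash(config)),
    paste0("# seed=", seed))
}

write_stamped_tsv <- function(df, path, config, seed = NA) {
  # list-columns are flattened to semicolon-joined strings
  df <- as_tibble(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(x) paste(unlist(x), collapse = ";"),
                          character(1))
    }
  }
  readr::write_lines(stamp_header(config, seed), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Detect eCIS loci across a batch of genomes
#'
#' Applies the batch-wide HMM bitscore percentile filter once, then runs
#' [detect_loci()] per genome, collecting loci, per-filter rejection
#' tallies and a run-level summary (genomes scanned, genomes with at
#' least one locus, locus count, multi-copy histogram).
#'
#' @param genes Gene tibble covering one or more genomes, or a character
#'   vector of gene-table paths read via [read_gene_table()].
#' @param hits HMM hit tibble (unfiltered), or a character vector of hit
#'   file paths read via [read_hmm_hits()].
#' @param config An [core_config()] object.
#' @param output_dir Optional directory; when given, writes `loci.tsv` and
#'   `summary.tsv` stamped with version, config hash and seed.
#' @param seed Optional seed recorded in output stamps (detection itself
#'   is deterministic).
#' @return An object of class `ecis_detection`: list with `loci`,
#'   `summary` (one-row tibble), `provenance`, `config`, `seed`.
#' @export
run_detect <- function(genes, hits, config = core_config(), output_dir = NULL,
                       seed = NA) {
  if (is.character(genes)) genes <- bind_rows(lapply(genes, read_gene_table))
  if (is.character(hits)) hits <- bind_rows(lapply(hits, read_hmm_hits))
  if (nrow(genes) == 0) abort("No input genes.")
  thr <- config$thresholds
  hits <- percentile_filter(hits, thr$hmm_keep_fraction,
                            per_profile = config$percentile_scope == "per_profile")
  genomes <- unique(genes$genome_id)
  loci_list <- list()
  prov_list <- list()
  for (g in genomes) {
    li <- detect_loci(genes[genes$genome_id == g, , drop = FALSE],
                      hits[hits$gene_id %in% genes$gene_id[genes$genome_id == g], ,
                           drop = FALSE],
                      config, filter_hits = FALSE)
    pv <- attr(li, "provenance")
    pv$genome_id <- g
    prov_list[[g]] <- pv
    loci_list[[g]] <- li
  }
  loci <- bind_rows(lapply(loci_list, as_tibble))
  per_genome <- table(factor(loci$genome_id, levels = genomes))
  copy_hist <- table(per_genome[per_genome > 0])
  summary_tbl <- tibble(
    genomes_scanned = length(genomes),
    genomes_with_loci = sum(per_genome > 0),
    pct_genomes_with_loci = 100 * sum(per_genome > 0) / length(genomes),
    n_loci = nrow(loci),
    multi_copy_genomes = sum(per_genome > 1)
  )
  res <- structure(list(loci = loci, summary = summary_tbl,
                        copy_histogram = copy_hist,
                        provenance = bind_rows(prov_list),
                        config = config, seed = seed),
                   class = "ecis_detection")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_stamped_tsv(loci, file.path(output_dir, "loci.tsv"), config, seed)
    write_stamped_tsv(summary_tbl, file.path(output_dir, "summary.tsv"), config, seed)
  }
  res
}

#' @export
print.ecis_detection <- function(x, ...) {
  s <- x$summary
  cat("<ecis_detection> ", s$n_loci, " loci in ", s$genomes_with_loci, "/",
      s$genomes_scanned, " genomes (", sprintf("%.1f", s$pct_genomes_with_loci),
      "%)\n", sep = "")
  invisible(x)
}

#' @rdname run_detect
#' @param x An `ecis_detection` object.
#' @param ... Unused.
#' @export
tidy.ecis_detection <- function(x, ...) as_tibble(x$loci)

#' @rdname run_detect
#' @export
glance.ecis_detection <- function(x, ...) x$summary

#' Enrichment analyses over a detection run
#'
#' Produces the three comparative tables: genus enrichment
#' ([genus_enrichment()]), pfam enrichment with core/shell/cloud classes
#' ([pfam_enrichment()]) and, when a tree and trait table are supplied,
#' trait association with the contrasting-pairs test
#' ([trait_association()]).
#'
#' @param detection An `ecis_detection` object (or a locus tibble).
#' @param genes Gene universe used for pfam enrichment backgrounds.
#' @param taxonomy Optional tibble `genome_id`, `genus`, `phylum`.
#' @param traits Optional trait tibble incl. an `ecis` column; if the
#'   column is absent it is derived from the detection result.
#' @param tree Optional rooted [ape::phylo] for the pairwise test.
#' @param config Configuration used for output stamps.
#' @param output_dir Optional output directory (`genus_enrichment.tsv`,
#'   `pfam_enrichment.tsv`, `trait_association.tsv`).
#' @param seed Optional stamp seed.
#' @return A list of class `ecis_enrichment` with elements `genus`,
#'   `pfam`, `traits` (tibbles or `NULL`).
#' @export
run_enrich <- function(detection, genes, taxonomy = NULL, traits = NULL,
                       tree = NULL, config = core_config(), output_dir = NULL,
                       seed = NA) {
  loci <- if (inherits(detection, "ecis_detection")) detection$loci else detection
  genomes <- unique(genes$genome_id)
  presence <- tibble(genome_id = genomes,
                     ecis = as.integer(genomes %in% loci$genome_id))
  genus_tbl <- NULL
  if (!is.null(taxonomy) && "genus" %in% names(taxonomy)) {
    genus_tbl <- genus_enrichment(presence, taxonomy[, c("genome_id", "genus")])
  }
  phyla <- if (!is.null(taxonomy) && "phylum" %in% names(taxonomy)) {
    taxonomy[, c("genome_id", "phylum")]
  }
  pfam_tbl <- pfam_enrichment(loci, genes, phyla)
  trait_tbl <- NULL
  if (!is.null(traits) && !is.null(tree)) {
    if (!"ecis" %in% names(traits)) {
      traits <- left_join(traits, presence, by = "genome_id")
    }
    trait_tbl <- trait_association(traits, tree, presence = "ecis")
  }
  res <- structure(list(genus = genus_tbl, pfam = pfam_tbl, traits = trait_tbl),
                   class = "ecis_enrichment")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(genus_tbl)) {
      write_stamped_tsv(genus_tbl, file.path(output_dir, "genus_enrichment.tsv"),
                        config, seed)
    }
    if (!is.null(pfam_tbl)) {
      write_stamped_tsv(pfam_tbl, file.path(output_dir, "pfam_enrichment.tsv"),
                        config, seed)
    }
    if (!is.null(trait_tbl)) {
      write_stamped_tsv(trait_tbl, file.path(output_dir, "trait_association.tsv"),
                        config, seed)
    }
  }
  res
}

#' Classify tail fibers for a run
#'
#' Selects the high-confidence afp13 gene set from HMM hits and classifies
#' each against the phage and eukaryotic-virus BLAST results. When one
#' BLAST file is missing the run proceeds with a warning and all calls are
#' limited to the present database.
#'
#' @param afp13_hits HMM hit tibble (afp13 rows are used).
#' @param phage_hits,virus_hits BLAST hit tibbles (either may be `NULL`).
#' @param config An [core_config()] object (fiber thresholds).
#' @param output_dir Optional directory for `fiber_calls.tsv`.
#' @param seed Optional stamp seed.
#' @return An `ecis_fibers` tibble (see [classify_fibers()]) restricted to
#'   the selected fiber set, with a `counts` attribute.
#' @export
run_fibers <- function(afp13_hits, phage_hits = NULL, virus_hits = NULL,
                       config = core_config(), output_dir = NULL, seed = NA) {
  thr <- config$thresholds
  if (is.null(phage_hits) || is.null(virus_hits)) {
    warn("Only one BLAST database supplied: calls are limited to that database.")
  }
  fiber_set <- select_fiber_set(afp13_hits, thr$fiber_select_fraction)
  calls <- classify_fibers(phage_hits, virus_hits, gene_ids = fiber_set,
                           evalue_cut = thr$fiber_evalue_cut,
                           delta = thr$fiber_bitscore_delta)
  attr(calls, "counts") <- table(factor(calls$call, levels = c(
    "phage", "euk_virus", "inconclusive", "no_hit")))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_stamped_tsv(calls, file.path(output_dir, "fiber_calls.tsv"), config, seed)
  }
  calls
}

#' @rdname run_fibers
#' @param x An `ecis_fibers` object.
#' @param ... Unused.
#' @export
glance.ecis_fibers <- function(x, ...) {
  counts <- attr(x, "counts") %||% table(factor(x$call, levels = c(
    "phage", "euk_virus", "inconclusive", "no_hit")))
  as_tibble(as.list(counts))
}
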