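# Synthetic-data generators: genomes with planted eCIS operons and decoy
# loci, trees with trait tables, and dual-database fiber hit tables, all
# with known labels. The generators emit annotation-level data only (no
# nucleotide/protein realism is needed by the pipeline's logic) and are
# deterministic given their seed.
#
# Planted operons are built to satisfy every detection threshold by
# construction; each decoy kind violates exactly one named rule:
#   ecis_no_specific_core -> the R-type-pyocin screen (no afp12/13/14/16)
#   ecis_undersized       -> the >= 10 core gene census
#   phage_decoy           -> a capsid-pfam gene within the 10 kb window
#   t6ss_decoy            -> a T6SS-COG gene within the 10 kb window
# Background genes draw from a pfam vocabulary disjoint from the eCIS and
# blocklist vocabularies, so truth labels are exact. Planted HMM bitscores
# (60-100 bits) are strictly above decoy/noise scores (10-25 bits) so
# planted cores always survive the top-half percentile filter.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

plant_kinds <- c("ecis_valid", "ecis_no_specific_core", "ecis_undersized",
                 "phage_decoy", "t6ss_decoy", "empty")

#' Specify a feature to plant on a synthetic scaffold
#'
#' @param kind One of `"ecis_valid"` (a detectable operon),
#'   `"ecis_no_specific_core"` (pyocin-like: enough cores but none of
#'   afp12/13/14/16), `"ecis_undersized"` (passes the seed filter, fails
#'   the 10-core census), `"phage_decoy"` / `"t6ss_decoy"` (valid operon
#'   plus a blocklisted gene nearby), `"empty"` (background only).
#' @param n_core_genes Number of core genes; defaults: 12 for operon
#'   kinds, 6 for `ecis_undersized`.
#' @param contaminant_offset_bp Gap between the operon's last gene and the
#'   blocklisted contaminant; default 8000 for the decoy kinds (inside the
#'   10 kb window). May also be set on `ecis_valid` to place a contaminant
#'   outside the window (e.g. 11000, which must leave detection intact),
#'   or 0 to put the blocklisted annotation on an operon member itself.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(kind = plant_kinds, n_core_genes = NULL,
                       contaminant_offset_bp = NULL) {
  kind <- match.arg(kind)
  n_core_genes <- n_core_genes %||%
    switch(kind, ecis_undersized = 6L, empty = 0L, 12L)
  if (kind %in% c("phage_decoy", "t6ss_decoy") && is.null(contaminant_offset_bp)) {
    contaminant_offset_bp <- 8000L
  }
  structure(list(kind = kind, n_core_genes = as.integer(n_core_genes),
                 contaminant_offset_bp = contaminant_offset_bp),
            class = "plant_spec")
}

check_plant <- function(spec, config) {
  thr <- config$thresholds
  if (spec$kind %in% c("ecis_valid", "phage_decoy", "t6ss_decoy",
                       "ecis_no_specific_core") &&
      spec$n_core_genes < thr$min_core_genes) {
    abort(paste0("Contradictory plant: kind '", spec$kind, "' needs at least ",
                 thr$min_core_genes, " core genes, got ", spec$n_core_genes))
  }
  if (spec$kind == "ecis_undersized" &&
      (spec$n_core_genes >= thr$min_core_genes ||
       spec$n_core_genes < thr$min_seed_genes)) {
    abort(paste0("Contradictory plant: 'ecis_undersized' needs between ",
                 thr$min_seed_genes, " and ", thr$min_core_genes - 1,
                 " core genes, got ", spec$n_core_genes))
  }
  invisible(spec)
}

# role plan for the cores of one planted operon: the first four genes carry
# distinct eCIS pfams (the seed requirement), the rest carry HMM roles.
plant_roles <- function(kind, n_core) {
  seed_pfams <- c("PF06841", "PF04984", "PF04965", "PF04865")
  hmm_pool <- if (kind == "ecis_no_specific_core") {
    c("afp3", "afp4", "afp5", "afp6", "afp7", "afp8", "afp15")
  } else {
    c("afp13", "afp3", "afp4", "afp5", "afp6", "afp7", "afp8")
  }
  n_hmm <- max(0L, n_core - 4L)
  list(seed_pfams = seed_pfams[seq_len(min(4L, n_core))],
       hmm_roles = rep_len(hmm_pool, n_hmm))
}

#' Generate one synthetic genome with planted features
#'
#' Builds one scaffold per plant: background genes (random non-eCIS
#' pfams), the planted operon or decoy, a couple of non-coding RNA genes
#' flanking the plant (to exercise expansion skipping), a blocklisted
#' contaminant where the plant calls for one, and per-profile HMM hits
#' (high bitscores for planted cores, one low-scoring noise hit per
#' profile on a far background gene). Output is byte-stable for a given
#' seed.
#'
#' @param plants List of [plant_spec()] objects (one scaffold each).
#' @param n_background_genes Total background genes, split evenly across
#'   scaffolds (half upstream, half downstream of the plant).
#' @param seed Integer seed.
#' @param genome_id Genome identifier.
#' @param config An [core_config()] object.
#' @return A list with `genes` (gene tibble), `hmm_hits` (hit tibble) and
#'   `manifest` (tibble: `genome_id`, `scaffold_id`, `kind`,
#'   `planted_gene_ids` list-column of core gene ids, `expect_detection`).
#' @examples
#' sim <- sim_genome(list(plant_spec("ecis_valid")), seed = 1)
#' nrow(detect_loci(sim$genes, sim$hmm_hits))  # 1
#' @export
sim_genome <- function(plants, n_background_genes = 40 * length(plants),
                       seed = 1, genome_id = "genomeA", config = core_config()) {
  stopifnot(length(plants) >= 1)
  plants <- lapply(plants, function(p) {
    if (!inherits(p, "plant_spec")) abort("`plants` must be plant_spec objects.")
    check_plant(p, config)
  })
  bg_per <- max(2L, floor(n_background_genes / length(plants)))
  with_seed(seed, {
    all_genes <- list()
    all_hits <- list()
    manifest <- list()
    for (si in seq_along(plants)) {
      sp <- plants[[si]]
      scaffold_id <- sprintf("scf%02d", si)
      pre <- paste0(genome_id, "_", scaffold_id, "_g")
      n_up <- ceiling(bg_per / 2)
      n_down <- bg_per - n_up
      cursor <- 1L
      idx <- 0L
      genes <- list()
      hits <- list()
      add_gene <- function(len, pc = TRUE, pfams = character(0), cogs = character(0),
                           gap = NULL) {
        # `gap` is the nearest-boundary distance to the previous gene
        gap <- gap %||% as.integer(runif(1, 5, 500))
        start <- cursor + gap + 1L
        idx <<- idx + 1L
        g <- tibble(gene_id = paste0(pre, idx), genome_id = genome_id,
                    scaffold_id = scaffold_id, start = start,
                    end = start + len - 1L,
                    strand = sample(c("+", "-"), 1), is_protein_coding = pc,
                    pfams = list(pfams), cogs = list(cogs))
        genes[[length(genes) + 1]] <<- g
        cursor <<- g$end
        g$gene_id
      }
      bg_gene <- function() {
        pf <- sprintf("PFX%04d", sample.int(500, sample(0:2, 1)))
        add_gene(as.integer(runif(1, 300, 1500)), pfams = pf)
      }
      up_ids <- vapply(seq_len(n_up), function(i) bg_gene(), character(1))
      core_ids <- character(0)
      profile_uses <- integer(0)  # planted hit count per profile
      if (sp$kind != "empty") {
        rp <- plant_roles(sp$kind, sp$n_core_genes)
        add_gene(120L, pc = FALSE)  # ncRNA flanking the operon
        # contaminant upstream of the operon, its gap to the first core gene
        # (a seed-group member) probing the contamination window
        core1_gap <- NULL
        if (!is.null(sp$contaminant_offset_bp) && sp$contaminant_offset_bp > 0) {
          contaminant <- switch(sp$kind,
            phage_decoy = list(pf = config$phage_blocklist_pfams[1], cg = character(0)),
            t6ss_decoy = list(pf = character(0), cg = config$t6ss_blocklist_cogs[1]),
            list(pf = config$phage_blocklist_pfams[1], cg = character(0)))
          add_gene(900L, pfams = contaminant$pf, cogs = contaminant$cg)
          core1_gap <- as.integer(sp$contaminant_offset_bp)
        }
        for (ci in seq_len(sp$n_core_genes)) {
          pf <- if (ci <= length(rp$seed_pfams)) rp$seed_pfams[ci] else character(0)
          cg <- character(0)
          if (!is.null(sp$contaminant_offset_bp) && sp$contaminant_offset_bp == 0 &&
              ci == 5L) {
            if (sp$kind == "t6ss_decoy") cg <- config$t6ss_blocklist_cogs[1]
            if (sp$kind == "phage_decoy") pf <- c(pf, config$phage_blocklist_pfams[1])
          }
          gid <- add_gene(as.integer(runif(1, 300, 4500)), pfams = pf, cogs = cg,
                          gap = if (ci == 1L) core1_gap else NULL)
          core_ids <- c(core_ids, gid)
          if (ci > 4L) {
            role <- rp$hmm_roles[ci - 4L]
            profile_uses[role] <- if (role %in% names(profile_uses))
              profile_uses[[role]] + 1L else 1L
            hits[[length(hits) + 1]] <- tibble(
              gene_id = gid, profile_id = role,
              bitscore = round(runif(1, 60, 100), 1),
              evalue = 10^-runif(1, 20, 60))
          }
        }
        add_gene(110L, pc = FALSE)  # second flanking ncRNA
      }
      for (i in seq_len(n_down)) bg_gene()
      genes <- bind_rows(genes)
      # low-scoring noise hits on background genes far enough from the plant
      # that they can never enter a locus window. One noise hit per planted
      # hit of each profile, so planted hits always occupy the top half of
      # their profile's bitscore ranking, batch-wide, by construction.
      far_pool <- up_ids[seq_len(max(0L, n_up - 15L))]
      if (length(far_pool)) {
        for (role in names(profile_uses)) {
          for (k in seq_len(profile_uses[[role]])) {
            hits[[length(hits) + 1]] <- tibble(
              gene_id = sample(far_pool, 1), profile_id = role,
              bitscore = round(runif(1, 10, 25), 1),
              evalue = 10^-runif(1, 2, 6))
          }
        }
      }
      all_genes[[si]] <- genes
      all_hits[[si]] <- bind_rows(hits)
      manifest[[si]] <- tibble(
        genome_id = genome_id, scaffold_id = scaffold_id, kind = sp$kind,
        planted_gene_ids = list(core_ids),
        expect_detection = sp$kind == "ecis_valid")
    }
    list(genes = sort_genes(bind_rows(all_genes)),
         hmm_hits = bind_rows(all_hits),
         manifest = bind_rows(manifest))
  })
}

#' Generate a random tree with paired binary traits
#'
#' Three scenarios exercise the contrasting-pairs test: in
#' `"independent_assoc"` genotype equals phenotype and the positive tips
#' alternate across the tree's tip ladder, so the association recurs in
#' many independent clades; in `"clade_confounded"` both traits equal the
#' indicator of a single clade (closest to half the tips), the classic
#' taxonomic confounder that should collapse to one contrasting pair; in
#' `"null"` both traits are independent fair coin flips per tip.
#'
#' @param n_tips Number of tips (>= 4).
#' @param scenario One of `"independent_assoc"`, `"clade_confounded"`,
#'   `"null"`.
#' @param seed Integer seed.
#' @return A list with `tree` (an [ape::phylo]) and `traits` (tibble:
#'   `genome_id`, `ecis` genotype, `trait` phenotype).
#' @export
sim_tree_traits <- function(n_tips, scenario = c("independent_assoc",
                                                 "clade_confounded", "null"),
                            seed = 1) {
  scenario <- match.arg(scenario)
  if (n_tips < 4) abort("`n_tips` must be at least 4.")
  with_seed(seed, {
    tree <- ape::rtree(n_tips)
    tree$tip.label <- sprintf("genome%03d", seq_len(n_tips))
    cw <- ape::reorder.phylo(tree, "cladewise")
    ladder <- cw$edge[cw$edge[, 2] <= n_tips, 2]  # tips in plotted order
    g <- integer(n_tips)
    if (scenario == "independent_assoc") {
      g[ladder] <- rep_len(c(1L, 0L), n_tips)
      p <- g
    } else if (scenario == "clade_confounded") {
      parts <- ape::prop.part(tree)
      sizes <- lengths(parts)
      ok <- sizes < n_tips
      pick <- which(ok)[which.min(abs(sizes[ok] - n_tips / 2))]
      g[parts[[pick]]] <- 1L
      p <- g
    } else {
      g <- sample(0:1, n_tips, replace = TRUE)
      p <- sample(0:1, n_tips, replace = TRUE)
    }
    list(tree = tree,
         traits = tibble(genome_id = tree$tip.label, ecis = g, trait = p))
  })
}

#' Generate dual-database fiber BLAST hits with known calls
#'
#' Bitscore pairs are drawn to realize each intended call under the
#' bitscore-difference rule: decided calls differ by more than `delta`
#' bits (and sometimes have a hit in only one database), inconclusive
#' calls differ by at most `delta`, and `no_hit` genes either have no
#' rows or only rows failing the E-value cutoff.
#'
#' @param n_genes Number of query genes.
#' @param class_mix Named proportions over
#'   `c("phage", "euk_virus", "inconclusive", "no_hit")`; must sum to 1.
#'   Counts are allocated deterministically (largest-remainder).
#' @param seed Integer seed.
#' @param evalue_cut,delta Classification parameters (defaults 1e-3, 15).
#' @return A list with `phage_hits`, `virus_hits` (BLAST hit tibbles) and
#'   `truth` (tibble: `gene_id`, `call`).
#' @export
sim_fiber_hits <- function(n_genes,
                           class_mix = c(phage = 0.25, euk_virus = 0.25,
                                         inconclusive = 0.25, no_hit = 0.25),
                           seed = 1, evalue_cut = 1e-3, delta = 15) {
  classes <- c("phage", "euk_virus", "inconclusive", "no_hit")
  if (!setequal(names(class_mix), classes) || abs(sum(class_mix) - 1) > 1e-8) {
    abort("`class_mix` must be proportions over the four call classes summing to 1.")
  }
  counts <- floor(class_mix[classes] * n_genes)
  rem <- n_genes - sum(counts)
  if (rem > 0) {
    frac <- class_mix[classes] * n_genes - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  with_seed(seed, {
    labels <- sample(rep(classes, counts))
    ph <- list(); vi <- list()
    good_e <- function(n) 10^-runif(n, 5, 40)
    bad_e <- function(n) runif(n, evalue_cut * 2, 0.5)
    row <- function(gene, db, bs, ev) {
      tibble(query_id = gene, subject_id = paste0(db, "_subj"),
             subject_db = db, bitscore = round(bs, 1), evalue = ev)
    }
    for (i in seq_len(n_genes)) {
      gene <- sprintf("fiber%04d", i)
      lab <- labels[i]
      if (lab == "phage") {
        bs <- runif(1, 80, 130)
        ph[[length(ph) + 1]] <- row(gene, "phage", bs, good_e(1))
        if (runif(1) > 0.3) {
          vi[[length(vi) + 1]] <- row(gene, "euk_virus",
                                      bs - delta - runif(1, 1, 30), good_e(1))
        }
      } else if (lab == "euk_virus") {
        bs <- runif(1, 80, 130)
        vi[[length(vi) + 1]] <- row(gene, "euk_virus", bs, good_e(1))
        if (runif(1) > 0.3) {
          ph[[length(ph) + 1]] <- row(gene, "phage",
                                      bs - delta - runif(1, 1, 30), good_e(1))
        }
      } else if (lab == "inconclusive") {
        bs <- runif(1, 80, 130)
        ph[[length(ph) + 1]] <- row(gene, "phage", bs, good_e(1))
        vi[[length(vi) + 1]] <- row(gene, "euk_virus",
                                    bs + runif(1, -delta, delta), good_e(1))
      } else if (runif(1) > 0.5) {  # no_hit: half with failing rows
        ph[[length(ph) + 1]] <- row(gene, "phage", runif(1, 30, 60), bad_e(1))
        vi[[length(vi) + 1]] <- row(gene, "euk_virus", runif(1, 30, 60), bad_e(1))
      }
    }
    empty <- tibble(query_id = character(), subject_id = character(),
                    subject_db = character(), bitscore = double(), evalue = double())
    list(phage_hits = if (length(ph)) bind_rows(ph) else empty,
         virus_hits = if (length(vi)) bind_rows(vi) else empty,
         truth = tibble(gene_id = sprintf("fiber%04d", seq_len(n_genes)),
                        call = labels))
  })
}

#' Write a simulated genome to disk
#'
#' Emits the gene table TSV, the simple HMM hit TSV and the truth manifest
#' as JSON into `dir`.
#'
#' @param sim Result of [sim_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("Writing the manifest requires the jsonlite package.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_hmm_hits(sim$hmm_hits, file.path(dir, "hmm_hits.tsv"))
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
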