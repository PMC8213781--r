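#' Core configuration for eCIS locus detection
#'
#' Bundles everything the detection and downstream statistics need to know
#' about the eCIS gene vocabulary: which pfam domains mark core components
#' (and which Afp role each one maps to), which core roles are
#' eCIS-specific (distinguishing eCIS from R-type pyocins), the phage and
#' T6SS contamination blocklists, and all numeric thresholds. Every default
#' can be overridden, and a configuration can be round-tripped through YAML
#' with [read_core_config()] / [write_core_config()].
#'
#' The default pfam-to-role map covers the classic core domains: tail tube
#' (Phage_T4_gp19, PF06841), sheath (Phage_sheath_1, PF04984), baseplate
#' (GPW_gp25, PF04965; Baseplate_J, PF04865), spike (PAAR_motif, PF05488;
#' Phage_GPD, PF05954), ATPase (AAA, PF00004) and the cap / tail terminator
#' (DUF4255, PF14065, mapped to the eCIS-specific role afp16). It is a
#' starting vocabulary, not a closed list: extend `pfam_to_role` with any
#' in-house profile-to-role curation.
#'
#' @param pfam_to_role Named character vector mapping pfam accessions to
#'   core roles (`afp1`..`afp16`).
#' @param specific_cores Roles that distinguish eCIS from R-type pyocins.
#' @param phage_blocklist_pfams Pfam accessions flagging phage cassettes
#'   (e.g. the major capsid protein E, PF03864).
#' @param t6ss_blocklist_cogs COG accessions flagging type VI secretion
#'   loci (e.g. TssM, COG3523).
#' @param thresholds Named list of numeric parameters; see Details.
#' @param count_core_as `"genes"` (default) counts core genes with
#'   multiplicity (two afp1 paralogs count twice); `"roles"` counts
#'   distinct roles.
#' @param percentile_scope `"per_profile"` (default) applies the HMM
#'   bitscore percentile filter within each profile; `"global"` ranks all
#'   hits together.
#'
#' @details Threshold defaults (all strictly positive):
#' \describe{
#'   \item{linkage_gap_bp (12000)}{maximum nearest-boundary gap, in bp,
#'     between seed genes of one group (inclusive).}
#'   \item{contamination_window_bp (10000)}{window, in bp, around group
#'     members scanned for blocklisted genes (inclusive).}
#'   \item{expansion_genes (10)}{protein-coding genes added up/downstream
#'     of the seed extrema before the core census.}
#'   \item{min_seed_genes (4)}{minimum seed-group size.}
#'   \item{min_distinct_seed_pfams (3)}{minimum distinct eCIS pfams among
#'     seed genes.}
#'   \item{min_core_genes (10)}{minimum core-gene census of a final locus.}
#'   \item{boundary_flank_genes (4)}{protein-coding genes added up/downstream
#'     of the extreme core genes to delimit the reported locus.}
#'   \item{hmm_keep_fraction (0.5)}{fraction of HMM hits kept by bitscore
#'     rank.}
#'   \item{fiber_select_fraction (0.25)}{fraction of afp13 genes kept for
#'     tail-fiber analysis.}
#'   \item{fiber_evalue_cut (1e-3)}{BLAST E-value cutoff for fiber hits.}
#'   \item{fiber_bitscore_delta (15)}{bitscore margin required to call a
#'     database preference; a difference of exactly this value is
#'     inconclusive.}
#'   \item{plasmid_score_cut (0.7)}{cutoff applied to externally computed
#'     plasmid scores when such a column is joined.}
#' }
#'
#' @return A list of class `ecis_config`.
#' @examples
#' cfg <- core_config()
#' cfg$thresholds$min_core_genes
#' @export
core_config <- function(pfam_to_role = NULL,
                        specific_cores = c("afp12", "afp13", "afp14", "afp16"),
                        phage_blocklist_pfams = c("PF03864", "PF05065", "PF04233"),
                        t6ss_blocklist_cogs = c("COG3523", "COG3516", "COG3517", "COG3519"),
                        thresholds = list(),
                        count_core_as = c("genes", "roles"),
                        percentile_scope = c("per_profile", "global")) {
  default_map <- c(
    PF06841 = "afp1",  # Phage_T4_gp19, tail tube
    PF04984 = "afp2",  # Phage_sheath_1
    PF05954 = "afp8",  # Phage_GPD, spike complex
    PF04965 = "afp9",  # GPW_gp25, baseplate
    PF05488 = "afp10", # PAAR_motif, spike tip
    PF04865 = "afp11", # Baseplate_J
    PF00004 = "afp15", # AAA ATPase
    PF14065 = "afp16"  # DUF4255, cap / tail terminator (eCIS-specific)
  )
  pfam_to_role <- pfam_to_role %||% default_map
  if (is.null(names(pfam_to_role)) || any(!nzchar(names(pfam_to_role)))) {
    abort("`pfam_to_role` must be a named character vector (pfam -> role).")
  }
  default_thresholds <- list(
    linkage_gap_bp = 12000,
    contamination_window_bp = 10000,
    expansion_genes = 10,
    min_seed_genes = 4,
    min_distinct_seed_pfams = 3,
    min_core_genes = 10,
    boundary_flank_genes = 4,
    hmm_keep_fraction = 0.5,
    fiber_select_fraction = 0.25,
    fiber_evalue_cut = 1e-3,
    fiber_bitscore_delta = 15,
    plasmid_score_cut = 0.7
  )
  unknown <- setdiff(names(thresholds), names(default_thresholds))
  if (length(unknown)) {
    abort(paste0("Unknown threshold(s): ", paste(unknown, collapse = ", ")))
  }
  thresholds <- utils::modifyList(default_thresholds, thresholds)
  bad <- names(thresholds)[!vapply(thresholds, function(x) {
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  }, logical(1))]
  if (length(bad)) {
    abort(paste0("Thresholds must be single strictly positive numbers; bad: ",
                 paste(bad, collapse = ", ")))
  }
  roles <- paste0("afp", 1:16)
  if (!all(specific_cores %in% roles)) {
    abort("`specific_cores` must be a subset of afp1..afp16.")
  }
  if (!all(pfam_to_role %in% roles)) {
    abort("`pfam_to_role` values must be roles afp1..afp16.")
  }
  cfg <- list(
    pfam_to_role = pfam_to_role,
    roles = roles,
    specific_cores = specific_cores,
    phage_blocklist_pfams = phage_blocklist_pfams,
    t6ss_blocklist_cogs = t6ss_blocklist_cogs,
    thresholds = thresholds,
    count_core_as = match.arg(count_core_as),
    percentile_scope = match.arg(percentile_scope)
  )
  structure(cfg, class = "ecis_config")
}

#' @export
print.ecis_config <- function(x, ...) {
  cat("<ecis_config>\n")
  cat("  core pfams:", length(x$pfam_to_role),
      " roles:", length(unique(x$pfam_to_role)), "\n")
  cat("  specific cores:", paste(x$specific_cores, collapse = ", "), "\n")
  cat("  phage blocklist:", length(x$phage_blocklist_pfams),
      "pfams; T6SS blocklist:", length(x$t6ss_blocklist_cogs), "COGs\n")
  thr <- unlist(x$thresholds)
  cat("  thresholds:\n")
  for (nm in names(thr)) cat(sprintf("    %-24s %g\n", nm, thr[[nm]]))
  cat("  core census:", x$count_core_as,
      "| percentile scope:", x$percentile_scope, "\n")
  invisible(x)
}

#' Read / write a core configuration as YAML
#'
#' @param path File path.
#' @return `read_core_config()` returns an `ecis_config`;
#'   `write_core_config()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yml")
#' write_core_config(core_config(), p)
#' cfg <- read_core_config(p)
#' @export
read_core_config <- function(path) {
  raw <- yaml::read_yaml(path)
  core_config(
    pfam_to_role = unlist(raw$pfam_to_role),
    specific_cores = raw$specific_cores %||% c("afp12", "afp13", "afp14", "afp16"),
    phage_blocklist_pfams = raw$phage_blocklist_pfams %||% character(),
    t6ss_blocklist_cogs = raw$t6ss_blocklist_cogs %||% character(),
    thresholds = raw$thresholds %||% list(),
    count_core_as = raw$count_core_as %||% "genes",
    percentile_scope = raw$percentile_scope %||% "per_profile"
  )
}

#' @rdname read_core_config
#' @param config An `ecis_config`.
#' @export
write_core_config <- function(config, path) {
  stopifnot(inherits(config, "ecis_config"))
  out <- list(
    pfam_to_role = as.list(config$pfam_to_role),
    specific_cores = config$specific_cores,
    phage_blocklist_pfams = config$phage_blocklist_pfams,
    t6ss_blocklist_cogs = config$t6ss_blocklist_cogs,
    thresholds = config$thresholds,
    count_core_as = config$count_core_as,
    percentile_scope = config$percentile_scope
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

# Stable short hash of a configuration, used to stamp output files so two
# runs are comparable at a glance. md5 of the canonical YAML serialization.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_core_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Normalize an HMM profile name to a core role
#'
#' Recognizes the Afp1-16 naming in common spellings ("Afp8", "AFP_8",
#' "afp08") and returns the canonical lowercase `afpN`; anything else is
#' returned unchanged (lowercased spellings that are not Afp profiles are
#' left as-is so raw profile names survive).
#'
#' @param x Character vector of profile names.
#' @return Character vector of the same length.
#' @examples
#' normalize_profile(c("Afp8", "AFP_13", "PF99999"))
#' @export
normalize_profile <- function(x) {
  m <- regmatches(x, regexec("^[Aa][Ff][Pp][_-]?0*([0-9]{1,2})$", x))
  vapply(seq_along(x), function(i) {
    if (length(m[[i]]) == 2) {
      num <- as.integer(m[[i]][2])
      if (num >= 1 && num <= 16) return(paste0("afp", num))
    }
    x[[i]]
  }, character(1))
}
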