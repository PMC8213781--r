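# Readers and writers for the external formats the pipeline touches.
# Conventions fixed here once for all modules: coordinates are 1-based
# inclusive; strand is "+" or "-"; pfam/COG annotation sets are list-columns
# of deduplicated accessions; inter-gene distance is the nearest-boundary
# gap, max(0, downstream start - upstream end - 1), strand-ignored.

split_accessions <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    unique(parts[nzchar(parts)])
  })
}

normalize_strand <- function(x) {
  x <- as.character(x)
  x[x %in% c("-", "−", "-1")] <- "-"
  x[x %in% c("+", "1")] <- "+"
  bad <- !x %in% c("+", "-")
  if (any(bad)) {
    abort(paste0("Invalid strand value(s): ", paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "yes", "1")
}

#' Read an IMG-style gene annotation table
#'
#' One row per gene, tab-separated, with header columns `gene_id`,
#' `scaffold`, `start`, `end`, `strand`, `pfams`, `cogs` (pfams/cogs
#' semicolon-joined, possibly empty). Optional columns: `genome_id` and
#' `is_protein_coding` (defaults `TRUE`). Rows are returned sorted by
#' (scaffold, start).
#'
#' @param path Path to the TSV file.
#' @param genome_id Genome identifier used when the file has no
#'   `genome_id` column; defaults to the file name without extension.
#' @return A tibble of genes with list-columns `pfams` and `cogs`.
#' @seealso [write_gene_table()] for the exact inverse.
#' @export
read_gene_table <- function(path, genome_id = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("gene_id", "scaffold", "start", "end", "strand", "pfams", "cogs")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Gene table ", path, " is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  bad_num <- which(is.na(start) | is.na(end))
  if (length(bad_num)) {
    abort(paste0("Non-numeric start/end at data line(s) ",
                 paste(bad_num, collapse = ", "), " of ", path))
  }
  bad <- which(end < start)
  if (length(bad)) {
    abort(paste0("end < start at data line(s) ", paste(bad, collapse = ", "),
                 " of ", path, " (gene ", paste(raw$gene_id[bad], collapse = ", "), ")"))
  }
  dup <- unique(raw$gene_id[duplicated(raw$gene_id)])
  if (length(dup)) {
    abort(paste0("Duplicated gene_id(s) in ", path, ": ", paste(dup, collapse = ", ")))
  }
  gid <- if ("genome_id" %in% names(raw)) raw$genome_id else
    rep(genome_id %||% sub("\\.[^.]*$", "", basename(path)), nrow(raw))
  genes <- tibble(
    gene_id = raw$gene_id,
    genome_id = gid,
    scaffold_id = raw$scaffold,
    start = start,
    end = end,
    strand = normalize_strand(raw$strand),
    is_protein_coding = if ("is_protein_coding" %in% names(raw))
      as_flag(raw$is_protein_coding) else rep(TRUE, nrow(raw)),
    pfams = split_accessions(raw$pfams),
    cogs = split_accessions(raw$cogs)
  )
  arrange(genes, .data$scaffold_id, .data$start)
}

#' Write a gene table in the TSV dialect read by [read_gene_table()]
#'
#' Round-trips exactly: `read_gene_table(write_gene_table(genes, path))`
#' reproduces all fields.
#'
#' @param genes A gene tibble as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- tibble(
    gene_id = genes$gene_id,
    genome_id = genes$genome_id,
    scaffold = genes$scaffold_id,
    start = genes$start,
    end = genes$end,
    strand = genes$strand,
    is_protein_coding = genes$is_protein_coding,
    pfams = vapply(genes$pfams, paste, character(1), collapse = ";"),
    cogs = vapply(genes$cogs, paste, character(1), collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 (+ optional protein FASTA)
#'
#' CDS features are collapsed by their `ID` attribute: a gene split over
#' several CDS lines becomes one record spanning min(start)..max(end).
#' Coordinates are taken as-is (GFF3 is 1-based inclusive). When `faa` is
#' given, protein sequences whose FASTA identifier matches a CDS `ID` are
#' attached in a `protein` column; sequences with no matching feature are
#' dropped with a warning. A GFF with no CDS features yields an empty
#' tibble, not an error.
#'
#' @param gff Path to a GFF3 file.
#' @param faa Optional path to a protein FASTA whose identifiers (first
#'   whitespace-separated token of each header) match CDS `ID` attributes.
#' @param genome_id Genome identifier; defaults to the GFF file name.
#' @return A gene tibble (see [read_gene_table()]); pfam/COG sets are empty
#'   because GFF3 carries none.
#' @export
read_gff_fasta <- function(gff, faa = NULL, genome_id = NULL) {
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(gff))
  g <- ape::read.gff(gff)
  g <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(g) == 0) {
    out <- tibble(gene_id = character(), genome_id = character(),
                  scaffold_id = character(), start = integer(), end = integer(),
                  strand = character(), is_protein_coding = logical(),
                  pfams = list(), cogs = list())
    return(out)
  }
  ids <- stringr::str_match(g$attributes, "(?:^|;)\\s*ID=([^;]+)")[, 2]
  if (anyNA(ids)) {
    abort(paste0("CDS feature(s) without an ID attribute in ", gff))
  }
  genes <- tibble(
    gene_id = ids,
    scaffold_id = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = normalize_strand(as.character(g$strand))
  ) %>%
    group_by(.data$gene_id, .data$scaffold_id) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              strand = .data$strand[1], .groups = "drop") %>%
    mutate(genome_id = genome_id, is_protein_coding = TRUE,
           pfams = list(character(0)), cogs = list(character(0))) %>%
    select("gene_id", "genome_id", "scaffold_id", "start", "end", "strand",
           "is_protein_coding", "pfams", "cogs") %>%
    arrange(.data$scaffold_id, .data$start)
  if (!is.null(faa)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Reading protein FASTA requires the Biostrings package.")
    }
    aa <- Biostrings::readAAStringSet(faa)
    seq_ids <- sub("\\s.*$", "", names(aa))
    orphan <- !seq_ids %in% genes$gene_id
    if (any(orphan)) {
      warn(paste0(sum(orphan), " FASTA sequence(s) with no matching CDS ID dropped: ",
                  paste(utils::head(seq_ids[orphan], 5), collapse = ", ")))
    }
    prot <- setNames(as.character(aa)[!orphan], seq_ids[!orphan])
    genes$protein <- unname(prot[genes$gene_id])
  }
  genes
}

#' Read HMM search hits
#'
#' Supports hmmsearch `--domtblout` output (one line per domain hit;
#' the full-sequence bitscore and E-value are taken from each line, and
#' duplicate (gene, profile) lines are retained as separate hits) and a
#' simplified 4-column TSV with header `gene_id`, `profile_id`,
#' `bitscore`, `evalue`. Profile names recognizable as Afp profiles are
#' normalized to lowercase `afpN` (see [normalize_profile()]).
#'
#' @param path Path to the hits file.
#' @param dialect `"auto"` (default; domtblout if the first non-comment
#'   line has more than 4 fields), `"domtblout"` or `"simple_tsv"`.
#' @return A tibble with columns `gene_id`, `profile_id`, `bitscore`,
#'   `evalue`.
#' @export
read_hmm_hits <- function(path, dialect = c("auto", "domtblout", "simple_tsv")) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (dialect == "auto") {
    first <- lines[keep][1]
    dialect <- if (is.na(first)) "simple_tsv"
      else if (length(strsplit(trimws(first), "[ \t]+")[[1]]) > 4) "domtblout"
      else "simple_tsv"
  }
  if (dialect == "domtblout") {
    body <- lines[keep]
    if (!length(body)) {
      return(tibble(gene_id = character(), profile_id = character(),
                    bitscore = double(), evalue = double()))
    }
    fields <- strsplit(trimws(body), "[ \t]+")
    short <- which(vapply(fields, length, integer(1)) < 8)
    if (length(short)) {
      abort(paste0("domtblout line(s) with fewer than 8 fields at non-comment line(s) ",
                   paste(short, collapse = ", "), " of ", path))
    }
    gene <- vapply(fields, `[[`, character(1), 1)
    prof <- vapply(fields, `[[`, character(1), 4)
    ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 7)))
    bs <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 8)))
    bad <- which(is.na(ev) | is.na(bs))
    if (length(bad)) {
      abort(paste0("Unparseable bitscore/E-value at non-comment line(s) ",
                   paste(bad, collapse = ", "), " of ", path))
    }
    hits <- tibble(gene_id = gene, profile_id = normalize_profile(prof),
                   bitscore = bs, evalue = ev)
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           comment = "#", progress = FALSE)
    required <- c("gene_id", "profile_id", "bitscore", "evalue")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols)) {
      abort(paste0("HMM hit table ", path, " is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    bs <- suppressWarnings(as.numeric(raw$bitscore))
    ev <- suppressWarnings(as.numeric(raw$evalue))
    bad <- which(is.na(bs) | is.na(ev))
    if (length(bad)) {
      abort(paste0("Unparseable bitscore/E-value at data line(s) ",
                   paste(bad, collapse = ", "), " of ", path))
    }
    hits <- tibble(gene_id = raw$gene_id, profile_id = normalize_profile(raw$profile_id),
                   bitscore = bs, evalue = ev)
  }
  if (any(!is.finite(hits$bitscore))) abort("Non-finite bitscore in HMM hits.")
  if (any(hits$evalue < 0)) abort("Negative E-value in HMM hits.")
  hits
}

#' Write HMM hits in the simple 4-column TSV dialect
#'
#' @param hits A hit tibble (`gene_id`, `profile_id`, `bitscore`, `evalue`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm_hits <- function(hits, path) {
  readr::write_tsv(hits[, c("gene_id", "profile_id", "bitscore", "evalue")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Standard 12-column output: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore. Hits are tagged with the
#' originating database label so phage and eukaryotic-virus searches can be
#' combined downstream.
#'
#' @param path Path to the tabular BLAST output. An empty file yields an
#'   empty tibble.
#' @param db_label `"phage"` or `"euk_virus"`.
#' @return A tibble with columns `query_id`, `subject_id`, `subject_db`,
#'   `bitscore`, `evalue`.
#' @export
read_blast_tab <- function(path, db_label = c("phage", "euk_virus")) {
  db_label <- match.arg(db_label)
  empty <- tibble(query_id = character(), subject_id = character(),
                  subject_db = character(), bitscore = double(), evalue = double())
  if (!file.size(path)) return(empty)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 12) {
    abort(paste0("BLAST tabular file ", path, " has ", ncol(raw),
                 " columns; outfmt 6 requires 12."))
  }
  ev <- suppressWarnings(as.numeric(raw[[11]]))
  bs <- suppressWarnings(as.numeric(raw[[12]]))
  if (anyNA(ev) || anyNA(bs)) {
    abort(paste0("Unparseable evalue/bitscore in ", path))
  }
  tibble(query_id = raw[[1]], subject_id = raw[[2]], subject_db = db_label,
         bitscore = bs, evalue = ev)
}

#' Read a newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces unique tip labels
#' and a single tree per file. Polytomies are preserved; the node ape
#' designates as root is treated as the root by the contrasting-pairs
#' machinery.
#'
#' @param path Path to a newick file (or a literal newick string via
#'   `text`).
#' @param text Optional newick string, used instead of `path`.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) abort("Failed to parse newick input.")
  if (inherits(tr, "multiPhylo")) abort("Expected a single newick tree.")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    abort(paste0("Duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  tr
}

#' Read a binary trait table
#'
#' TSV with a `genome_id` column and one column per binary trait; values
#' must be 0, 1 or missing.
#'
#' @param path Path to the TSV.
#' @return A tibble with `genome_id` and integer 0/1 trait columns.
#' @export
read_trait_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"genome_id" %in% names(raw)) {
    abort(paste0("Trait table ", path, " is missing mandatory column: genome_id"))
  }
  dup <- unique(raw$genome_id[duplicated(raw$genome_id)])
  if (length(dup)) {
    abort(paste0("Duplicated genome_id(s) in trait table: ", paste(dup, collapse = ", ")))
  }
  for (col in setdiff(names(raw), "genome_id")) {
    v <- raw[[col]]
    ok <- is.na(v) | v %in% c("0", "1")
    if (!all(ok)) {
      abort(paste0("Trait column '", col, "' has non-binary value(s): ",
                   paste(unique(v[!ok]), collapse = ", ")))
    }
    raw[[col]] <- as.integer(v)
  }
  raw
}
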