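# Compact constructors for hand-built fixtures.

make_genes <- function(start, end, pfams = NULL, cogs = NULL, strand = NULL,
                       pc = NULL, scaffold = "s1", genome = "gA",
                       ids = NULL) {
  n <- length(start)
  tibble::tibble(
    gene_id = ids %||% paste0("g", seq_len(n)),
    genome_id = genome,
    scaffold_id = rep_len(scaffold, n),
    start = as.integer(start),
    end = as.integer(end),
    strand = strand %||% rep("+", n),
    is_protein_coding = pc %||% rep(TRUE, n),
    pfams = pfams %||% rep(list(character(0)), n),
    cogs = cogs %||% rep(list(character(0)), n)
  )
}

make_hits <- function(gene_id, profile_id, bitscore, evalue = 1e-20) {
  tibble::tibble(gene_id = gene_id, profile_id = profile_id,
                 bitscore = bitscore, evalue = evalue)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A run of evenly spaced genes with a planted operon: k genes carrying the
# given pfam/role annotations starting at gene index `at`, gene length
# `len`, nearest-boundary gaps `gap`.
spaced_genes <- function(n, len = 900, gap = 200, scaffold = "s1", genome = "gA") {
  starts <- (seq_len(n) - 1L) * (len + gap) + 1L
  make_genes(starts, starts + len - 1L, scaffold = scaffold, genome = genome)
}

sort_genes_for_test <- function(g) g[order(g$scaffold_id, g$start), ]
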