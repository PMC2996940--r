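# Programmatic fixtures: random gene models with known intron offsets,
# and minimal EMBL/GenBank flat-file records.

# A sample's own equal-count boundaries, via the degenerate combined
# call (combining a sample with itself returns its own boundaries).
own_boundaries_for_test <- function(v, k) {
  combined_bin_boundaries(v, v, k)$combined
}

empty_marks_tbl <- function() {
  tibble::tibble(residue_index = integer(), phase = integer())
}

random_protein_seq <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}

# A random gene model with n_exons exons encoding a p_len-residue protein
# (coding length includes the stop codon). Returns the model row plus the
# true coding offsets of its introns.
make_random_gene_model <- function(p_len = sample(10:80, 1),
                                   n_exons = sample(1:20, 1),
                                   strand = c("forward", "reverse"),
                                   id = "g1") {
  strand <- match.arg(strand)
  total <- 3L * (p_len + 1L)
  n_exons <- min(n_exons, total)
  cuts <- if (n_exons > 1L) sort(sample(seq_len(total - 1L),
                                        n_exons - 1L)) else integer()
  lens <- diff(c(0L, cuts, total))
  gaps <- sample(20:200, n_exons, replace = TRUE)  # intron + leading gap
  starts_fwd <- integer(n_exons)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    pos <- pos + gaps[[i]]
    starts_fwd[[i]] <- pos + 1L
    pos <- pos + lens[[i]]
  }
  ends_fwd <- starts_fwd + lens - 1L
  genome_len <- pos + sample(20:100, 1)
  segments <- if (strand == "forward") {
    tibble::tibble(start = starts_fwd, end = ends_fwd)
  } else {
    # mirror the layout; rows stay in coding order, which on the reverse
    # strand means descending genomic start
    tibble::tibble(start = genome_len - ends_fwd + 1L,
                   end = genome_len - starts_fwd + 1L)
  }
  model <- tibble::tibble(
    species = "spX", gene_id = id, spliceform_id = paste0(id, "_t1"),
    organelle = "nuclear", strand = strand, segments = list(segments),
    translation = random_protein_seq(p_len))
  list(model = model, offsets = cuts, p_len = p_len)
}

embl_text <- function(...) paste(c(...), sep = "\n", collapse = "\n")

embl_cds_record <- function(location, gene = "G1", protein_id = "P1",
                            translation = "MKLSVNNQW", organelle = NULL,
                            species = "Homo sapiens") {
  src <- c("FT   source          1..5000",
           if (!is.null(organelle))
             sprintf("FT                   /organelle=\"%s\"", organelle))
  embl_text(
    "ID   X56734; SV 1; linear; DNA; STD; HUM; 5000 BP.",
    sprintf("OS   %s", species),
    src,
    sprintf("FT   CDS             %s", location),
    if (!is.null(gene)) sprintf("FT                   /gene=\"%s\"", gene),
    if (!is.null(protein_id))
      sprintf("FT                   /protein_id=\"%s\"", protein_id),
    if (!is.null(translation))
      sprintf("FT                   /translation=\"%s\"", translation),
    "//")
}

genbank_cds_record <- function(location, gene_id = "101", protein_id = "NP_1",
                               translation = "MKLSVNNQW",
                               species = "Arabidopsis thaliana") {
  embl_text(
    "LOCUS       NC_0001   5000 bp    DNA     linear   PLN 01-JAN-2008",
    "SOURCE      plant",
    sprintf("  ORGANISM  %s", species),
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    sprintf("     CDS             %s", location),
    sprintf("                     /db_xref=\"GeneID:%s\"", gene_id),
    sprintf("                     /protein_id=\"%s\"", protein_id),
    sprintf("                     /translation=\"%s\"", translation),
    "ORIGIN",
    "//")
}

# Small protein-record tibble built directly (no parsing).
make_record <- function(species, gene, spliceform, sequence,
                        mark_residues = integer(),
                        phases = rep(0L, length(mark_residues)),
                        organelle = "nuclear", primary = TRUE) {
  tibble::tibble(
    species = species, gene_id = gene, spliceform_id = spliceform,
    organelle = organelle, sequence = sequence, length = nchar(sequence),
    marks = list(tibble::tibble(residue_index = as.integer(mark_residues),
                                phase = as.integer(phases))),
    primary = primary)
}
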