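test_that("EMBL CDS join locations parse into coding-ordered gene models", {
  txt <- embl_cds_record("join(1..30,101..160)")
  g <- parse_gene_records(txt, "embl")
  expect_equal(nrow(g), 1L)
  expect_equal(g$gene_id, "G1")
  expect_equal(g$spliceform_id, "P1")
  expect_equal(g$species, "Homo sapiens")
  expect_equal(g$strand, "forward")
  expect_equal(g$segments[[1]]$start, c(1L, 101L))
  expect_equal(g$segments[[1]]$end, c(30L, 160L))

  rev <- parse_gene_records(
    embl_cds_record("join(complement(101..160),complement(1..30))"), "embl")
  expect_equal(rev$strand, "reverse")
  # coding order for reverse strand: highest coordinates first
  expect_equal(rev$segments[[1]]$start, c(101L, 1L))
  expect_equal(rev$segments[[1]]$end, c(160L, 30L))

  wrapped <- parse_gene_records(
    embl_cds_record("complement(join(1..30,101..160))"), "embl")
  expect_equal(wrapped$strand, "reverse")
  expect_equal(wrapped$segments[[1]]$start, c(101L, 1L))
})

test_that("fuzzy locations and missing qualifiers are skipped with warnings", {
  expect_warning(
    g <- parse_gene_records(embl_cds_record("join(<1..30,101..160)"), "embl"),
    "fuzzy")
  expect_equal(nrow(g), 0L)
  expect_warning(
    g2 <- parse_gene_records(embl_cds_record("1..30", protein_id = NULL),
                             "embl"),
    "protein_id")
  expect_equal(nrow(g2), 0L)
  expect_warning(
    g3 <- parse_gene_records(embl_cds_record("join(30..1)"), "embl"),
    "unparseable")
  expect_equal(nrow(g3), 0L)
})

test_that("GenBank dialect captures GeneID and organelle", {
  g <- parse_gene_records(genbank_cds_record("join(1..30,101..160)"),
                          "genbank")
  expect_equal(g$gene_id, "101")
  expect_equal(g$spliceform_id, "NP_1")
  expect_equal(g$species, "Arabidopsis thaliana")

  mito <- parse_gene_records(
    embl_cds_record("1..30", organelle = "mitochondrion"), "embl")
  expect_equal(mito$organelle, "mitochondrial")
})

test_that("multi-record files and multi-line translations parse", {
  txt <- paste(embl_cds_record("1..30", protein_id = "P1"),
               embl_cds_record("join(1..15,100..114)", protein_id = "P2"),
               sep = "\n")
  g <- parse_gene_records(txt, "embl")
  expect_equal(g$spliceform_id, c("P1", "P2"))

  long <- embl_text(
    "ID   X; SV 1; linear; DNA; STD; HUM; 500 BP.",
    "OS   Homo sapiens",
    "FT   CDS             1..30",
    "FT                   /protein_id=\"P9\"",
    "FT                   /translation=\"MKLSV",
    "FT                   NNQW\"",
    "//")
  g2 <- parse_gene_records(long, "embl")
  expect_equal(g2$translation, "MKLSVNNQW")
})

test_that("intron offsets are cumulative coding lengths at junctions", {
  expect_equal(intron_offsets(c(30L, 60L)), 30L)
  expect_equal(intron_offsets(c(31L, 59L)), 31L)
  expect_equal(intron_offsets(90L), integer())
  expect_equal(intron_offsets(c(10L, 20L, 30L)), c(10L, 30L))
  expect_error(
    intron_offsets(tibble::tibble(start = c(1L, 20L), end = c(30L, 40L))),
    "overlap")
})

test_that("intron offsets map to residue floor(k/3) and phase k mod 3", {
  seq30 <- random_protein_seq(29)  # 90 nt with stop
  model <- function(lens) tibble::tibble(
    species = "s", gene_id = "g", spliceform_id = "t",
    organelle = "nuclear", strand = "forward",
    segments = list(tibble::tibble(
      start = cumsum(c(1L, utils::head(lens, -1L))),
      end = cumsum(lens))),
    translation = seq30)
  r <- mark_proteins(model(c(30L, 60L)))
  expect_equal(r$marks[[1]]$residue_index, 10L)
  expect_equal(r$marks[[1]]$phase, 0L)
  r2 <- mark_proteins(model(c(31L, 59L)))
  expect_equal(r2$marks[[1]]$residue_index, 10L)
  expect_equal(r2$marks[[1]]$phase, 1L)
  # two introns in the same codon are both retained, distinct phases
  r3 <- mark_proteins(model(c(30L, 1L, 59L)))
  expect_equal(r3$marks[[1]]$residue_index, c(10L, 10L))
  expect_equal(r3$marks[[1]]$phase, c(0L, 1L))
  # junction inside the stop codon is dropped with a warning
  expect_warning(r4 <- mark_proteins(model(c(88L, 2L))), "stop codon")
  expect_equal(nrow(r4$marks[[1]]), 0L)
  # incompatible lengths are an error naming the record
  bad <- model(c(30L, 60L))
  bad$translation <- random_protein_seq(10)
  expect_error(mark_proteins(bad), "incompatible")
})

test_that("offset reconstruction and strand invariance hold on random models", {
  set.seed(101)
  for (i in 1:60) {
    gm <- make_random_gene_model()
    rec <- suppressWarnings(mark_proteins(gm$model))
    m <- rec$marks[[1]]
    kept <- gm$offsets[gm$offsets < 3L * gm$p_len]
    expect_equal(m$residue_index * 3L + m$phase, kept)
    # the same exon lengths on the reverse strand give identical marks
    gm_r <- make_random_gene_model(p_len = gm$p_len, strand = "reverse")
    fwd_lens <- with(gm$model$segments[[1]], end - start + 1L)
    rev_segs <- gm_r$model$segments[[1]]
    same <- gm_r$model
    # rebuild the reverse gene with the forward gene's exon lengths
    starts <- rev_segs$start[1] - c(0L, cumsum(utils::head(fwd_lens, -1L) + 50L))
    same$segments <- list(tibble::tibble(start = starts - fwd_lens + 1L,
                                         end = starts))
    same$translation <- gm$model$translation
    rec_r <- suppressWarnings(mark_proteins(same))
    expect_equal(rec_r$marks[[1]], m)
  }
})

test_that("longest-spliceform selection removes duplicates and breaks ties", {
  recs <- dplyr::bind_rows(
    make_record("s", "g1", "t_long", random_protein_seq(100)),
    make_record("s", "g1", "t_short", random_protein_seq(80)),
    make_record("s", "g2", "t_b", "MKLSV", mark_residues = 2L),
    make_record("s", "g2", "t_a", "MKLSV", mark_residues = 2L),  # duplicate
    make_record("s", "g3", "t_z", "AAAAA"),
    make_record("s", "g3", "t_y", "CCCCC"))
  out <- select_spliceforms(recs)
  expect_true(out$primary[out$spliceform_id == "t_long"])
  expect_false(out$primary[out$spliceform_id == "t_short"])
  # exact duplicate removed, smaller id kept
  expect_equal(out$spliceform_id[out$gene_id == "g2"], "t_a")
  # length tie broken lexicographically
  expect_equal(out$spliceform_id[out$gene_id == "g3" & out$primary], "t_y")
})

test_that("marked FASTA parses lower-case marks and validates headers", {
  r <- read_marked_fasta(">hsa|g1|t1\nMKlS\n")
  expect_equal(r$sequence, "MKLS")
  expect_equal(r$marks[[1]]$residue_index, 2L)
  expect_true(is.na(r$marks[[1]]$phase))
  r2 <- read_marked_fasta(">hsa|g1|t1\nMKLS\n")
  expect_equal(nrow(r2$marks[[1]]), 0L)
  expect_error(read_marked_fasta(">hsa|g1\nMKLS\n"), "header")
})

test_that("marked FASTA round-trips sequence and mark positions", {
  set.seed(7)
  recs <- dplyr::bind_rows(lapply(1:300, function(i) {
    len <- sample(5:200, 1)
    n_marks <- sample(0:min(6, len - 1), 1)
    make_record("sp", sprintf("g%d", i), sprintf("g%d_t1", i),
                random_protein_seq(len),
                mark_residues = sort(sample(0:(len - 1), n_marks)))
  }))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_marked_fasta(recs, f)
  back <- read_marked_fasta(f)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(lapply(back$marks, `[[`, "residue_index"),
               lapply(recs$marks, `[[`, "residue_index"))
  expect_equal(back$spliceform_id, recs$spliceform_id)
})
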