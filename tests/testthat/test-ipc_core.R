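# Build a tiny alignment keyed by spliceform id.
aln <- function(...) c(...)

test_that("marks project onto the alignment columns of their residues", {
  expect_equal(project_marks("MK-LS", tibble::tibble(residue_index = 2L,
                                                     phase = 0L)), 3L)
  expect_equal(project_marks("MK-LS", empty_marks_tbl()), integer())
  expect_error(project_marks("MK-LS", tibble::tibble(residue_index = 4L,
                                                     phase = 0L)),
               "beyond ungapped length")
  # same-residue marks of different phase collapse to one column
  m <- tibble::tibble(residue_index = c(2L, 2L), phase = c(0L, 1L))
  expect_equal(project_marks("MK-LS", m), 3L)
  # random gap patterns: the marked column always holds the marked residue
  set.seed(21)
  for (i in 1:100) {
    seq <- random_protein_seq(sample(5:40, 1))
    n <- nchar(seq)
    res <- sort(sample(0:(n - 1), sample(1:4, 1)))
    chars <- strsplit(seq, "")[[1]]
    gapped <- character()
    for (ch in chars) {
      gapped <- c(gapped, rep("-", sample(0:2, 1)), ch)
    }
    aligned <- paste(gapped, collapse = "")
    cols <- project_marks(aligned, res)
    got <- strsplit(aligned, "")[[1]][cols + 1L]
    expect_equal(got, chars[res + 1L])
  }
})

test_that("shared counts are column-set intersections", {
  expect_equal(count_shared(c(3L, 7L), c(3L, 9L)), 1L)
  expect_equal(count_shared(1:4, 1:4), 4L)
  expect_equal(count_shared(1:3, 4:6), 0L)
})

test_that("IPC is symmetric, bounded, 1 at identity and undefined for intronless pairs", {
  expect_equal(ipc_score(2, 3, 2), 0.8)
  for (n in 1:5) expect_equal(ipc_score(n, n, n), 1)
  expect_true(is.na(ipc_score(0, 0, 0)))
  expect_equal(ipc_score(0, 0, 4), 0)  # one-sided intronless
  expect_error(ipc_score(3, 2, 4), "exceeds")
  expect_equal(ipc_score(2, 3, 2, method = "jaccard"), 2 / 3)
  set.seed(22)
  for (i in 1:50) {
    na <- sample(0:8, 1); nb <- sample(0:8, 1)
    s <- if (min(na, nb) > 0) sample(0:min(na, nb), 1) else 0L
    v <- ipc_score(s, na, nb)
    expect_equal(v, ipc_score(s, nb, na))
    if (!is.na(v)) expect_true(v >= 0 && v <= 1)
  }
})

test_that("identity counts matches over co-aligned columns only", {
  expect_equal(pairwise_identity("MKLS", "MKIS"), 0.75)
  expect_equal(pairwise_identity("MKLS", "MKLS"), 1)
  expect_equal(pairwise_identity("MK--", "--LS"), 0)
  expect_equal(pairwise_identity("MK-S", "MKL-"), 1)  # 2 co-aligned, both match
  expect_error(pairwise_identity("MK", "MKL"), "lengths differ")
})

test_that("a one-residue mark shift destroys sharing; a phase-only change does not", {
  a <- make_record("s", "gA", "gA_t1", "MKLSVNNQW", mark_residues = 4L,
                   phases = 0L)
  al <- aln(gA_t1 = "MKLSVNNQW", gB_t1 = "MKLSVNNQW")
  shift <- make_record("s", "gB", "gB_t1", "MKLSVNNQW", mark_residues = 5L,
                       phases = 0L)
  expect_equal(score_pair(a, shift, al)$introns_shared, 0L)
  rephase <- make_record("s", "gB", "gB_t1", "MKLSVNNQW", mark_residues = 4L,
                         phases = 2L)
  expect_equal(score_pair(a, rephase, al)$introns_shared, 1L)
  expect_equal(score_pair(a, rephase, al)$ipc, 1)
})

test_that("spliceform maximization equals exhaustive enumeration", {
  set.seed(23)
  base <- "MKLSVNNQWADERTYHGFPL"
  for (i in 1:100) {
    n_a <- sample(1:3, 1); n_b <- sample(1:2, 1)
    mk <- function(gene, k) {
      dplyr::bind_rows(lapply(seq_len(k), function(j) {
        nmk <- sample(0:4, 1)
        make_record("s", gene, sprintf("%s_t%d", gene, j), base,
                    mark_residues = sort(sample(0:19, nmk)))
      }))
    }
    ra <- mk("gA", n_a); rb <- mk("gB", n_b)
    al <- stats::setNames(rep(base, n_a + n_b),
                          c(ra$spliceform_id, rb$spliceform_id))
    got <- score_pair(ra, rb, al)
    # independent enumeration over every spliceform combination
    best <- -Inf; found_defined <- FALSE
    for (x in seq_len(n_a)) for (y in seq_len(n_b)) {
      ca <- ra$marks[[x]]$residue_index; cb <- rb$marks[[y]]$residue_index
      na <- length(unique(ca)); nb <- length(unique(cb))
      if (na + nb == 0) next
      found_defined <- TRUE
      v <- 2 * length(intersect(unique(ca), unique(cb))) / (na + nb)
      best <- max(best, v)
    }
    if (found_defined) expect_equal(got$ipc, best) else expect_true(is.na(got$ipc))
  }
})

# Convenience: an extended-cluster member table built by hand.
ext_row <- function(cid, sp, id, seed, cno = NA_character_,
                    cni = NA_character_, boot = NA_real_) {
  tibble::tibble(cluster_id = cid, species = sp, member_id = id,
                 confidence = 1, is_seed = seed, S = 100,
                 bootstrap = boot, cno = cno, cni = cni)
}

test_that("a 1:1 cluster yields one o-o value and one averaged o-cno value", {
  recs <- dplyr::bind_rows(
    make_record("spA", "A1", "A1_t1", "MKLSVNNQW", mark_residues = c(2L, 5L)),
    make_record("spB", "B1", "B1_t1", "MKLSVNNQW", mark_residues = c(2L, 5L)),
    make_record("spB", "X1", "X1_t1", "MKLSVNNQW", mark_residues = 2L),
    make_record("spA", "Y1", "Y1_t1", "MKLSVNNQW", mark_residues = integer()))
  al <- stats::setNames(rep("MKLSVNNQW", 4),
                        c("A1_t1", "B1_t1", "X1_t1", "Y1_t1"))
  ext <- dplyr::bind_rows(
    ext_row("C1", "spA", "A1", TRUE, cno = "X1"),
    ext_row("C1", "spB", "B1", TRUE, cno = "Y1"))
  res <- score_extended_cluster(ext, recs, al)
  oo <- res$pairs[res$pairs$pair_type == "o-o", ]
  expect_equal(nrow(oo), 1L)
  expect_equal(oo$ipc, 1)
  ocno <- res$pairs[res$pairs$pair_type == "o-cno", ]
  expect_equal(nrow(ocno), 1L)
  # (A1 vs X1): 2*1/3; (B1 vs Y1): one-sided intronless = 0; mean = 1/3
  expect_equal(ocno$ipc, mean(c(2 / 3, 0)))
  expect_false("i-i" %in% res$pairs$pair_type)
  expect_true(is.na(res$summary$consistent))  # not a multi-cluster
})

test_that("seed ties with the best inparalog pair count as consistent", {
  recs <- dplyr::bind_rows(
    make_record("spA", "A1", "A1_t1", "MKLSVNNQW", mark_residues = 2L),
    make_record("spA", "A2", "A2_t1", "MKLSVNNQW", mark_residues = 2L),
    make_record("spB", "B1", "B1_t1", "MKLSVNNQW", mark_residues = 2L))
  al <- stats::setNames(rep("MKLSVNNQW", 3), c("A1_t1", "A2_t1", "B1_t1"))
  ext <- dplyr::bind_rows(
    ext_row("C1", "spA", "A1", TRUE),
    ext_row("C1", "spA", "A2", FALSE),
    ext_row("C1", "spB", "B1", TRUE))
  res <- score_extended_cluster(ext, recs, al)
  expect_equal(res$summary$seed_pair_ipc, res$summary$max_ortholog_pair_ipc)
  expect_true(res$summary$consistent)
})

test_that("cluster pair values equal independent per-pair recomputation", {
  set.seed(24)
  base <- "MKLSVNNQWADERTYHGFPL"
  for (rep_i in 1:10) {
    genes <- c(A1 = "spA", A2 = "spA", A3 = "spA", B1 = "spB", B2 = "spB")
    recs <- dplyr::bind_rows(purrr::imap(genes, function(sp, g) {
      make_record(sp, g, paste0(g, "_t1"), base,
                  mark_residues = sort(sample(0:19, sample(1:5, 1))))
    }))
    al <- stats::setNames(rep(base, nrow(recs)), recs$spliceform_id)
    ext <- dplyr::bind_rows(
      ext_row("C1", "spA", "A1", TRUE),
      ext_row("C1", "spA", "A2", FALSE),
      ext_row("C1", "spA", "A3", FALSE),
      ext_row("C1", "spB", "B1", TRUE),
      ext_row("C1", "spB", "B2", FALSE))
    res <- score_extended_cluster(ext, recs, al)
    marks_of <- stats::setNames(purrr::map(recs$marks,
                                           ~ unique(.x$residue_index)),
                                recs$gene_id)
    naive_ipc <- function(g1, g2) {
      a <- marks_of[[g1]]; b <- marks_of[[g2]]
      2 * length(intersect(a, b)) / (length(a) + length(b))
    }
    for (r in which(res$pairs$pair_type %in% c("o-o", "i-i"))) {
      expect_equal(res$pairs$ipc[[r]],
                   naive_ipc(res$pairs$id_a[[r]], res$pairs$id_b[[r]]))
    }
    # o-o count: 3 x 2 cross pairs; i-i: choose(3,2) + choose(2,2)
    expect_equal(sum(res$pairs$pair_type == "o-o"), 6L)
    expect_equal(sum(res$pairs$pair_type == "i-i"), 4L)
    # member-order permutation leaves the summary unchanged
    res2 <- score_extended_cluster(ext[sample(nrow(ext)), ], recs, al)
    expect_equal(res2$summary, res$summary)
  }
})

test_that("a missing aligned sequence is an error naming it", {
  recs <- make_record("spA", "A1", "A1_t1", "MKL")
  expect_error(score_pair(recs, recs, c(other = "MKL")), "A1_t1")
})

test_that("aligned FASTA reading keeps case and maps headers to spliceform ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">spA|g1|g1_t1|nuclear", "MK-lS", ">g2_t1", "MKL-S"), f)
  a <- read_aligned_fasta(f)
  expect_equal(names(a), c("g1_t1", "g2_t1"))
  expect_equal(unname(a[1]), "MK-lS")
})
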