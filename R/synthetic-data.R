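# Two-species gene-family simulator with known orthology and intron
# histories. Each family descends from one ancestral gene: an optional
# pre-speciation duplication creates an outparalog lineage (the future
# cno/cni material), the speciation event splits every lineage into the
# two species, and optional post-speciation duplications create
# inparalogs. Sequences evolve by per-residue substitution (indel-free,
# so true alignments are trivial); intron marks are inherited with
# exponential survival against loss and Poisson gains restricted to a
# protosplice-like set of eligible sites. Similarity scores are a
# monotone decreasing function of divergence time plus bounded noise, so
# bidirectional best hits recover the true orthologs when the noise is
# small.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Simulation parameters
#'
#' Defaults describe a moderately diverged two-species comparison:
#' proteins of 300 residues with 7 ancestral introns, speciation one time
#' unit ago, inparalog duplications 0.3 units ago, the outparalog
#' duplication 1.8 units ago (pre-speciation, so the copy falls outside
#' the ortholog cluster), intron loss at 0.5 events per intron per unit
#' time (ortholog retention about `exp(-0.5)`), sparse intron gain
#' restricted to a protosplice set of 10% of sites, and 2% relative
#' noise on similarity scores.
#'
#' @param n_families Number of simulated families.
#' @param protein_length Residues per protein (indel-free).
#' @param n_ancestral_introns Intron marks on the ancestral gene.
#' @param speciation_depth Time of the speciation event.
#' @param duplication_depth Time of post-speciation (inparalog)
#'   duplications; must be `< speciation_depth`.
#' @param outparalog_depth Time of the pre-speciation duplication; must
#'   be `> speciation_depth`.
#' @param intron_loss_rate Loss events per intron per unit time.
#' @param intron_gain_rate Gain events per eligible site per unit time.
#' @param protosplice_fraction Fraction of sites eligible for gain.
#' @param substitution_rate Substitutions per residue per unit time.
#' @param p_outparalog Probability a family has the outparalog lineage.
#' @param p_inparalog Per-species probability of an inparalog
#'   duplication.
#' @param p_inconsistent Probability that a family with inparalogs is
#'   flagged inconsistent-by-construction (extra intron loss on the seed
#'   terminal branch, so a non-seed pair tends to attain the highest
#'   IPC).
#' @param seed_extra_loss Loss-rate multiplier applied to the focal
#'   seed's terminal branch in flagged families.
#' @param p_extra_spliceform Probability a gene emits a shorter (80%)
#'   second spliceform.
#' @param score_scale,score_noise Similarity-score scale and relative
#'   noise bound.
#' @param bootstrap_high,bootstrap_low Bootstrap sampling ranges
#'   (percent) for the high/low regimes.
#' @param p_low_flagged,p_low_unflagged Probability that a flagged /
#'   unflagged multi-cluster draws its seed bootstraps from the low
#'   regime.
#' @param seed Random seed.
#' @return A validated parameter list of class `sim_params`.
#' @export
sim_params <- function(n_families = 200L,
                       protein_length = 300L,
                       n_ancestral_introns = 7L,
                       speciation_depth = 1,
                       duplication_depth = 0.3,
                       outparalog_depth = 1.8,
                       intron_loss_rate = 0.5,
                       intron_gain_rate = 0.01,
                       protosplice_fraction = 0.1,
                       substitution_rate = 0.2,
                       p_outparalog = 1,
                       p_inparalog = 0.5,
                       p_inconsistent = 0.25,
                       seed_extra_loss = 5,
                       p_extra_spliceform = 0.2,
                       score_scale = 500,
                       score_noise = 0.02,
                       bootstrap_high = c(91, 100),
                       bootstrap_low = c(40, 89),
                       p_low_flagged = 0.8,
                       p_low_unflagged = 0.15,
                       seed = 1L) {
  p <- as.list(environment())
  rates <- c(p$intron_loss_rate, p$intron_gain_rate, p$substitution_rate)
  if (any(rates < 0)) abort_ipcon("rates must be non-negative")
  fracs <- c(p$protosplice_fraction, p$p_outparalog, p$p_inparalog,
             p$p_inconsistent, p$p_extra_spliceform, p$p_low_flagged,
             p$p_low_unflagged)
  if (any(fracs < 0 | fracs > 1)) abort_ipcon("fractions must be in [0, 1]")
  if (p$duplication_depth >= p$speciation_depth) {
    abort_ipcon("duplication_depth must be < speciation_depth")
  }
  if (p$outparalog_depth < p$speciation_depth) {
    abort_ipcon("outparalog_depth must be >= speciation_depth")
  }
  structure(p, class = "sim_params")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_sim_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Evolve intron marks along one branch
#'
#' Each parental intron survives independently with probability
#' `exp(-loss_rate * branch_length)`. Gains are drawn as a Poisson count
#' with mean `gain_rate * branch_length * length(eligible_sites)` and
#' placed (with random phase) at eligible sites not already marked.
#'
#' @param parent_marks Marks tibble (`residue_index`, `phase`).
#' @param branch_length Branch length in time units.
#' @param loss_rate,gain_rate Rates per intron / per eligible site per
#'   unit time.
#' @param eligible_sites Integer vector of 0-based residue indices
#'   eligible for gain (the protosplice set).
#' @return Child marks tibble.
#' @export
evolve_introns <- function(parent_marks, branch_length, loss_rate,
                           gain_rate, eligible_sites = integer()) {
  if (branch_length < 0) abort_ipcon("branch_length must be >= 0")
  keep <- stats::runif(nrow(parent_marks)) <
    exp(-loss_rate * branch_length)
  res <- parent_marks$residue_index[keep]
  ph <- parent_marks$phase[keep]
  n_gain <- stats::rpois(1L, gain_rate * branch_length *
                           length(eligible_sites))
  open <- setdiff(eligible_sites, res)
  n_gain <- min(n_gain, length(open))
  if (n_gain > 0L) {
    res <- c(res, as.integer(sample_safe(open, n_gain)))
    ph <- c(ph, sample(0:2, n_gain, replace = TRUE))
  }
  o <- order(res, ph)
  tibble::tibble(residue_index = res[o], phase = ph[o])
}

# sample() misbehaves on length-1 vectors; this never does.
sample_safe <- function(x, n) x[sample.int(length(x), n)]

mutate_sequence <- function(chars, branch_length, rate) {
  hit <- which(stats::runif(length(chars)) < 1 - exp(-rate * branch_length))
  if (length(hit)) {
    # shift within the alphabet guarantees a different residue
    shift <- sample.int(19L, length(hit), replace = TRUE)
    chars[hit] <- AA20[((match(chars[hit], AA20) - 1L + shift) %% 20L) + 1L]
  }
  chars
}

#' Simulate one gene family
#'
#' @param params Parameters from [sim_params()].
#' @param family_id Integer family index (used in identifiers).
#' @return List with `genes` (tibble: `family`, `gene_id`, `species`,
#'   `role`, `sequence`, `marks`, `flagged`), `relations` (tibble of all
#'   within-family gene pairs with their true relation, time to the most
#'   recent common ancestor and, under pure loss, the expected IPC
#'   `exp(-loss_rate * t_mrca)`), and `flagged`
#'   (inconsistent-by-construction indicator).
#' @export
simulate_family <- function(params, family_id = 1L) {
  p <- params
  L <- p$protein_length
  anc_chars <- sample_safe(AA20, 1L)
  anc_chars <- sample(AA20, L, replace = TRUE)
  n_anc <- min(p$n_ancestral_introns, L)
  anc_marks <- tibble::tibble(
    residue_index = as.integer(sort(sample_safe(0:(L - 1L), n_anc))),
    phase = sample(0:2, n_anc, replace = TRUE))
  eligible <- sort(sample_safe(setdiff(0:(L - 1L), anc_marks$residue_index),
                               round(p$protosplice_fraction * L)))
  has_out <- stats::runif(1) < p$p_outparalog
  dup_a <- stats::runif(1) < p$p_inparalog
  dup_b <- stats::runif(1) < p$p_inparalog
  flagged <- dup_a && stats::runif(1) < p$p_inconsistent

  evolve <- function(node, t, loss_mult = 1) {
    list(chars = mutate_sequence(node$chars, t, p$substitution_rate),
         marks = evolve_introns(node$marks, t,
                                p$intron_loss_rate * loss_mult,
                                p$intron_gain_rate, eligible))
  }
  root <- list(chars = anc_chars, marks = anc_marks)
  t_stem <- p$outparalog_depth - p$speciation_depth
  stem_m <- if (has_out) evolve(root, t_stem) else root
  stem_o <- if (has_out) evolve(root, t_stem) else NULL

  genes <- list()
  add_gene <- function(label, species, role, node) {
    genes[[length(genes) + 1L]] <<- tibble::tibble(
      family = family_id,
      gene_id = sprintf("F%04d_%s", family_id, label),
      species = species, role = role,
      sequence = paste(node$chars, collapse = ""),
      marks = list(node$marks), flagged = flagged)
  }
  side <- function(species, label_main, dup, seed_mult) {
    t_pre <- p$speciation_depth - p$duplication_depth
    if (dup) {
      pre <- evolve(stem_m, t_pre)
      add_gene(paste0(label_main, "1"), species, "seed",
               evolve(pre, p$duplication_depth, seed_mult))
      add_gene(paste0(label_main, "2"), species, "inparalog",
               evolve(pre, p$duplication_depth))
    } else {
      add_gene(paste0(label_main, "1"), species, "seed",
               evolve(stem_m, p$speciation_depth, seed_mult))
    }
  }
  side("spA", "A", dup_a, if (flagged) p$seed_extra_loss else 1)
  side("spB", "B", dup_b, 1)
  if (has_out) {
    add_gene("OA", "spA", "outparalog", evolve(stem_o, p$speciation_depth))
    add_gene("OB", "spB", "outparalog", evolve(stem_o, p$speciation_depth))
  }
  genes <- dplyr::bind_rows(genes)

  t_mrca_of <- function(ga, ra, sa, gb, rb, sb) {
    out_a <- ra == "outparalog"; out_b <- rb == "outparalog"
    if (out_a != out_b) return(p$outparalog_depth)
    if (out_a && out_b) return(p$speciation_depth)
    if (sa != sb) return(p$speciation_depth)
    p$duplication_depth
  }
  relation_of <- function(ra, sa, rb, sb) {
    if (ra == "outparalog" || rb == "outparalog") {
      if (sa == sb) "outparalog_within" else "outparalog_cross"
    } else if (sa == sb) "inparalog_pair" else "ortholog_pair"
  }
  combos <- utils::combn(nrow(genes), 2L)
  ia <- combos[1L, ]; ib <- combos[2L, ]
  t_mrca <- vapply(seq_along(ia), function(i) {
    t_mrca_of(genes$gene_id[[ia[[i]]]], genes$role[[ia[[i]]]],
              genes$species[[ia[[i]]]], genes$gene_id[[ib[[i]]]],
              genes$role[[ib[[i]]]], genes$species[[ib[[i]]]])
  }, double(1))
  relation <- vapply(seq_along(ia), function(i) {
    relation_of(genes$role[[ia[[i]]]], genes$species[[ia[[i]]]],
                genes$role[[ib[[i]]]], genes$species[[ib[[i]]]])
  }, character(1))
  relations <- tibble::tibble(
    family = family_id, id_a = genes$gene_id[ia], id_b = genes$gene_id[ib],
    relation = relation, t_mrca = t_mrca,
    expected_ipc = exp(-p$intron_loss_rate * t_mrca))
  list(genes = genes, relations = relations, flagged = flagged)
}

#' Simulate a complete two-species dataset
#'
#' Runs [simulate_family()] for every family and assembles all pipeline
#' inputs in memory: protein records (with optional shorter second
#' spliceforms), the all-vs-all similarity table (within-family hits,
#' both directions plus self hits), the truth-derived cluster table with
#' seed bootstrap values tied to the inconsistency flags, one trivial
#' true alignment per family/cluster, and GO/Pfam annotation tables for
#' the focal species with a term planted at elevated frequency in
#' flagged families. Deterministic given `params$seed`.
#'
#' @param params Parameters from [sim_params()].
#' @return List with `records`, `hits`, `clusters`, `alignments` (named
#'   list by cluster id), `go`, `pfam`, `clan_map`, `truth` (list:
#'   `genes`, `relations`).
#' @export
simulate_dataset <- function(params) {
  p <- params
  with_sim_seed(p$seed, {
    fams <- purrr::map(seq_len(p$n_families), ~ simulate_family(p, .x))
    genes <- dplyr::bind_rows(purrr::map(fams, "genes"))
    relations <- dplyr::bind_rows(purrr::map(fams, "relations"))

    # protein records: primary spliceform per gene + optional shorter one
    records <- genes %>%
      dplyr::mutate(
        spliceform_id = paste0(.data$gene_id, "_t1"),
        organelle = "nuclear",
        length = nchar(.data$sequence),
        primary = TRUE) %>%
      dplyr::select("species", "gene_id", "spliceform_id", "organelle",
                    "sequence", "length", "marks", "primary")
    extra_idx <- which(stats::runif(nrow(records)) < p$p_extra_spliceform)
    extras <- records[extra_idx, ] %>%
      dplyr::mutate(
        spliceform_id = sub("_t1$", "_t2", .data$spliceform_id),
        length = as.integer(floor(0.8 * .data$length)),
        sequence = substr(.data$sequence, 1L, .data$length),
        marks = purrr::map2(.data$marks, .data$length,
                            ~ .x[.x$residue_index < .y, , drop = FALSE]),
        primary = FALSE)
    records <- dplyr::bind_rows(records, extras)

    # similarity hits: all ordered within-family pairs incl. self hits
    score_of <- function(t) {
      p$score_scale * exp(-t) *
        (1 + p$score_noise * stats::runif(length(t), -1, 1))
    }
    sp_of <- stats::setNames(genes$species, genes$gene_id)
    sym <- relations %>%
      dplyr::select("id_a", "id_b", "t_mrca")
    hits <- dplyr::bind_rows(
      sym %>% dplyr::transmute(query = .data$id_a, subject = .data$id_b,
                               t_mrca = .data$t_mrca),
      sym %>% dplyr::transmute(query = .data$id_b, subject = .data$id_a,
                               t_mrca = .data$t_mrca),
      tibble::tibble(query = genes$gene_id, subject = genes$gene_id,
                     t_mrca = 0)) %>%
      dplyr::mutate(qspecies = unname(sp_of[.data$query]),
                    sspecies = unname(sp_of[.data$subject]),
                    score = score_of(.data$t_mrca),
                    qcov = 1, segcov = 1) %>%
      dplyr::select("query", "subject", "qspecies", "sspecies", "score",
                    "qcov", "segcov")

    # truth-derived cluster table (seeds + inparalogs; outparalogs stay out)
    flagged_fams <- purrr::map_lgl(fams, "flagged")
    clusters <- purrr::map(seq_along(fams), function(fi) {
      g <- fams[[fi]]$genes %>%
        dplyr::filter(.data$role %in% c("seed", "inparalog"))
      cid <- sprintf("C%04d", fi)
      seeds <- g$gene_id[g$role == "seed"]
      s_hits <- hits$score[(hits$query == seeds[[1]] &
                              hits$subject == seeds[[2]]) |
                             (hits$query == seeds[[2]] &
                                hits$subject == seeds[[1]])]
      S <- mean(s_hits)
      is_multi <- any(g$role == "inparalog")
      low <- stats::runif(1) < if (flagged_fams[[fi]]) p$p_low_flagged else
        p$p_low_unflagged
      rng <- if (low) p$bootstrap_low else p$bootstrap_high
      boots <- round(stats::runif(2, rng[[1]], rng[[2]]))
      tibble::tibble(
        cluster_id = cid, species = g$species, member_id = g$gene_id,
        confidence = ifelse(g$role == "seed", 1,
                            round(stats::runif(nrow(g), 0.3, 0.99), 3)),
        is_seed = g$role == "seed", S = S,
        bootstrap = ifelse(g$role == "seed",
                           boots[match(g$species, c("spA", "spB"))],
                           NA_real_),
        is_multi = is_multi)
    }) %>% dplyr::bind_rows() %>% dplyr::select(-"is_multi")

    # trivial true alignments (indel-free; shorter spliceforms padded)
    aln_len <- p$protein_length
    alignments <- purrr::map(seq_along(fams), function(fi) {
      fam_genes <- fams[[fi]]$genes$gene_id
      r <- dplyr::filter(records, .data$gene_id %in% fam_genes)
      stats::setNames(
        purrr::map_chr(r$sequence, function(s) {
          paste0(s, strrep("-", aln_len - nchar(s)))
        }), r$spliceform_id)
    })
    names(alignments) <- sprintf("C%04d", seq_along(fams))

    # focal-species annotations with a planted term in flagged families
    focal <- genes %>% dplyr::filter(.data$species == "spA")
    planted_rate <- ifelse(focal$flagged, 0.5, 0.1)
    go <- dplyr::bind_rows(
      tibble::tibble(gene_id = focal$gene_id, term = "GO:1000001",
                     keep = stats::runif(nrow(focal)) < planted_rate),
      purrr::map(sprintf("GO:%07d", 2000001:2000010), function(tm) {
        tibble::tibble(gene_id = focal$gene_id, term = tm,
                       keep = stats::runif(nrow(focal)) < 0.1)
      }) %>% dplyr::bind_rows()) %>%
      dplyr::filter(.data$keep) %>%
      dplyr::select("gene_id", "term")
    domains <- sprintf("PF%05d", 1:10)
    pfam <- purrr::map(seq_len(nrow(focal)), function(i) {
      n_dom <- sample(1:3, 1L)
      dom <- sample(domains, n_dom, replace = TRUE)
      rep_run <- stats::runif(1) < 0.2
      if (rep_run) dom <- c(dom, rep("PFR0001", sample(2:4, 1L)))
      tibble::tibble(gene_id = focal$gene_id[[i]], domain = dom,
                     start = seq_along(dom) * 50L,
                     repeat_type = dom == "PFR0001")
    }) %>% dplyr::bind_rows()
    clan_map <- tibble::tibble(
      domain = c("PF00001", "PF00002", "PF00003"),
      clan = c("CL0001", "CL0001", "CL0002"))

    list(records = records, hits = hits, clusters = clusters,
         alignments = alignments, go = go, pfam = pfam,
         clan_map = clan_map,
         truth = list(genes = genes %>% dplyr::select(-"sequence", -"marks"),
                      relations = relations))
  })
}

#' Write a simulated dataset to pipeline input files
#'
#' Emits the formats the pipeline consumes: `proteins.fasta` (marked
#' FASTA), `similarity.tsv`, `clusters.tsv` (with seed bootstraps),
#' `alignments/<cluster_id>.fasta`, `go_annotations.tsv`,
#' `pfam_domains.tsv`, `clan_map.tsv`, plus truth tables
#' (`truth_genes.tsv`, `truth_relations.tsv`). Byte-identical for a
#' fixed `params$seed`.
#'
#' @param params Parameters from [sim_params()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the in-memory dataset from [simulate_dataset()].
#' @export
emit_dataset <- function(params, dir) {
  ds <- simulate_dataset(params)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  write_marked_fasta(ds$records, file.path(dir, "proteins.fasta"))
  write_tsv_quiet(dplyr::mutate(ds$hits,
                                score = round(.data$score, 4)),
                  file.path(dir, "similarity.tsv"))
  write_tsv_quiet(dplyr::mutate(ds$clusters, S = round(.data$S, 4)),
                  file.path(dir, "clusters.tsv"))
  purrr::iwalk(ds$alignments, function(aln, cid) {
    write_aligned_fasta(aln, file.path(dir, "alignments",
                                       paste0(cid, ".fasta")))
  })
  write_tsv_quiet(ds$go, file.path(dir, "go_annotations.tsv"))
  write_tsv_quiet(ds$pfam, file.path(dir, "pfam_domains.tsv"))
  write_tsv_quiet(ds$clan_map, file.path(dir, "clan_map.tsv"))
  write_tsv_quiet(ds$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv_quiet(dplyr::mutate(ds$truth$relations,
                                expected_ipc = round(.data$expected_ipc, 6)),
                  file.path(dir, "truth_relations.tsv"))
  invisible(ds)
}

#' Simulate annotation tables with one planted term
#'
#' Builds a gene universe with a designated foreground subset and plants
#' one term at `fold` times the background annotation rate in the
#' foreground, alongside unenriched noise terms. Used to test
#' planted-enrichment recovery.
#'
#' @param n_fg,n_bg Foreground/background gene counts.
#' @param planted_term Term id to plant.
#' @param fold Foreground enrichment factor on the annotation rate.
#' @param base_rate Background annotation probability per gene.
#' @param n_noise_terms Number of unenriched terms.
#' @param noise_rate Annotation probability per gene for noise terms.
#' @return List with `fg`, `universe`, `annotations`.
#' @export
simulate_annotations <- function(n_fg = 200L, n_bg = 800L,
                                 planted_term = "GO:PLANTED",
                                 fold = 5, base_rate = 0.05,
                                 n_noise_terms = 20L,
                                 noise_rate = 0.1) {
  genes <- sprintf("g%04d", seq_len(n_fg + n_bg))
  fg <- genes[seq_len(n_fg)]
  rate <- ifelse(genes %in% fg, pmin(1, fold * base_rate), base_rate)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes, term = planted_term,
                   keep = stats::runif(length(genes)) < rate),
    purrr::map(sprintf("GO:N%03d", seq_len(n_noise_terms)), function(tm) {
      tibble::tibble(gene_id = genes, term = tm,
                     keep = stats::runif(length(genes)) < noise_rate)
    }) %>% dplyr::bind_rows()) %>%
    dplyr::filter(.data$keep) %>%
    dplyr::select("gene_id", "term")
  list(fg = fg, universe = genes, annotations = ann)
}
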