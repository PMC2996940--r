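# Simplified InParanoid-style two-species clustering: bidirectional best
# hits seed a cluster, within-species sequences at least as similar to the
# seed as the seed pair's score S join as inparalogs, and each member's
# closest non-ortholog (cno, other species) and closest non-inparalog
# (cni, same species) extend the cluster. The original algorithm's
# cluster-conflict resolution is replaced by greedy seed processing in
# descending S with members removed from the candidate pool once assigned;
# bootstrap values for seeds are consumed as input, never computed here.

#' Coverage filter for similarity hits
#'
#' A hit passes when its query coverage is at least `overlap_cutoff` and
#' its longest contiguous matching segment covers at least
#' `segment_cutoff` of the query. Both boundaries are inclusive.
#'
#' @param hits Similarity-hit tibble with columns `query`, `subject`,
#'   `qspecies`, `sspecies`, `score`, `qcov`, `segcov`.
#' @param overlap_cutoff,segment_cutoff Coverage cutoffs (fractions).
#' @return Logical vector, one element per hit.
#' @export
passes_coverage <- function(hits, overlap_cutoff = 0.5,
                            segment_cutoff = 0.25) {
  hits$qcov >= overlap_cutoff & hits$segcov >= segment_cutoff
}

#' Find seed ortholog pairs (bidirectional best hits)
#'
#' `(a, b)` is a seed pair when `b` is `a`'s best cross-species hit and
#' `a` is `b`'s best cross-species hit, considering only hits that pass
#' the coverage cutoffs. Best-hit ties are broken by lexicographic subject
#' id. The seed score `S` is the mean of the two directional scores.
#' `id_a` belongs to the lexicographically smaller species.
#'
#' @inheritParams passes_coverage
#' @return Tibble with `id_a`, `id_b`, `species_a`, `species_b`, `S`.
#' @export
find_seed_pairs <- function(hits, overlap_cutoff = 0.5,
                            segment_cutoff = 0.25) {
  empty <- tibble::tibble(id_a = character(), id_b = character(),
                          species_a = character(), species_b = character(),
                          S = double())
  if (nrow(hits) == 0L) return(empty)
  cross <- hits %>%
    dplyr::filter(passes_coverage(hits, overlap_cutoff, segment_cutoff)) %>%
    dplyr::filter(.data$qspecies != .data$sspecies)
  if (nrow(cross) == 0L) return(empty)
  best <- cross %>%
    dplyr::group_by(.data$qspecies, .data$query) %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$subject,
                   .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup()
  sp <- sort(unique(c(cross$qspecies, cross$sspecies)))
  a_best <- dplyr::filter(best, .data$qspecies == sp[[1]])
  b_best <- dplyr::filter(best, .data$qspecies == sp[[length(sp)]])
  mutual <- dplyr::inner_join(
    dplyr::select(a_best, id_a = "query", id_b = "subject",
                  score_ab = "score"),
    dplyr::select(b_best, id_b = "query", id_a = "subject",
                  score_ba = "score"),
    by = c("id_a", "id_b"))
  mutual %>%
    dplyr::transmute(.data$id_a, .data$id_b,
                     species_a = sp[[1]], species_b = sp[[length(sp)]],
                     S = (.data$score_ab + .data$score_ba) / 2) %>%
    dplyr::arrange(dplyr::desc(.data$S), .data$id_a, .data$id_b)
}

# Within-species similarity of x to the seed: score of the hit with the
# seed as subject.
within_scores <- function(hits, species, seed) {
  hits %>%
    dplyr::filter(.data$qspecies == species, .data$sspecies == species,
                  .data$subject == seed)
}

#' Attach inparalogs to a seed pair
#'
#' Per species independently, a sequence `x` joins the cluster when its
#' similarity to that species' seed is at least the seed score `S`
#' (inclusive). The similarity used is the score of the hit with the seed
#' as subject. Confidence is `(sim - S) / (self - S)` clamped to
#' `[0, 1]`, where `self` is the seed's self-hit score; seeds have
#' confidence 1. When `self <= S` the seed keeps confidence 1, other
#' members get 0, with a warning.
#'
#' @inheritParams passes_coverage
#' @param seed One row of [find_seed_pairs()] output.
#' @param candidates Optional character vector restricting which ids may
#'   join (used by the greedy pool in [build_clusters()]).
#' @return Member tibble: `species`, `member_id`, `confidence`,
#'   `is_seed`, sorted seeds first then confidence descending.
#' @export
add_inparalogs <- function(hits, seed, candidates = NULL,
                           overlap_cutoff = 0.5, segment_cutoff = 0.25) {
  hits <- dplyr::filter(
    hits, passes_coverage(hits, overlap_cutoff, segment_cutoff))
  one_side <- function(species, seed_id) {
    ws <- within_scores(hits, species, seed_id) %>%
      dplyr::filter(.data$query != seed_id)
    if (!is.null(candidates)) {
      ws <- dplyr::filter(ws, .data$query %in% candidates)
    }
    selfs <- within_scores(hits, species, seed_id) %>%
      dplyr::filter(.data$query == seed_id)
    self <- if (nrow(selfs)) max(selfs$score) else NA_real_
    inp <- if (nrow(ws) == 0L) {
      tibble::tibble(query = character(), sim = double())
    } else {
      ws %>%
        dplyr::group_by(.data$query) %>%
        dplyr::summarise(sim = max(.data$score), .groups = "drop") %>%
        dplyr::filter(.data$sim >= seed$S)
    }
    conf <- if (nrow(inp) == 0L) {
      double()
    } else if (is.na(self) || self <= seed$S) {
      warn_ipcon("seed %s self-score not above S; inparalog confidences set to 0",
                 seed_id)
      rep(0, nrow(inp))
    } else {
      pmin(1, pmax(0, (inp$sim - seed$S) / (self - seed$S)))
    }
    dplyr::bind_rows(
      tibble::tibble(species = species, member_id = seed_id,
                     confidence = 1, is_seed = TRUE),
      tibble::tibble(species = species, member_id = inp$query,
                     confidence = conf, is_seed = FALSE)) %>%
      dplyr::arrange(dplyr::desc(.data$is_seed),
                     dplyr::desc(.data$confidence), .data$member_id)
  }
  dplyr::bind_rows(one_side(seed$species_a, seed$id_a),
                   one_side(seed$species_b, seed$id_b))
}

#' Build disjoint ortholog clusters from a similarity table
#'
#' Finds seed pairs, processes them greedily in descending `S` (ties by
#' member ids), and attaches inparalogs from the pool of genes not yet
#' assigned to any cluster, so clusters are disjoint by construction.
#' Seeds whose members were already consumed by a stronger cluster are
#' dropped.
#'
#' @inheritParams passes_coverage
#' @return Cluster tibble: `cluster_id`, `species`, `member_id`,
#'   `confidence`, `is_seed`, `S`.
#' @export
build_clusters <- function(hits, overlap_cutoff = 0.5,
                           segment_cutoff = 0.25) {
  seeds <- find_seed_pairs(hits, overlap_cutoff, segment_cutoff)
  assigned <- character()
  all_ids <- unique(c(hits$query, hits$subject))
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(seeds))) {
    seed <- seeds[i, ]
    if (seed$id_a %in% assigned || seed$id_b %in% assigned) next
    k <- k + 1L
    members <- add_inparalogs(hits, seed,
                              candidates = setdiff(all_ids, assigned),
                              overlap_cutoff = overlap_cutoff,
                              segment_cutoff = segment_cutoff)
    members$cluster_id <- sprintf("C%04d", k)
    members$S <- seed$S
    assigned <- c(assigned, members$member_id)
    out[[k]] <- members
  }
  if (k == 0L) {
    return(tibble::tibble(cluster_id = character(), species = character(),
                          member_id = character(), confidence = double(),
                          is_seed = logical(), S = double()))
  }
  dplyr::bind_rows(out) %>%
    dplyr::select("cluster_id", "species", "member_id", "confidence",
                  "is_seed", "S")
}

#' Extend clusters with closest non-orthologs and non-inparalogs
#'
#' For each cluster member `m`, the closest non-ortholog `cno(m)` is the
#' highest-scoring hit of `m` in the other species that is not a member
#' of this cluster and passes the coverage cutoffs; the closest
#' non-inparalog `cni(m)` is the analogue within `m`'s own species. A cno
#' or cni may belong to another cluster; only membership in the focal
#' cluster excludes it. Absence is recorded as `NA`. Clusters containing
#' any mitochondrial gene are dropped entirely (all such genes are
#' intronless), which requires `records` with an `organelle` column.
#'
#' @param clusters Cluster tibble from [build_clusters()] or
#'   [read_cluster_table()].
#' @inheritParams passes_coverage
#' @param records Optional protein-record tibble supplying `organelle`
#'   per `(species, gene_id)`.
#' @return The cluster tibble with `cno` and `cni` columns added.
#' @export
extend_clusters <- function(clusters, hits, records = NULL,
                            overlap_cutoff = 0.5, segment_cutoff = 0.25) {
  if (!is.null(records)) {
    mito <- records %>%
      dplyr::filter(.data$organelle == "mitochondrial") %>%
      dplyr::distinct(.data$species, gene_id = .data$gene_id)
    bad <- clusters %>%
      dplyr::semi_join(mito, by = c("species", member_id = "gene_id")) %>%
      dplyr::pull("cluster_id")
    clusters <- dplyr::filter(clusters, !.data$cluster_id %in% bad)
  }
  good <- dplyr::filter(
    hits, passes_coverage(hits, overlap_cutoff, segment_cutoff),
    .data$query != .data$subject) %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$subject)
  by_query <- split(seq_len(nrow(good)), good$query)
  members_of <- split(clusters$member_id, clusters$cluster_id)
  best_excluding <- function(m, mspecies, other_species, excluded) {
    idx <- by_query[[m]]
    if (is.null(idx)) return(NA_character_)
    cand <- good[idx, ]
    keep <- if (other_species) cand$sspecies != mspecies else
      cand$sspecies == mspecies
    keep <- keep & !(cand$subject %in% excluded)
    if (!any(keep)) NA_character_ else cand$subject[which(keep)[[1]]]
  }
  clusters %>%
    dplyr::mutate(
      cno = purrr::pmap_chr(
        list(.data$member_id, .data$species, .data$cluster_id),
        function(m, s, cid) best_excluding(m, s, TRUE, members_of[[cid]])),
      cni = purrr::pmap_chr(
        list(.data$member_id, .data$species, .data$cluster_id),
        function(m, s, cid) best_excluding(m, s, FALSE, members_of[[cid]])))
}

#' Read and write cluster tables
#'
#' The TSV dialect mirrors InParanoid-style output: columns `cluster_id`,
#' `species`, `member_id`, `confidence`, `S`, optionally `bootstrap`
#' (percent, seeds only) and `is_seed`. When `is_seed` is absent, the
#' highest-confidence member per cluster and species is taken as the
#' seed. A member appearing in two clusters is an error.
#'
#' @param path File path (or the TSV text itself if it contains a
#'   newline).
#' @return A cluster tibble (with `bootstrap` column, `NA` where
#'   unknown).
#' @export
read_cluster_table <- function(path) {
  x <- if (length(path) == 1L && grepl("\n", path)) I(path) else path
  tab <- read_tsv_quiet(x)
  need <- c("cluster_id", "species", "member_id", "confidence", "S")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    abort_ipcon("cluster table lacks column(s): %s",
                paste(missing, collapse = ", "))
  }
  dup <- tab %>%
    dplyr::distinct(.data$cluster_id, .data$species, .data$member_id) %>%
    dplyr::count(.data$species, .data$member_id) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort_ipcon("member(s) present in more than one cluster: %s",
                paste(dup$member_id, collapse = ", "))
  }
  if (!"bootstrap" %in% names(tab)) tab$bootstrap <- NA_real_
  if (!"is_seed" %in% names(tab)) {
    tab <- tab %>%
      dplyr::group_by(.data$cluster_id, .data$species) %>%
      dplyr::mutate(is_seed = dplyr::row_number(
        order(-.data$confidence, .data$member_id)) == 1L) %>%
      dplyr::ungroup()
  }
  tab %>%
    dplyr::mutate(cluster_id = as.character(.data$cluster_id),
                  member_id = as.character(.data$member_id)) %>%
    dplyr::select("cluster_id", "species", "member_id", "confidence",
                  "is_seed", "S", "bootstrap")
}

#' @param clusters Cluster tibble to write.
#' @rdname read_cluster_table
#' @export
write_cluster_table <- function(clusters, path) {
  write_tsv_quiet(clusters, path)
  invisible(path)
}

#' Read a similarity-hit table
#'
#' TSV with columns `query`, `subject`, `qspecies`, `sspecies`, `score`,
#' `qcov`, `segcov` (bit-score-like positive scores; coverages in
#' `[0, 1]`).
#'
#' @inheritParams read_cluster_table
#' @return Similarity-hit tibble.
#' @export
read_similarity_table <- function(path) {
  x <- if (length(path) == 1L && grepl("\n", path)) I(path) else path
  tab <- read_tsv_quiet(x)
  need <- c("query", "subject", "qspecies", "sspecies", "score",
            "qcov", "segcov")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    abort_ipcon("similarity table lacks column(s): %s",
                paste(missing, collapse = ", "))
  }
  dplyr::mutate(tab, query = as.character(.data$query),
                subject = as.character(.data$subject))
}

#' Flag multi-clusters
#'
#' A multi-cluster contains at least one non-seed member (inparalog).
#'
#' @param clusters Cluster tibble.
#' @return Tibble `cluster_id`, `is_multi`.
#' @export
cluster_multi_flags <- function(clusters) {
  clusters %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(is_multi = any(!.data$is_seed), .groups = "drop")
}
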