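# Hypergeometric term enrichment of inconsistent-cluster genes with BH
# FDR control, the term-association network with greedy representative
# selection, Pfam clan rollup, repeat collapsing and protein-property
# comparisons.

#' Remove oversize multi-clusters
#'
#' Very large clusters (e.g. olfactory-receptor expansions of several
#' hundred genes) are likely orthology artifacts and would dominate an
#' enrichment analysis; clusters whose total member count exceeds
#' `max_genes` (strictly) are removed.
#'
#' @param clusters Cluster tibble (one row per member).
#' @param max_genes Size threshold (strict `>`).
#' @return List with `clusters` (filtered tibble) and `removed` (tibble
#'   of removed cluster ids with their sizes).
#' @export
filter_oversize <- function(clusters, max_genes = 200L) {
  sizes <- dplyr::count(clusters, .data$cluster_id, name = "n_genes")
  removed <- dplyr::filter(sizes, .data$n_genes > max_genes)
  if (nrow(removed)) {
    warn_ipcon("removed %d oversize cluster(s): %s", nrow(removed),
               paste(sprintf("%s (%d genes)", removed$cluster_id,
                             removed$n_genes), collapse = ", "))
  }
  list(clusters = dplyr::filter(clusters,
                                !.data$cluster_id %in% removed$cluster_id),
       removed = removed)
}

#' Hypergeometric enrichment/depletion test for one term
#'
#' Draws of size `|fg|` from a universe of `|universe|` genes containing
#' `K` term-annotated genes. `p_enriched` is the upper tail
#' `P(X >= fg_count)`, `p_depleted` the lower tail `P(X <= fg_count)`;
#' the direction is the smaller tail.
#'
#' @param term Term identifier.
#' @param fg Foreground gene set (subset of `universe`).
#' @param universe Background gene set.
#' @param annotations Tibble `gene_id`, `term`.
#' @return One-row tibble: `term`, `fg_count`, `bg_count`, `fg_size`,
#'   `bg_size`, `p_enriched`, `p_depleted`, `direction`.
#' @export
hypergeom_term_test <- function(term, fg, universe, annotations) {
  genes_with <- unique(
    annotations$gene_id[annotations$term == term &
                          annotations$gene_id %in% universe])
  K <- length(genes_with)
  if (K == 0L) abort_ipcon("term %s annotates no gene in the universe", term)
  N <- length(universe)
  n <- length(fg)
  x <- sum(fg %in% genes_with)
  p_enr <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
  p_dep <- stats::phyper(x, K, N - K, n)
  tibble::tibble(
    term = term, fg_count = x, bg_count = K, fg_size = n, bg_size = N,
    p_enriched = p_enr, p_depleted = p_dep,
    direction = ifelse(p_enr <= p_dep, "enriched", "depleted"))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up procedure on the per-term two-sided p-values (the doubled
#' minimal tail, capped at 1): the largest `k` with
#' `p_(k) <= k * fdr / m` and everything ranked at or below it is
#' significant.
#'
#' @param p Numeric vector of p-values.
#' @param fdr Target false discovery rate.
#' @return Logical vector of significance flags.
#' @export
bh_significant <- function(p, fdr = 0.01) {
  stats::p.adjust(p, method = "BH") <= fdr
}

#' Term enrichment analysis with FDR control
#'
#' Tests every term annotated to at least one universe gene for
#' enrichment or depletion of the foreground set, and flags significance
#' by Benjamini-Hochberg on the two-sided p-values (`p_two = min(1, 2 *
#' min(p_enriched, p_depleted))`), treating enrichment and depletion as
#' one test family by default (`family = "joint"`); `family =
#' "separate"` runs BH within each direction.
#'
#' @inheritParams hypergeom_term_test
#' @param fdr Target false discovery rate.
#' @param family `"joint"` or `"separate"`, see Description.
#' @return Tibble of class `ipc_enrichment`, one row per term, with
#'   `p_two` and `significant` columns, sorted by `p_two`.
#' @export
enrich_terms <- function(fg, universe, annotations, fdr = 0.01,
                         family = c("joint", "separate")) {
  family <- match.arg(family)
  if (!all(fg %in% universe)) {
    abort_ipcon("foreground contains genes outside the universe")
  }
  ann <- dplyr::filter(annotations, .data$gene_id %in% universe)
  terms <- sort(unique(ann$term))
  res <- purrr::map(terms, hypergeom_term_test, fg = fg,
                    universe = universe, annotations = ann) %>%
    dplyr::bind_rows() %>%
    dplyr::mutate(p_two = pmin(1, 2 * pmin(.data$p_enriched,
                                           .data$p_depleted)))
  if (family == "joint") {
    res$significant <- bh_significant(res$p_two, fdr)
  } else {
    res$significant <- FALSE
    for (d in c("enriched", "depleted")) {
      i <- res$direction == d
      if (any(i)) res$significant[i] <- bh_significant(res$p_two[i], fdr)
    }
  }
  res <- dplyr::arrange(res, .data$p_two, .data$term)
  structure(res, class = c("ipc_enrichment", class(res)),
            fdr = fdr, family = family)
}

#' Term-association edges by exclusion re-testing
#'
#' For each significant term `A`, the full enrichment analysis is rerun
#' on the universe with all `A`-annotated genes excluded. Every term `B`
#' that was significant on the full set but is no longer significant
#' after the exclusion (including terms that drop out of the testable
#' set) is considered associated with `A`: a directed edge `A -> B` is
#' recorded, and edges are treated symmetrically when counting links.
#'
#' @param result `ipc_enrichment` result on the full set.
#' @inheritParams enrich_terms
#' @return Tibble of directed edges `from`, `to`.
#' @export
term_association_edges <- function(result, fg, universe, annotations,
                                   fdr = attr(result, "fdr") %||% 0.01,
                                   family = attr(result, "family") %||% "joint") {
  sig <- result$term[result$significant]
  if (length(sig) < 2L) {
    return(tibble::tibble(from = character(), to = character()))
  }
  edges <- purrr::map(sig, function(a) {
    a_genes <- unique(annotations$gene_id[annotations$term == a])
    uni2 <- setdiff(universe, a_genes)
    fg2 <- intersect(fg, uni2)
    others <- setdiff(sig, a)
    still <- character()
    if (length(fg2) > 0L && length(uni2) > 0L) {
      ann2 <- dplyr::filter(annotations, .data$gene_id %in% uni2)
      if (nrow(ann2) > 0L) {
        res2 <- enrich_terms(fg2, uni2, ann2, fdr = fdr, family = family)
        still <- res2$term[res2$significant]
      }
    }
    lost <- setdiff(others, still)
    if (length(lost) == 0L) return(NULL)
    tibble::tibble(from = a, to = lost)
  })
  dplyr::bind_rows(c(list(tibble::tibble(from = character(),
                                         to = character())),
                     purrr::compact(edges)))
}

#' Greedy representative selection on a term-association network
#'
#' Iteratively selects the node with the most links (ties broken by
#' smallest term id), records it together with its current neighbors as
#' one group, removes the representative and its neighbors, and repeats
#' until no node remains. Isolated nodes become their own
#' representatives. The resulting groups partition the node set.
#'
#' @param edges Edge tibble `from`, `to` (interpreted symmetrically).
#' @param nodes Character vector of all nodes (defaults to the nodes in
#'   `edges`).
#' @return Tibble with `representative`, `members` (list column of
#'   absorbed neighbor sets, excluding the representative itself) and
#'   `n_links`.
#' @export
pick_representatives <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  adj <- purrr::map(
    stats::setNames(nodes, nodes),
    function(v) {
      sort(unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
    })
  remaining <- nodes
  out <- list(tibble::tibble(representative = character(),
                             members = list(), n_links = integer()))
  while (length(remaining) > 0L) {
    deg <- purrr::map_int(remaining, ~ length(intersect(adj[[.x]], remaining)))
    pick <- remaining[order(-deg, remaining)][[1]]
    nb <- intersect(adj[[pick]], remaining)
    out[[length(out) + 1L]] <- tibble::tibble(
      representative = pick, members = list(nb), n_links = length(nb))
    remaining <- setdiff(remaining, c(pick, nb))
  }
  dplyr::bind_rows(out)
}

#' Roll up domain annotations to Pfam clans
#'
#' Replaces each domain by its clan where the clan map provides one,
#' keeps unmapped domains as-is, and deduplicates per-gene term sets.
#'
#' @param annotations Tibble `gene_id`, `term` (domain ids).
#' @param clan_map Tibble `domain`, `clan` (partial).
#' @return Annotation tibble at clan level.
#' @export
clan_rollup <- function(annotations, clan_map) {
  annotations %>%
    dplyr::left_join(clan_map, by = c(term = "domain")) %>%
    dplyr::mutate(term = dplyr::coalesce(.data$clan, .data$term)) %>%
    dplyr::select(-"clan") %>%
    dplyr::distinct()
}

#' Collapse consecutive repeat-type domain hits
#'
#' Maximal consecutive runs of the same Repeat/Motif-type domain along a
#' protein collapse into a single pseudo-domain (repeat copy-number is
#' highly variable and would otherwise dominate domain counts);
#' non-repeat domains are left unchanged.
#'
#' @param hits Tibble of ordered domain hits with columns `gene_id`,
#'   `domain`, `start` (position order along the protein) and
#'   `repeat_type` (logical).
#' @return List with `hits` (collapsed tibble) and `counts` (tibble
#'   `gene_id`, `n_pseudo_domains`).
#' @export
collapse_repeats <- function(hits) {
  if (nrow(hits) == 0L) {
    return(list(hits = hits,
                counts = tibble::tibble(gene_id = character(),
                                        n_pseudo_domains = integer())))
  }
  collapsed <- hits %>%
    dplyr::arrange(.data$gene_id, .data$start) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(run = cumsum(
      !(.data$repeat_type &
          .data$domain == dplyr::lag(.data$domain, default = "\r") &
          dplyr::lag(.data$repeat_type, default = FALSE)))) %>%
    dplyr::group_by(.data$gene_id, .data$run) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"run")
  counts <- dplyr::count(collapsed, .data$gene_id,
                         name = "n_pseudo_domains")
  list(hits = collapsed, counts = counts)
}

#' Compare protein properties between two gene sets
#'
#' Two-sided rank-sum test per property plus the percent difference of
#' foreground vs background means, for properties such as protein length
#' (aa), number of pseudo-domains and number of introns.
#'
#' @param fg,bg Character vectors of gene ids.
#' @param properties Tibble with `gene_id` and one numeric column per
#'   property.
#' @return Tibble with one row per property: `p_value`,
#'   `mean_fg`, `mean_bg`, `percent_difference`.
#' @export
property_tests <- function(fg, bg, properties) {
  prop_cols <- setdiff(names(properties), "gene_id")
  purrr::map(prop_cols, function(pc) {
    x <- properties[[pc]][properties$gene_id %in% fg]
    y <- properties[[pc]][properties$gene_id %in% bg]
    tibble::tibble(
      property = pc,
      p_value = mww_test(x, y),
      mean_fg = mean(x), mean_bg = mean(y),
      percent_difference = 100 * (mean(x) / mean(y) - 1))
  }) %>% dplyr::bind_rows()
}
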