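# Tidiers for the package's result objects.

#' Tidy an IPC pair-type comparison
#'
#' One row per pair type, combining the mean IPC/identity with the
#' Spearman correlation against identity.
#'
#' @param x An `ipc_comparison` from [compare_pair_types()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ipc_comparison <- function(x, ...) {
  dplyr::left_join(x$means, x$spearman, by = "pair_type")
}

#' Glance at an IPC pair-type comparison
#'
#' A one-row summary: per-type mean IPC, the two rank-sum p-values and
#' the agreement fractions by bootstrap support.
#'
#' @inheritParams tidy.ipc_comparison
#' @return A one-row tibble.
#' @export
glance.ipc_comparison <- function(x, ...) {
  wide <- x$means %>%
    dplyr::select("pair_type", "mean_ipc") %>%
    tidyr::pivot_wider(names_from = "pair_type", values_from = "mean_ipc",
                       names_prefix = "mean_ipc_")
  names(wide) <- gsub("-", "_", names(wide))
  p <- stats::setNames(x$mww$p_value,
                       c("p_oo_vs_ocno", "p_ii_vs_icni")[
                         seq_len(nrow(x$mww))])
  dplyr::bind_cols(
    tibble::tibble(label = x$label), wide,
    tibble::as_tibble(as.list(p)),
    dplyr::select(x$agreement, "fraction_high", "fraction_low"))
}

#' Tidy a term-enrichment result
#'
#' @param x An `ipc_enrichment` from [enrich_terms()].
#' @param ... Unused.
#' @return The per-term tibble (already tidy), without the subclass.
#' @export
tidy.ipc_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at a term-enrichment result
#'
#' @inheritParams tidy.ipc_enrichment
#' @return A one-row tibble with term counts and the FDR setting.
#' @export
glance.ipc_enrichment <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    n_significant = sum(x$significant),
    n_enriched = sum(x$significant & x$direction == "enriched"),
    n_depleted = sum(x$significant & x$direction == "depleted"),
    fdr = attr(x, "fdr"))
}
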