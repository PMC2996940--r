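# ggplot2 displays for the result objects.

#' Plot an IPC pair-type comparison
#'
#' `type = "means"` shows the mean IPC per pair type (the headline
#' contrast: o-o vs o-cno and i-i vs i-cni); `type = "bins"` shows the
#' per-bin log2 ratio of mean IPC across identity bins, one panel per
#' contrast, where a ratio above 0 means the ortholog-side type retains
#' more intron positions at matched sequence identity.
#'
#' @param object An `ipc_comparison` from [compare_pair_types()].
#' @param type `"means"` or `"bins"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipc_comparison <- function(object, type = c("means", "bins"),
                                    ...) {
  type <- match.arg(type)
  if (type == "means") {
    df <- dplyr::mutate(object$means, pair_type = factor(
      .data$pair_type, levels = c("o-o", "o-cno", "i-i", "i-cni")))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_type,
                                       y = .data$mean_ipc)) +
        ggplot2::geom_col(fill = "grey35") +
        ggplot2::labs(x = NULL, y = "mean IPC score",
                      title = object$label) +
        ggplot2::theme_minimal())
  }
  if (length(object$bins) == 0L) {
    abort_ipcon("no identity bins available (samples smaller than k)")
  }
  df <- purrr::imap(object$bins, function(b, nm) {
    dplyr::mutate(b$ratios, contrast = paste(b$types, collapse = " / "))
  }) %>% dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::scale_x_continuous(breaks = unique(df$bin)) +
    ggplot2::labs(x = "sequence-identity bin",
                  y = "log2(ratio of mean IPC)", title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot a term-enrichment result
#'
#' Shows the significant terms (or the `n_top` smallest two-sided
#' p-values when nothing is significant) as `-log10(p)` bars, colored by
#' direction.
#'
#' @param object An `ipc_enrichment` from [enrich_terms()].
#' @param n_top Maximum number of terms displayed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipc_enrichment <- function(object, n_top = 20L, ...) {
  df <- tibble::as_tibble(object)
  sel <- if (any(df$significant)) dplyr::filter(df, .data$significant)
  else df
  sel <- dplyr::slice_min(sel, .data$p_two, n = n_top, with_ties = FALSE)
  ggplot2::ggplot(sel, ggplot2::aes(
    x = -log10(pmax(.data$p_two, 1e-300)),
    y = stats::reorder(.data$term, -.data$p_two),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 two-sided p", y = NULL,
                  fill = "direction") +
    ggplot2::theme_minimal()
}
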