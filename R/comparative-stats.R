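# Distribution tests between pair types, identity-controlled binning with
# combined equal-count boundaries, log2 IPC ratios, Spearman correlations
# and the seed-agreement/bootstrap split.

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided rank-sum p-value: exact when the combined sample size is at
#' most 20 and there are no ties, otherwise the tie-corrected normal
#' approximation (no continuity correction).
#'
#' @param xs,ys Numeric samples (non-empty).
#' @return Two-sided p-value.
#' @export
mww_test <- function(xs, ys) {
  xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
  if (length(xs) == 0L || length(ys) == 0L) {
    abort_ipcon("mww_test requires two non-empty samples")
  }
  if (stats::sd(c(xs, ys)) == 0) return(1)  # all values tied
  exact <- (length(xs) + length(ys)) <= 20L &&
    anyDuplicated(c(xs, ys)) == 0L
  suppressWarnings(
    stats::wilcox.test(xs, ys, exact = exact, correct = FALSE)$p.value)
}

# Equal-count bin boundaries of one sample: midpoints between the
# adjacent order statistics at each k-quantile split.
own_bin_boundaries <- function(v, k) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < k) abort_ipcon("sample of size %d cannot fill %d bins", n, k)
  s <- sort(v)
  idx <- floor(seq_len(k - 1L) * n / k)
  idx <- pmax(1L, pmin(idx, n - 1L))
  (s[idx] + s[idx + 1L]) / 2
}

#' Combined equal-count bin boundaries for two pair types
#'
#' Each sample is first split into `k` equal-count bins; boundary `j` of
#' a sample is the midpoint between the adjacent order statistics at the
#' j-th k-quantile split. The combined boundary `j` is the mean of the
#' two samples' boundaries `j`; both samples are then re-assigned by the
#' combined boundaries.
#'
#' @param xs,ys Identity samples of the two pair types (each of size
#'   `>= k`).
#' @param k Number of bins.
#' @return List with `boundaries_x`, `boundaries_y` and `combined`
#'   (each length `k - 1`, ascending).
#' @export
combined_bin_boundaries <- function(xs, ys, k = 10L) {
  bx <- own_bin_boundaries(xs, k)
  by <- own_bin_boundaries(ys, k)
  comb <- (bx + by) / 2
  if (any(diff(comb) <= 0)) {
    warn_ipcon("combined bin boundaries are not strictly ascending (ties in identities)")
  }
  list(boundaries_x = bx, boundaries_y = by, combined = comb)
}

#' Assign values to bins defined by boundaries
#'
#' Intervals are half-open and right-closed: a value exactly on a
#' boundary goes to the lower bin; the top interval is unbounded above.
#'
#' @param values Numeric vector.
#' @param boundaries Ascending boundary values (length `k - 1`).
#' @return Integer bin indices in `1..k`.
#' @export
assign_bins <- function(values, boundaries) {
  findInterval(values, boundaries, left.open = TRUE) + 1L
}

#' Per-bin log2 ratio of mean IPC between two pair types
#'
#' For each bin, the mean IPC (over pairs with defined IPC) of each type
#' is computed and `log2(mean_1 / mean_2)` reported. Bins where either
#' type is empty or either mean is 0 are flagged undefined (`NA` ratio)
#' rather than `±Inf`.
#'
#' @param pairs Tibble with columns `pair_type`, `identity`, `ipc`.
#' @param boundaries Combined boundaries from
#'   [combined_bin_boundaries()].
#' @param type_1,type_2 The two pair-type labels (numerator,
#'   denominator).
#' @return Tibble with one row per bin: counts, per-type means,
#'   `log2_ratio`, `defined`.
#' @export
binned_log2_ratio <- function(pairs, boundaries, type_1 = "o-o",
                              type_2 = "o-cno") {
  k <- length(boundaries) + 1L
  df <- pairs %>%
    dplyr::filter(.data$pair_type %in% c(type_1, type_2),
                  !is.na(.data$ipc)) %>%
    dplyr::mutate(bin = assign_bins(.data$identity, boundaries))
  per <- df %>%
    dplyr::group_by(.data$bin, .data$pair_type) %>%
    dplyr::summarise(mean_ipc = mean(.data$ipc), n = dplyr::n(),
                     .groups = "drop")
  out <- tidyr::expand_grid(bin = seq_len(k),
                            pair_type = c(type_1, type_2)) %>%
    dplyr::left_join(per, by = c("bin", "pair_type")) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    tidyr::pivot_wider(names_from = "pair_type",
                       values_from = c("mean_ipc", "n"))
  m1 <- out[[paste0("mean_ipc_", type_1)]]
  m2 <- out[[paste0("mean_ipc_", type_2)]]
  defined <- !is.na(m1) & !is.na(m2) & m1 > 0 & m2 > 0
  out$log2_ratio <- ifelse(defined, log2(m1 / m2), NA_real_)
  out$defined <- defined
  out
}

#' Spearman correlation between IPC and sequence identity per pair type
#'
#' Average-rank Spearman rho with a p-value from the t-approximation.
#' Types with fewer than 3 defined pairs or constant input are flagged
#' (`defined = FALSE`, `NA` estimates).
#'
#' @param pairs Tibble with `pair_type`, `ipc`, `identity`.
#' @return Tibble with one row per pair type: `rho`, `p_value`, `n`,
#'   `defined`.
#' @export
spearman_by_type <- function(pairs) {
  pairs %>%
    dplyr::filter(!is.na(.data$ipc)) %>%
    dplyr::group_by(.data$pair_type) %>%
    dplyr::summarise(res = list({
      x <- .data$ipc; y <- .data$identity
      if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
        tibble::tibble(rho = NA_real_, p_value = NA_real_,
                       n = length(x), defined = FALSE)
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x, y, method = "spearman", exact = FALSE))
        tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                       n = length(x), defined = TRUE)
      }
    }), .groups = "drop") %>%
    tidyr::unnest("res")
}

#' Agreement between seed assignment and IPC, split by bootstrap support
#'
#' Among multi-clusters with known seed bootstrap values, computes the
#' fraction of consistent clusters (seed pair attains the highest o-o
#' IPC) separately for clusters whose minimum seed bootstrap is at least
#' `threshold` and for the rest. Clusters with unknown bootstrap are
#' excluded and counted.
#'
#' @param summaries Cluster-summary tibble from [score_clusters()].
#' @param threshold Bootstrap split point (percent).
#' @return One-row tibble: `n_high`, `fraction_high`, `n_low`,
#'   `fraction_low`, `n_unknown_bootstrap` (fractions `NA` when a group
#'   is empty).
#' @export
agreement_by_bootstrap <- function(summaries, threshold = 90) {
  multi <- dplyr::filter(summaries, .data$is_multi,
                         !is.na(.data$consistent))
  unknown <- sum(is.na(multi$seed_bootstrap_min))
  known <- dplyr::filter(multi, !is.na(.data$seed_bootstrap_min))
  hi <- dplyr::filter(known, .data$seed_bootstrap_min >= threshold)
  lo <- dplyr::filter(known, .data$seed_bootstrap_min < threshold)
  frac <- function(d) if (nrow(d) == 0L) NA_real_ else mean(d$consistent)
  tibble::tibble(
    n_high = nrow(hi), fraction_high = frac(hi),
    n_low = nrow(lo), fraction_low = frac(lo),
    n_unknown_bootstrap = unknown)
}

#' Partition focal-species genes by cluster-consistency status
#'
#' A gene appearing (across one or more species comparisons) only in
#' consistent multi-clusters is `"only_consistent"`, only in inconsistent
#' ones `"only_inconsistent"`, and in both kinds `"both"`. Genes in the
#' `"both"` class cannot be unambiguously associated with either category
#' and are excluded from downstream enrichment. Genes found only in
#' one-to-one clusters never enter the input and so appear in no class.
#'
#' @param cluster_genes Tibble with columns `gene_id` and `consistent`
#'   (one row per gene per multi-cluster; rows with `NA` consistency are
#'   ignored). Extra columns (e.g. `comparison`, `cluster_id`) are
#'   allowed.
#' @return Tibble `gene_id`, `class`.
#' @export
gene_consistency_sets <- function(cluster_genes) {
  cluster_genes %>%
    dplyr::filter(!is.na(.data$consistent)) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(any_c = any(.data$consistent),
                     any_i = any(!.data$consistent), .groups = "drop") %>%
    dplyr::mutate(class = dplyr::case_when(
      .data$any_c & .data$any_i ~ "both",
      .data$any_c ~ "only_consistent",
      TRUE ~ "only_inconsistent")) %>%
    dplyr::select("gene_id", "class")
}

#' Compare the four pair types of one species comparison
#'
#' Bundles the comparative statistics for one two-species analysis:
#' per-type mean IPC and identity, rank-sum tests (o-o vs o-cno and i-i
#' vs i-cni), identity-controlled binning with combined boundaries and
#' per-bin log2 IPC ratios, Spearman correlations per type, and the
#' agreement-by-bootstrap split. The rank-sum test is applied to
#' per-cluster per-type mean IPC values by default (`mww_mode =
#' "cluster_means"`); `"pairs"` uses the raw per-pair values.
#'
#' @param pairs Per-pair score tibble from [score_clusters()].
#' @param summaries Cluster-summary tibble from [score_clusters()].
#' @param k Number of identity bins.
#' @param mww_mode `"cluster_means"` or `"pairs"`.
#' @param bootstrap_threshold Bootstrap split point (percent).
#' @param label Optional species-pair label carried into the result.
#' @return An object of class `ipc_comparison` with components `means`,
#'   `mww`, `spearman`, `bins`, `agreement`, `label`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
compare_pair_types <- function(pairs, summaries, k = 10L,
                               mww_mode = c("cluster_means", "pairs"),
                               bootstrap_threshold = 90,
                               label = "comparison") {
  mww_mode <- match.arg(mww_mode)
  means <- pairs %>%
    dplyr::filter(!is.na(.data$ipc)) %>%
    dplyr::group_by(.data$pair_type) %>%
    dplyr::summarise(mean_ipc = mean(.data$ipc),
                     mean_identity = mean(.data$identity),
                     n_pairs = dplyr::n(), .groups = "drop")
  mww_sample <- function(t1, t2) {
    if (mww_mode == "cluster_means") {
      key <- function(t) paste0("mean_ipc_", gsub("-", "_", t))
      list(x = stats::na.omit(summaries[[key(t1)]]),
           y = stats::na.omit(summaries[[key(t2)]]))
    } else {
      list(x = pairs$ipc[pairs$pair_type == t1 & !is.na(pairs$ipc)],
           y = pairs$ipc[pairs$pair_type == t2 & !is.na(pairs$ipc)])
    }
  }
  mww_row <- function(t1, t2) {
    s <- mww_sample(t1, t2)
    p <- if (length(s$x) && length(s$y)) mww_test(s$x, s$y) else NA_real_
    tibble::tibble(comparison = sprintf("%s vs %s", t1, t2),
                   n_1 = length(s$x), n_2 = length(s$y), p_value = p)
  }
  mww <- dplyr::bind_rows(mww_row("o-o", "o-cno"), mww_row("i-i", "i-cni"))
  bin_block <- function(t1, t2) {
    sub <- dplyr::filter(pairs, !is.na(.data$ipc))
    xs <- sub$identity[sub$pair_type == t1]
    ys <- sub$identity[sub$pair_type == t2]
    if (length(xs) < k || length(ys) < k) return(NULL)
    b <- combined_bin_boundaries(xs, ys, k)
    ratios <- binned_log2_ratio(sub, b$combined, t1, t2)
    list(boundaries = b, ratios = ratios, types = c(t1, t2))
  }
  structure(list(
    label = label,
    means = means,
    mww = mww,
    spearman = spearman_by_type(pairs),
    bins = purrr::compact(list(ortholog = bin_block("o-o", "o-cno"),
                               inparalog = bin_block("i-i", "i-cni"))),
    agreement = agreement_by_bootstrap(summaries, bootstrap_threshold),
    k = k, mww_mode = mww_mode,
    bootstrap_threshold = bootstrap_threshold
  ), class = "ipc_comparison")
}

#' @export
print.ipc_comparison <- function(x, ...) {
  cat("IPC pair-type comparison:", x$label, "\n\n")
  print(x$means)
  cat("\nRank-sum tests (", x$mww_mode, "):\n", sep = "")
  print(x$mww)
  cat("\nAgreement by bootstrap (threshold ", x$bootstrap_threshold,
      "%):\n", sep = "")
  print(x$agreement)
  invisible(x)
}
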