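# IPC scoring: intron marks are projected through a multiple alignment
# and two sequences share an intron position when the same alignment
# column carries a mark in both. Because a mark lower-cases the codon's
# residue, same-column equality is exactly the same-codon criterion: an
# intron may slide up to 2 nt and still hit the same codon.

#' Project intron marks onto alignment columns
#'
#' Maps each marked residue (0-based index in the ungapped sequence) to
#' the 0-based alignment column holding that residue. Distinct marked
#' residues give distinct columns; two marks on the same residue
#' (different phases) collapse to one marked column, which is the
#' codon-level conservation criterion.
#'
#' @param aligned_sequence Aligned sequence with `-` gap characters.
#' @param marks Marks tibble (`residue_index`, `phase`) or an integer
#'   vector of 0-based residue indices.
#' @return Sorted integer vector of 0-based column indices.
#' @export
project_marks <- function(aligned_sequence, marks) {
  res <- if (is.data.frame(marks)) marked_residues(marks) else sort(unique(as.integer(marks)))
  if (length(res) == 0L) return(integer())
  chars <- strsplit(aligned_sequence, "")[[1]]
  ungapped <- which(chars != "-")
  if (max(res) + 1L > length(ungapped)) {
    abort_ipcon("mark at residue %d beyond ungapped length %d",
                max(res), length(ungapped))
  }
  ungapped[res + 1L] - 1L
}

#' Count shared marked columns
#'
#' @param columns_a,columns_b Integer vectors of marked column indices.
#' @return Number of columns marked in both sequences.
#' @export
count_shared <- function(columns_a, columns_b) {
  length(intersect(columns_a, columns_b))
}

#' Intron position conservation score
#'
#' The default `"fraction"` form is `2 * shared / (n_a + n_b)`: symmetric,
#' bounded in `[0, 1]` and equal to 1 exactly when the two marked-residue
#' sets coincide. The `"jaccard"` alternative
#' `shared / (n_a + n_b - shared)` is available as a configuration
#' switch. A pair where both sequences are intronless
#' (`n_a + n_b == 0`) has no defined score and returns `NA`; a one-sided
#' intronless pair scores 0.
#'
#' @param shared Number of shared intron positions.
#' @param n_a,n_b Intron (marked-residue) counts of the two sequences.
#' @param method `"fraction"` (default) or `"jaccard"`.
#' @return Numeric score in `[0, 1]` or `NA`. Vectorized.
#' @export
ipc_score <- function(shared, n_a, n_b, method = c("fraction", "jaccard")) {
  method <- match.arg(method)
  if (any(shared > pmin(n_a, n_b))) {
    abort_ipcon("shared intron count exceeds min(n_a, n_b)")
  }
  denom <- if (method == "fraction") n_a + n_b else n_a + n_b - shared
  num <- if (method == "fraction") 2 * shared else shared
  out <- ifelse(n_a + n_b == 0, NA_real_, num / denom)
  as.numeric(out)
}

#' Pairwise sequence identity over co-aligned columns
#'
#' Identical residues divided by the number of columns where both
#' sequences are non-gap (case-insensitive); 0 when no column is
#' co-aligned.
#'
#' @param aligned_a,aligned_b Aligned sequences of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort_ipcon("aligned lengths differ (%d vs %d)",
                nchar(aligned_a), nchar(aligned_b))
  }
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  sum(a[both] == b[both]) / sum(both)
}

# Precompute aligned sequence + projected mark columns per spliceform.
prepare_aligned <- function(records, alignment) {
  missing <- setdiff(records$spliceform_id, names(alignment))
  if (length(missing)) {
    abort_ipcon("alignment is missing sequence(s): %s",
                paste(missing, collapse = ", "))
  }
  purrr::pmap(records, function(spliceform_id, marks, ...) {
    aln <- alignment[[spliceform_id]]
    cols <- project_marks(aln, marks)
    chars <- strsplit(toupper(aln), "")[[1]]
    list(id = spliceform_id, aligned = aln, chars = chars,
         nongap = chars != "-", columns = cols, n = length(cols))
  }) %>% stats::setNames(records$spliceform_id)
}

#' Score one gene pair with spliceform maximization
#'
#' Evaluates IPC over every combination of the two genes' spliceforms and
#' keeps the combination with the highest defined IPC (ties broken by
#' higher identity, then lexicographic spliceform ids). When every
#' combination is undefined (all spliceform pairs intronless) the pair's
#' IPC is `NA` and the identity of the identity-best combination is
#' reported.
#'
#' @param records_a,records_b Protein-record tibbles holding the
#'   spliceforms of gene A and gene B (each must appear in `alignment`).
#' @param alignment Named character vector of aligned sequences keyed by
#'   spliceform id.
#' @param method IPC normalization, see [ipc_score()].
#' @return One-row tibble: `spliceform_a`, `spliceform_b`,
#'   `introns_shared`, `introns_a`, `introns_b`, `ipc`, `identity`.
#' @export
score_pair <- function(records_a, records_b, alignment,
                       method = c("fraction", "jaccard")) {
  method <- match.arg(method)
  pa <- prepare_aligned(records_a, alignment)
  pb <- prepare_aligned(records_b, alignment)
  score_pair_prepared(pa, pb, method)
}

score_pair_prepared <- function(pa, pb, method) {
  grid <- expand.grid(sa = names(pa), sb = names(pb),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  ipc <- ident <- numeric(n)
  shared_v <- na_v <- nb_v <- integer(n)
  for (i in seq_len(n)) {
    a <- pa[[grid$sa[[i]]]]; b <- pb[[grid$sb[[i]]]]
    shared <- count_shared(a$columns, b$columns)
    shared_v[[i]] <- shared; na_v[[i]] <- a$n; nb_v[[i]] <- b$n
    ipc[[i]] <- ipc_score(shared, a$n, b$n, method)
    both <- a$nongap & b$nongap
    ident[[i]] <- if (!any(both)) 0 else
      sum(a$chars[both] == b$chars[both]) / sum(both)
  }
  best <- order(-ifelse(is.na(ipc), -Inf, ipc), -ident,
                grid$sa, grid$sb)[[1]]
  tibble::tibble(
    spliceform_a = grid$sa[[best]], spliceform_b = grid$sb[[best]],
    introns_shared = shared_v[[best]], introns_a = na_v[[best]],
    introns_b = nb_v[[best]],
    ipc = ipc[[best]], identity = ident[[best]])
}

#' Score an extended cluster
#'
#' Enumerates and scores the four pair types of one extended cluster:
#' \describe{
#'   \item{o-o}{every cross-species member pair;}
#'   \item{i-i}{every within-species member pair (species with two or
#'     more members);}
#'   \item{o-cno}{for each o-o pair `(a, b)`, the mean IPC and identity
#'     over the defined pairs among `(a, cno(a))` and `(b, cno(b))`;}
#'   \item{i-cni}{analogously from `(a, cni(a))` and `(b, cni(b))`.}
#' }
#' Members are scored with their full spliceform pool (shorter
#' spliceforms re-added); cno/cni partners use their primary spliceform.
#' Pairs with undefined IPC are excluded from means. The summary records
#' the seed pair's IPC, the maximum over all o-o pairs, and for
#' multi-clusters the consistency flag: the cluster is consistent when
#' the seed pair attains the highest IPC of all o-o pairs (ties count as
#' agreement).
#'
#' @param ext_members One cluster's rows of [extend_clusters()] output.
#' @param records Protein-record tibble covering members (all
#'   spliceforms), cnos and cnis.
#' @param alignment Named character vector of aligned sequences for this
#'   cluster.
#' @inheritParams score_pair
#' @return List with `pairs` (per-pair tibble, one row per o-o/i-i pair
#'   and one per averaged o-cno/i-cni value) and `summary` (one-row
#'   cluster summary tibble).
#' @export
score_extended_cluster <- function(ext_members, records, alignment,
                                   method = c("fraction", "jaccard")) {
  method <- match.arg(method)
  cid <- ext_members$cluster_id[[1]]
  member_forms <- function(gene, species) {
    dplyr::filter(records, .data$gene_id == gene, .data$species == species)
  }
  primary_form <- function(gene, species) {
    r <- member_forms(gene, species)
    if ("primary" %in% names(r) && any(r$primary)) r[r$primary, ] else
      r[which.max(r$length), ]
  }
  prep <- new.env(parent = emptyenv())
  prepared <- function(gene, species, full_pool) {
    key <- paste(species, gene, full_pool, sep = "\r")
    if (!is.null(prep[[key]])) return(prep[[key]])
    r <- if (full_pool) member_forms(gene, species) else primary_form(gene, species)
    if (nrow(r) == 0L) {
      abort_ipcon("cluster %s: no protein record for %s (%s)",
                  cid, gene, species)
    }
    p <- prepare_aligned(r, alignment)
    prep[[key]] <- p
    p
  }
  score_genes <- function(ga, sa, full_a, gb, sb, full_b) {
    score_pair_prepared(prepared(ga, sa, full_a), prepared(gb, sb, full_b),
                        method)
  }
  m <- ext_members
  sp <- sort(unique(m$species))
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 64); acc$k <- 0L
  push_row <- function(pair_type, id_a, id_b, is_seed_pair, ipc, identity,
                       shared = NA_integer_, n_a = NA_integer_,
                       n_b = NA_integer_) {
    acc$k <- acc$k + 1L
    if (acc$k > length(acc$rows)) length(acc$rows) <- 2L * length(acc$rows)
    acc$rows[[acc$k]] <- list(pair_type, id_a, id_b, is_seed_pair, ipc,
                              identity, shared, n_a, n_b)
  }

  # cross-species member pairs (o-o) and their attached o-cno values
  a_side <- dplyr::filter(m, .data$species == sp[[1]])
  b_side <- dplyr::filter(m, .data$species == sp[[length(sp)]])
  for (ia in seq_len(nrow(a_side))) for (ib in seq_len(nrow(b_side))) {
    a <- a_side[ia, ]; b <- b_side[ib, ]
    sc <- score_genes(a$member_id, a$species, TRUE,
                      b$member_id, b$species, TRUE)
    push_row("o-o", a$member_id, b$member_id, a$is_seed && b$is_seed,
             sc$ipc, sc$identity, sc$introns_shared, sc$introns_a,
             sc$introns_b)
    cno_vals <- purrr::map(list(a, b), function(mm) {
      if (is.na(mm$cno)) return(NULL)
      other <- setdiff(sp, mm$species)[[1]]
      score_genes(mm$member_id, mm$species, TRUE, mm$cno, other, FALSE)
    })
    def <- purrr::keep(purrr::compact(cno_vals), ~ !is.na(.x$ipc))
    if (length(def)) {
      push_row("o-cno", a$member_id, b$member_id, FALSE,
               mean(purrr::map_dbl(def, "ipc")),
               mean(purrr::map_dbl(def, "identity")))
    }
  }

  # within-species member pairs (i-i) and their attached i-cni values
  for (s in sp) {
    side <- dplyr::filter(m, .data$species == s)
    if (nrow(side) < 2L) next
    combos <- utils::combn(nrow(side), 2L)
    for (r in seq_len(ncol(combos))) {
      a <- side[combos[1L, r], ]; b <- side[combos[2L, r], ]
      sc <- score_genes(a$member_id, s, TRUE, b$member_id, s, TRUE)
      push_row("i-i", a$member_id, b$member_id, FALSE, sc$ipc,
               sc$identity, sc$introns_shared, sc$introns_a, sc$introns_b)
      cni_vals <- purrr::map(list(a, b), function(mm) {
        if (is.na(mm$cni)) return(NULL)
        score_genes(mm$member_id, s, TRUE, mm$cni, s, FALSE)
      })
      def <- purrr::keep(purrr::compact(cni_vals), ~ !is.na(.x$ipc))
      if (length(def)) {
        push_row("i-cni", a$member_id, b$member_id, FALSE,
                 mean(purrr::map_dbl(def, "ipc")),
                 mean(purrr::map_dbl(def, "identity")))
      }
    }
  }

  rows <- acc$rows[seq_len(acc$k)]
  col <- function(i, cast) cast(vapply(rows, function(r) r[[i]],
                                       vector(mode(cast(NA)), 1L)))
  pairs <- tibble::tibble(
    cluster_id = cid,
    pair_type = vapply(rows, function(r) r[[1]], character(1)),
    id_a = vapply(rows, function(r) r[[2]], character(1)),
    id_b = vapply(rows, function(r) r[[3]], character(1)),
    is_seed_pair = vapply(rows, function(r) r[[4]], logical(1)),
    ipc = vapply(rows, function(r) as.numeric(r[[5]]), double(1)),
    identity = vapply(rows, function(r) as.numeric(r[[6]]), double(1)),
    introns_shared = vapply(rows, function(r) as.integer(r[[7]]), integer(1)),
    introns_a = vapply(rows, function(r) as.integer(r[[8]]), integer(1)),
    introns_b = vapply(rows, function(r) as.integer(r[[9]]), integer(1)))
  oo_pairs <- dplyr::filter(pairs, .data$pair_type == "o-o")
  seed_ipc <- oo_pairs$ipc[oo_pairs$is_seed_pair]
  seed_ipc <- if (length(seed_ipc)) seed_ipc[[1]] else NA_real_
  max_oo <- if (all(is.na(oo_pairs$ipc))) NA_real_ else
    max(oo_pairs$ipc, na.rm = TRUE)
  is_multi <- any(!m$is_seed)
  consistent <- if (!is_multi || is.na(max_oo)) NA else
    (!is.na(seed_ipc) && seed_ipc >= max_oo)
  type_means <- pairs %>%
    dplyr::filter(!is.na(.data$ipc)) %>%
    dplyr::group_by(.data$pair_type) %>%
    dplyr::summarise(mean_ipc = mean(.data$ipc),
                     mean_identity = mean(.data$identity),
                     n_pairs = dplyr::n(), .groups = "drop")
  boot <- if ("bootstrap" %in% names(m)) {
    sb <- m$bootstrap[m$is_seed]
    if (length(sb) && !anyNA(sb)) min(sb) else NA_real_
  } else NA_real_
  summary <- tibble::tibble(
    cluster_id = cid, is_multi = is_multi,
    n_members = nrow(m),
    seed_pair_ipc = seed_ipc, max_ortholog_pair_ipc = max_oo,
    consistent = consistent, seed_bootstrap_min = boot)
  for (tt in c("o-o", "o-cno", "i-i", "i-cni")) {
    row <- dplyr::filter(type_means, .data$pair_type == tt)
    key <- gsub("-", "_", tt)
    summary[[paste0("mean_ipc_", key)]] <-
      if (nrow(row)) row$mean_ipc else NA_real_
    summary[[paste0("mean_identity_", key)]] <-
      if (nrow(row)) row$mean_identity else NA_real_
    summary[[paste0("n_", key)]] <- if (nrow(row)) row$n_pairs else 0L
  }
  list(pairs = pairs, summary = summary)
}

#' Score every extended cluster of a comparison
#'
#' @param ext Extended-cluster tibble from [extend_clusters()].
#' @param records Protein-record tibble covering all members, cnos, cnis
#'   and spliceforms.
#' @param alignments Either a named list of per-cluster alignments (named
#'   character vectors keyed by spliceform id) or a directory containing
#'   one FASTA per cluster named `<cluster_id>.fasta`.
#' @inheritParams score_pair
#' @return List with `pairs` (all per-pair scores) and `summaries` (one
#'   row per cluster).
#' @export
score_clusters <- function(ext, records, alignments,
                           method = c("fraction", "jaccard")) {
  method <- match.arg(method)
  if (is.character(alignments) && length(alignments) == 1L) {
    files <- list.files(alignments, pattern = "\\.fasta$",
                        full.names = TRUE)
    alignments <- stats::setNames(lapply(files, read_aligned_fasta),
                                  sub("\\.fasta$", "", basename(files)))
  }
  # spliceform id -> alignment name, for clusters whose ids do not match
  # the alignment names (e.g. clusters rebuilt from a similarity table)
  member_index <- stats::setNames(
    rep(names(alignments), lengths(alignments)),
    unlist(lapply(alignments, names), use.names = FALSE))
  primary_of <- if ("primary" %in% names(records)) {
    dplyr::filter(records, .data$primary)
  } else {
    records
  }
  form_of <- stats::setNames(primary_of$spliceform_id, primary_of$gene_id)
  get_alignment <- function(cid, members) {
    need <- form_of[members[[1]]]
    a <- alignments[[cid]]
    if (!is.null(a) && need %in% names(a)) return(a)
    hit <- member_index[need]
    if (is.na(hit)) abort_ipcon("no alignment found for cluster %s", cid)
    alignments[[hit]]
  }
  res <- ext %>%
    dplyr::group_split(.data$cluster_id) %>%
    purrr::map(function(m) {
      score_extended_cluster(
        m, records, get_alignment(m$cluster_id[[1]], m$member_id), method)
    })
  list(pairs = dplyr::bind_rows(purrr::map(res, "pairs")),
       summaries = dplyr::bind_rows(purrr::map(res, "summary")))
}

#' Read an aligned FASTA as a named vector
#'
#' Headers may be bare spliceform ids or the marked-FASTA convention
#' `species|gene_id|spliceform_id[|organelle]`; in the latter case the
#' spliceform id is used as the name. Case is preserved.
#'
#' @param path FASTA file path (or text containing a newline).
#' @return Named character vector of aligned sequences.
#' @export
read_aligned_fasta <- function(path) {
  lines <- if (length(path) == 1L && !grepl("[\n>]", path)) {
    readLines(path)
  } else {
    unlist(strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  hdr_at <- which(startsWith(lines, ">"))
  if (length(hdr_at) == 0L) abort_ipcon("no FASTA headers found")
  ends <- c(hdr_at[-1] - 1L, length(lines))
  seqs <- purrr::map2_chr(hdr_at, ends, function(h, e) {
    gsub("\\s", "", paste(lines[(h + 1L):e], collapse = ""))
  })
  ids <- purrr::map_chr(hdr_at, function(h) {
    fields <- strsplit(sub("^>", "", lines[[h]]), "|", fixed = TRUE)[[1]]
    if (length(fields) >= 3L) fields[[3]] else fields[[1]]
  })
  stats::setNames(seqs, ids)
}

#' Write a per-cluster aligned FASTA
#'
#' @param alignment Named character vector of aligned sequences.
#' @param path Output file path.
#' @export
write_aligned_fasta <- function(alignment, path) {
  out <- purrr::imap(alignment, ~ c(paste0(">", .y), .x))
  writeLines(unlist(out), path)
  invisible(path)
}
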