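# End-to-end orchestration: extract -> cluster -> extend -> align(hook)
# -> score -> analyze -> enrich, driven by one config, with per-stage
# logging, intermediate TSVs and a machine-readable JSON report.

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_ipc_pipeline()].
#' Either pass the fields directly or read them from a YAML file with
#' [read_pipeline_config()].
#'
#' @param proteins Path to a marked FASTA of proteins (or a flat file if
#'   `dialect` is given).
#' @param similarity Path to the all-vs-all similarity TSV.
#' @param clusters Optional path to a precomputed cluster table TSV
#'   (with seed bootstraps); when absent, clusters are built from the
#'   similarity table.
#' @param alignments Directory with one aligned FASTA per extended
#'   cluster (`<cluster_id>.fasta`).
#' @param go,pfam,clan_map Optional annotation TSV paths.
#' @param out_dir Output directory for intermediates and the report.
#' @param dialect Optional flat-file dialect (`"embl"`/`"genbank"`);
#'   when given, `proteins` is parsed as a flat file.
#' @param ipc_method IPC normalization (see [ipc_score()]).
#' @param bins Number of identity bins.
#' @param bootstrap_threshold Bootstrap split (percent).
#' @param fdr Enrichment false discovery rate.
#' @param max_cluster_size Oversize-cluster threshold (strict `>`).
#' @param mww_mode Rank-sum input, `"cluster_means"` or `"pairs"`.
#' @param aligner Optional external aligner command template containing
#'   `{in}` and `{out}` placeholders, run per cluster when `alignments`
#'   is absent.
#' @param focal_species Species whose annotations drive enrichment;
#'   defaults to the lexicographically first species.
#' @param overlap_cutoff,segment_cutoff Coverage cutoffs.
#' @return Config list of class `ipc_config`.
#' @export
pipeline_config <- function(proteins, similarity, alignments,
                            clusters = NULL, go = NULL, pfam = NULL,
                            clan_map = NULL, out_dir = tempfile("ipcrun"),
                            dialect = NULL,
                            ipc_method = "fraction", bins = 10L,
                            bootstrap_threshold = 90, fdr = 0.01,
                            max_cluster_size = 200L,
                            mww_mode = "cluster_means",
                            aligner = NULL, focal_species = NULL,
                            overlap_cutoff = 0.5, segment_cutoff = 0.25) {
  cfg <- as.list(environment())
  stopifnot(cfg$bins >= 2L, cfg$fdr > 0, cfg$fdr < 1,
            cfg$bootstrap_threshold >= 0, cfg$bootstrap_threshold <= 100)
  structure(cfg, class = "ipc_config")
}

#' @param path YAML file whose keys match [pipeline_config()] arguments;
#'   relative paths are resolved against the YAML file's directory.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("proteins", "similarity", "clusters", "alignments",
                "go", "pfam", "clan_map")) {
    if (!is.null(y[[key]]) && !startsWith(y[[key]], "/")) {
      y[[key]] <- file.path(base, y[[key]])
    }
  }
  do.call(pipeline_config, y)
}

run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort_ipcon("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full IPC pipeline
#'
#' Executes all stages in order, writing intermediate TSVs and a JSON
#' report to `config$out_dir`. Stage progress and tallies (records
#' parsed, clusters built, pairs scored/undefined) are logged as
#' messages; any stage error aborts with the stage name. The run is
#' deterministic given its inputs.
#'
#' @param config An `ipc_config` from [pipeline_config()] (or a YAML
#'   path).
#' @return Invisibly, a list of class `ipc_pipeline` with components
#'   `records`, `clusters`, `extended`, `pairs`, `summaries`,
#'   `comparison`, `enrichment` and `report` (the report is also written
#'   to `out_dir/report.json`).
#' @export
run_ipc_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  for (key in c("proteins", "similarity")) {
    if (!file.exists(cfg[[key]] %||% "")) {
      abort_ipcon("stage 'inputs' failed: missing %s file '%s'",
                  key, cfg[[key]] %||% "<unset>")
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  records <- run_stage("extract", {
    r <- if (is.null(cfg$dialect)) {
      read_marked_fasta(cfg$proteins)
    } else {
      mark_proteins(parse_gene_records(
        paste(readLines(cfg$proteins), collapse = "\n"), cfg$dialect))
    }
    select_spliceforms(r)
  })
  message(sprintf("extract: %d protein records (%d genes)",
                  nrow(records), sum(records$primary)))

  hits <- run_stage("cluster", read_similarity_table(cfg$similarity))
  clusters <- run_stage("cluster", {
    if (!is.null(cfg$clusters)) read_cluster_table(cfg$clusters)
    else build_clusters(hits, cfg$overlap_cutoff, cfg$segment_cutoff)
  })
  if (!"bootstrap" %in% names(clusters)) clusters$bootstrap <- NA_real_
  message(sprintf("cluster: %d clusters (%d members)",
                  dplyr::n_distinct(clusters$cluster_id), nrow(clusters)))

  ext <- run_stage("extend", {
    extend_clusters(clusters, hits, records,
                    cfg$overlap_cutoff, cfg$segment_cutoff)
  })
  write_tsv_quiet(ext, file.path(cfg$out_dir, "extended_clusters.tsv"))
  message(sprintf("extend: %d members with cno, %d with cni",
                  sum(!is.na(ext$cno)), sum(!is.na(ext$cni))))

  alignments <- run_stage("align", {
    if (!is.null(cfg$aligner) &&
        (is.null(cfg$alignments) || !dir.exists(cfg$alignments))) {
      align_with_hook(ext, records, cfg)
    } else {
      if (is.null(cfg$alignments) || !dir.exists(cfg$alignments)) {
        abort_ipcon("alignment directory '%s' not found",
                    cfg$alignments %||% "<unset>")
      }
      cfg$alignments
    }
  })

  scored <- run_stage("score", score_clusters(ext, records, alignments,
                                              cfg$ipc_method))
  write_tsv_quiet(scored$pairs, file.path(cfg$out_dir, "pair_scores.tsv"))
  write_tsv_quiet(scored$summaries,
                  file.path(cfg$out_dir, "cluster_summaries.tsv"))
  message(sprintf("score: %d pair values (%d undefined IPC)",
                  nrow(scored$pairs), sum(is.na(scored$pairs$ipc))))

  comparison <- run_stage("analyze", {
    compare_pair_types(scored$pairs, scored$summaries, k = cfg$bins,
                       mww_mode = cfg$mww_mode,
                       bootstrap_threshold = cfg$bootstrap_threshold,
                       label = paste(sort(unique(clusters$species)),
                                     collapse = "-"))
  })

  enr <- run_stage("enrich", {
    run_enrichment_stage(cfg, records, ext, scored$summaries)
  })

  report <- build_report(cfg, records, clusters, ext, scored, comparison,
                         enr)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  message(sprintf("report written to %s",
                  file.path(cfg$out_dir, "report.json")))
  invisible(structure(
    list(records = records, clusters = clusters, extended = ext,
         pairs = scored$pairs, summaries = scored$summaries,
         comparison = comparison, enrichment = enr, report = report,
         config = cfg),
    class = "ipc_pipeline"))
}

# External aligner hook: writes unaligned per-cluster FASTA and runs the
# command template per cluster. Untested surface unless an aligner is on
# PATH; the packaged workflow consumes precomputed alignments.
align_with_hook <- function(ext, records, cfg) {
  out <- file.path(cfg$out_dir, "alignments")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (cid in unique(ext$cluster_id)) {
    m <- dplyr::filter(ext, .data$cluster_id == cid)
    need <- unique(c(m$member_id, stats::na.omit(m$cno),
                     stats::na.omit(m$cni)))
    r <- dplyr::filter(records, .data$gene_id %in% need)
    fin <- file.path(out, paste0(cid, ".in.fasta"))
    fout <- file.path(out, paste0(cid, ".fasta"))
    write_aligned_fasta(stats::setNames(r$sequence, r$spliceform_id), fin)
    cmd <- gsub("{out}", fout,
                gsub("{in}", fin, cfg$aligner, fixed = TRUE), fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) abort_ipcon("aligner failed for cluster %s", cid)
  }
  out
}

run_enrichment_stage <- function(cfg, records, ext, summaries) {
  if (is.null(cfg$go)) return(NULL)
  focal <- cfg$focal_species %||% sort(unique(ext$species))[[1]]
  oversize <- filter_oversize(ext, cfg$max_cluster_size)
  kept <- oversize$clusters
  cluster_genes <- kept %>%
    dplyr::filter(.data$species == focal) %>%
    dplyr::inner_join(dplyr::select(summaries, "cluster_id", "is_multi",
                                    "consistent"),
                      by = "cluster_id") %>%
    dplyr::filter(.data$is_multi) %>%
    dplyr::transmute(gene_id = .data$member_id, .data$consistent)
  sets <- gene_consistency_sets(cluster_genes)
  fg <- sets$gene_id[sets$class == "only_inconsistent"]
  universe <- sets$gene_id[sets$class %in%
                             c("only_inconsistent", "only_consistent")]
  go_ann <- read_tsv_quiet(cfg$go) %>%
    dplyr::filter(.data$gene_id %in% universe)
  go_res <- NULL; go_edges <- NULL; go_reps <- NULL
  if (length(fg) > 0L && nrow(go_ann) > 0L) {
    go_res <- enrich_terms(fg, universe, go_ann, fdr = cfg$fdr)
    go_edges <- term_association_edges(go_res, fg, universe, go_ann)
    go_reps <- pick_representatives(go_edges,
                                    go_res$term[go_res$significant])
  }
  pfam_res <- NULL; props <- NULL; collapsed <- NULL
  if (!is.null(cfg$pfam)) {
    hits <- read_tsv_quiet(cfg$pfam)
    collapsed <- collapse_repeats(hits)
    dom_ann <- collapsed$hits %>%
      dplyr::transmute(gene_id = .data$gene_id, term = .data$domain) %>%
      dplyr::distinct()
    if (!is.null(cfg$clan_map)) {
      dom_ann <- clan_rollup(dom_ann, read_tsv_quiet(cfg$clan_map))
    }
    dom_ann <- dplyr::filter(dom_ann, .data$gene_id %in% universe)
    if (length(fg) > 0L && nrow(dom_ann) > 0L) {
      pfam_res <- enrich_terms(fg, universe, dom_ann, fdr = cfg$fdr)
    }
    prim <- records %>%
      dplyr::filter(.data$primary, .data$gene_id %in% universe)
    props <- tibble::tibble(
      gene_id = prim$gene_id,
      length_aa = prim$length,
      n_introns = purrr::map_int(prim$marks,
                                 ~ length(marked_residues(.x)))) %>%
      dplyr::left_join(collapsed$counts, by = "gene_id") %>%
      dplyr::mutate(n_pseudo_domains = dplyr::coalesce(
        .data$n_pseudo_domains, 0L))
    bg <- setdiff(universe, fg)
    props <- if (length(fg) && length(bg)) property_tests(fg, bg, props)
    else NULL
  }
  list(sets = sets, oversize_removed = oversize$removed,
       go = go_res, go_edges = go_edges, go_representatives = go_reps,
       pfam = pfam_res, properties = props, focal_species = focal)
}

round_num <- function(x, digits = 6) {
  if (is.numeric(x)) round(x, digits) else x
}

tbl_for_report <- function(x) {
  if (is.null(x)) return(NULL)
  df <- as.data.frame(dplyr::mutate(dplyr::as_tibble(x),
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round_num(.x))))
  df[purrr::map_lgl(df, ~ !is.list(.x))]
}

build_report <- function(cfg, records, clusters, ext, scored, comparison,
                         enr) {
  counts <- list(
    n_protein_records = nrow(records),
    n_genes = sum(records$primary),
    n_clusters = dplyr::n_distinct(clusters$cluster_id),
    n_clusters_scored = nrow(scored$summaries),
    n_multi_clusters = sum(scored$summaries$is_multi),
    n_members_with_cno = sum(!is.na(ext$cno)),
    n_members_with_cni = sum(!is.na(ext$cni)),
    n_pair_values = nrow(scored$pairs),
    n_pairs_undefined = sum(is.na(scored$pairs$ipc)))
  bins <- purrr::map(comparison$bins, function(b) {
    list(types = b$types,
         combined_boundaries = round_num(b$boundaries$combined),
         ratios = tbl_for_report(b$ratios))
  })
  enrichment <- if (is.null(enr)) NULL else list(
    focal_species = enr$focal_species,
    set_sizes = as.list(table(enr$sets$class)),
    oversize_removed = tbl_for_report(enr$oversize_removed),
    go_significant = if (is.null(enr$go)) NULL else
      tbl_for_report(dplyr::filter(enr$go, .data$significant)),
    go_representatives = if (is.null(enr$go_representatives)) NULL else
      tbl_for_report(dplyr::select(enr$go_representatives,
                                   "representative", "n_links")),
    pfam_significant = if (is.null(enr$pfam)) NULL else
      tbl_for_report(dplyr::filter(enr$pfam, .data$significant)),
    property_tests = tbl_for_report(enr$properties))
  list(
    label = comparison$label,
    parameters = list(ipc_method = cfg$ipc_method, bins = cfg$bins,
                      bootstrap_threshold = cfg$bootstrap_threshold,
                      fdr = cfg$fdr, max_cluster_size = cfg$max_cluster_size,
                      mww_mode = cfg$mww_mode,
                      overlap_cutoff = cfg$overlap_cutoff,
                      segment_cutoff = cfg$segment_cutoff),
    counts = counts,
    pair_type_means = tbl_for_report(comparison$means),
    mww_tests = tbl_for_report(comparison$mww),
    spearman = tbl_for_report(comparison$spearman),
    bins = bins,
    agreement_by_bootstrap = tbl_for_report(comparison$agreement),
    enrichment = enrichment)
}

#' @export
print.ipc_pipeline <- function(x, ...) {
  cat("IPC pipeline run:", x$report$label, "\n")
  cat(sprintf(" %d clusters scored, %d pair values\n",
              x$report$counts$n_clusters_scored,
              x$report$counts$n_pair_values))
  print(x$comparison)
  invisible(x)
}
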