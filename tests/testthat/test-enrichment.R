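test_that("oversize clusters are removed by a strict threshold", {
  cl <- tibble::tibble(
    cluster_id = c(rep("huge", 705), rep("big", 398), rep("edge", 200),
                   rep("small", 3)),
    member_id = sprintf("g%d", 1:1306))
  expect_warning(out <- filter_oversize(cl, max_genes = 200), "oversize")
  expect_setequal(out$removed$cluster_id, c("huge", "big"))
  expect_setequal(unique(out$clusters$cluster_id), c("edge", "small"))
})

test_that("hypergeometric tails match direct combinatorial summation", {
  ann <- tibble::tibble(gene_id = sprintf("g%d", 1:5), term = "T1")
  uni <- sprintf("g%d", 1:20)
  r <- hypergeom_term_test("T1", fg = sprintf("g%d", 1:10), uni, ann)
  want <- oracle_hyper_tails(5, 5, 20, 10)
  expect_equal(r$p_enriched, want$upper, tolerance = 1e-12)
  expect_equal(r$p_depleted, want$lower, tolerance = 1e-12)
  # fg = universe: upper tail is 1 for any annotated term
  r2 <- hypergeom_term_test("T1", uni, uni, ann)
  expect_equal(r2$p_enriched, 1)
  # fg_count 0: lower tail is the closed form C(N-K, n) / C(N, n)
  r3 <- hypergeom_term_test("T1", sprintf("g%d", 11:16), uni, ann)
  expect_equal(r3$p_depleted, choose(15, 6) / choose(20, 6),
               tolerance = 1e-12)
  expect_error(hypergeom_term_test("T9", uni[1:3], uni, ann),
               "annotates no gene")
  set.seed(41)
  for (i in 1:60) {
    N <- sample(10:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    genes <- sprintf("x%d", 1:N)
    a <- tibble::tibble(gene_id = genes[1:K], term = "T")
    fg <- sample(genes, n)
    got <- hypergeom_term_test("T", fg, genes, a)
    want <- oracle_hyper_tails(got$fg_count, K, N, n)
    expect_equal(got$p_enriched, want$upper, tolerance = 1e-10)
    expect_equal(got$p_depleted, want$lower, tolerance = 1e-10)
  }
})

test_that("BH step-up matches the direct computation", {
  expect_equal(bh_significant(c(0.001, 0.02, 0.03, 0.5), 0.01),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(bh_significant(rep(1, 5), 0.01), rep(FALSE, 5))
  expect_equal(bh_significant(rep(0, 5), 0.01), rep(TRUE, 5))
  set.seed(42)
  for (i in 1:30) {
    p <- stats::runif(sample(3:40, 1))^sample(1:3, 1)
    fdr <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(bh_significant(p, fdr), oracle_bh(p, fdr))
  }
})

test_that("terms with identical gene sets are mutually associated", {
  genes <- sprintf("g%d", 1:60)
  fg <- genes[1:20]
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes[1:18], term = "A"),
    tibble::tibble(gene_id = genes[1:18], term = "B"),
    tibble::tibble(gene_id = genes[c(1:12, 40:52)], term = "C"),
    tibble::tibble(gene_id = genes, term = "BG"))
  res <- enrich_terms(fg, genes, ann, fdr = 0.05)
  sig <- res$term[res$significant]
  expect_true(all(c("A", "B") %in% sig))
  edges <- term_association_edges(res, fg, genes, ann)
  expect_true(any(edges$from == "A" & edges$to == "B"))
  expect_true(any(edges$from == "B" & edges$to == "A"))
})

test_that("independently strong terms on disjoint gene sets form no edge", {
  genes <- sprintf("g%d", 1:80)
  fg <- genes[1:30]
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes[1:15], term = "A"),
    tibble::tibble(gene_id = genes[16:30], term = "B"),
    tibble::tibble(gene_id = genes, term = "BG"))
  res <- enrich_terms(fg, genes, ann, fdr = 0.05)
  expect_true(all(c("A", "B") %in% res$term[res$significant]))
  edges <- term_association_edges(res, fg, genes, ann)
  expect_false(any(edges$from == "A" & edges$to == "B"))
  expect_false(any(edges$from == "B" & edges$to == "A"))
})

test_that("association edges equal a naive per-exclusion recompute", {
  set.seed(43)
  for (i in 1:5) {
    genes <- sprintf("g%d", 1:70)
    fg <- genes[1:25]
    ann <- dplyr::bind_rows(lapply(sprintf("T%d", 1:5), function(tm) {
      core <- sample(genes[1:25], sample(8:16, 1))
      tail <- sample(genes[26:70], sample(0:6, 1))
      tibble::tibble(gene_id = c(core, tail), term = tm)
    }), tibble::tibble(gene_id = genes, term = "BG"))
    res <- enrich_terms(fg, genes, ann, fdr = 0.05)
    got <- term_association_edges(res, fg, genes, ann)
    want <- oracle_association_edges(res$term[res$significant], fg, genes,
                                     ann, 0.05)
    key <- function(d) sort(paste(d$from, d$to))
    expect_equal(key(got), key(want))
  }
})

test_that("representative selection is greedy by degree with id tie-breaks", {
  star <- tibble::tibble(from = "H", to = sprintf("L%d", 1:5))
  r <- pick_representatives(star)
  expect_equal(r$representative, "H")
  expect_equal(r$members[[1]], sort(sprintf("L%d", 1:5)))

  plus <- dplyr::bind_rows(star, tibble::tibble(from = "P1", to = "P2"))
  r2 <- pick_representatives(plus)
  expect_equal(r2$representative, c("H", "P1"))  # P1 < P2 tie-break

  iso <- pick_representatives(star, nodes = c("H", sprintf("L%d", 1:5), "Z"))
  expect_true("Z" %in% iso$representative)

  set.seed(44)
  for (i in 1:20) {
    nodes <- sprintf("n%02d", 1:12)
    m <- sample(5:20, 1)
    edges <- tibble::tibble(from = sample(nodes, m, replace = TRUE),
                            to = sample(nodes, m, replace = TRUE))
    edges <- dplyr::filter(edges, .data$from != .data$to)
    got <- pick_representatives(edges, nodes)
    want <- oracle_representatives(edges, nodes)
    expect_equal(got$representative, want$representatives)
    # groups partition the node set
    all_members <- c(got$representative, unlist(got$members))
    expect_setequal(all_members, nodes)
    expect_equal(anyDuplicated(all_members), 0L)
  }
})

test_that("clan rollup replaces mapped domains and deduplicates", {
  ann <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g3"),
                        term = c("PF00069", "PF99999", "PF00001", "PF00002"))
  cm <- tibble::tibble(domain = c("PF00069", "PF00001", "PF00002"),
                       clan = c("CL0016", "CL0023", "CL0023"))
  out <- clan_rollup(ann, cm)
  expect_equal(out$term[out$gene_id == "g1"], "CL0016")
  expect_equal(out$term[out$gene_id == "g2"], "PF99999")
  expect_equal(out$term[out$gene_id == "g3"], "CL0023")  # deduplicated
})

test_that("consecutive repeat runs collapse to one pseudo-domain", {
  hits <- tibble::tibble(
    gene_id = "g1", domain = c("A", "R", "R", "R", "B"),
    start = 1:5 * 10L, repeat_type = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  out <- collapse_repeats(hits)
  expect_equal(out$hits$domain, c("A", "R", "B"))
  expect_equal(out$counts$n_pseudo_domains, 3L)
  split_run <- tibble::tibble(
    gene_id = "g1", domain = c("R", "A", "R"), start = 1:3 * 10L,
    repeat_type = c(TRUE, FALSE, TRUE))
  out2 <- collapse_repeats(split_run)
  expect_equal(out2$hits$domain, c("R", "A", "R"))
  empty <- collapse_repeats(hits[0, ])
  expect_equal(nrow(empty$hits), 0L)
})

test_that("property comparisons report rank-sum p and percent differences", {
  props <- tibble::tibble(gene_id = sprintf("g%d", 1:20),
                          length_aa = c(rep(125, 10), rep(100, 10)))
  same <- property_tests(sprintf("g%d", 1:10), sprintf("g%d", 1:10), props)
  expect_equal(same$p_value, 1)
  expect_equal(same$percent_difference, 0)
  diff <- property_tests(sprintf("g%d", 1:10), sprintf("g%d", 11:20), props)
  expect_equal(diff$percent_difference, 25)
  set.seed(45)
  p2 <- tibble::tibble(gene_id = sprintf("g%d", 1:30),
                       v = stats::rnorm(30))
  fg <- sprintf("g%d", 1:12); bg <- sprintf("g%d", 13:30)
  got <- property_tests(fg, bg, p2)
  expect_equal(got$p_value, mww_test(p2$v[1:12], p2$v[13:30]))
})

test_that("a planted 5x term is recovered at FDR 1%", {
  set.seed(46)
  sim <- simulate_annotations(n_fg = 200, n_bg = 800, fold = 5,
                              base_rate = 0.05)
  res <- enrich_terms(sim$fg, sim$universe, sim$annotations, fdr = 0.01)
  expect_true(res$significant[res$term == "GO:PLANTED"])
  expect_equal(res$direction[res$term == "GO:PLANTED"], "enriched")
})
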