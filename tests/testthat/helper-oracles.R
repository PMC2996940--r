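# Independent brute-force oracles used to validate the implementation.
# Each is a deliberately naive restatement of the rule being tested and
# shares no code with the package internals.

# Exhaustive mutual-argmax seed scan over a similarity tibble.
oracle_seed_pairs <- function(hits, overlap = 0.5, segment = 0.25) {
  ok <- hits[hits$qcov >= overlap & hits$segcov >= segment &
               hits$qspecies != hits$sspecies, , drop = FALSE]
  best_of <- function(q) {
    h <- ok[ok$query == q, , drop = FALSE]
    if (nrow(h) == 0L) return(NA_character_)
    h <- h[order(-h$score, h$subject), , drop = FALSE]
    h$subject[[1]]
  }
  sp <- sort(unique(c(ok$qspecies, ok$sspecies)))
  a_ids <- sort(unique(ok$query[ok$qspecies == sp[[1]]]))
  out <- list()
  for (a in a_ids) {
    b <- best_of(a)
    if (!is.na(b) && identical(best_of(b), a)) {
      sab <- max(ok$score[ok$query == a & ok$subject == b])
      sba <- max(ok$score[ok$query == b & ok$subject == a])
      out[[length(out) + 1L]] <-
        data.frame(id_a = a, id_b = b, S = (sab + sba) / 2)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      S = double()))
  }
  do.call(rbind, out)
}

# Naive inparalog threshold scan: x joins iff score(x -> seed) >= S.
oracle_inparalog_members <- function(hits, species, seed_id, S,
                                     overlap = 0.5, segment = 0.25) {
  ok <- hits[hits$qcov >= overlap & hits$segcov >= segment, , drop = FALSE]
  ws <- ok[ok$qspecies == species & ok$sspecies == species &
             ok$subject == seed_id & ok$query != seed_id, , drop = FALSE]
  if (nrow(ws) == 0L) return(character())
  sims <- tapply(ws$score, ws$query, max)
  sort(names(sims)[sims >= S])
}

# Exhaustive filtered-argmax for cno/cni.
oracle_closest_nonmember <- function(hits, m, same_species, members,
                                     overlap = 0.5, segment = 0.25) {
  ok <- hits[hits$qcov >= overlap & hits$segcov >= segment &
               hits$query == m & hits$subject != m &
               !(hits$subject %in% members), , drop = FALSE]
  msp <- unique(hits$qspecies[hits$query == m])[[1]]
  ok <- if (same_species) ok[ok$sspecies == msp, , drop = FALSE]
  else ok[ok$sspecies != msp, , drop = FALSE]
  if (nrow(ok) == 0L) return(NA_character_)
  ok <- ok[order(-ok$score, ok$subject), , drop = FALSE]
  ok$subject[[1]]
}

# Random two-species similarity table on n_a x n_b genes (plus
# within-species and self hits), for oracle-equivalence sweeps.
random_hit_table <- function(n_a, n_b, p_fail_cov = 0.15) {
  ids_a <- sprintf("a%d", seq_len(n_a))
  ids_b <- sprintf("b%d", seq_len(n_b))
  all_ids <- c(ids_a, ids_b)
  sp <- c(rep("spA", n_a), rep("spB", n_b))
  grid <- expand.grid(qi = seq_along(all_ids), si = seq_along(all_ids))
  fail <- stats::runif(nrow(grid)) < p_fail_cov
  data.frame(
    query = all_ids[grid$qi], subject = all_ids[grid$si],
    qspecies = sp[grid$qi], sspecies = sp[grid$si],
    score = round(stats::runif(nrow(grid), 50, 500), 1),
    qcov = ifelse(fail, stats::runif(nrow(grid), 0, 0.49), 1),
    segcov = 1, stringsAsFactors = FALSE)
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n1 + n2, n1) group assignments.
oracle_mww_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- rank(c(x, y))
  w_obs <- sum(pooled[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(i) sum(pooled[i]))
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Hypergeometric tails by direct combinatorial summation.
oracle_hyper_tails <- function(x, K, N, n) {
  support <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  list(upper = sum(pmf[support >= x]), lower = sum(pmf[support <= x]))
}

# BH step-up by direct computation of the largest admissible rank.
oracle_bh <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * fdr / m)
  sig <- logical(m)
  if (length(k) > 0L) sig[o[seq_len(max(k))]] <- TRUE
  sig
}

# Spearman rho via explicit average-rank transform + Pearson, p via t.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# Independent step-by-step greedy representative simulation.
oracle_representatives <- function(edges, nodes) {
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  nb <- function(v, pool) {
    sort(intersect(unique(c(edges$to[edges$from == v],
                            edges$from[edges$to == v])), pool))
  }
  reps <- character(); groups <- list()
  pool <- nodes
  while (length(pool)) {
    degs <- vapply(pool, function(v) length(nb(v, pool)), integer(1))
    pick <- pool[order(-degs, pool)][[1]]
    reps <- c(reps, pick)
    groups[[pick]] <- nb(pick, pool)
    pool <- setdiff(pool, c(pick, groups[[pick]]))
  }
  list(representatives = reps, groups = groups)
}

# Simple enrichment oracle (direct summation + manual step-up) used to
# re-derive association edges naively.
oracle_enrich_sig <- function(fg, universe, annotations, fdr) {
  terms <- sort(unique(annotations$term[annotations$gene_id %in% universe]))
  p2 <- vapply(terms, function(tm) {
    genes <- unique(annotations$gene_id[annotations$term == tm &
                                          annotations$gene_id %in% universe])
    tails <- oracle_hyper_tails(sum(fg %in% genes), length(genes),
                                length(universe), length(fg))
    min(1, 2 * min(tails$upper, tails$lower))
  }, double(1))
  terms[oracle_bh(p2, fdr)]
}

oracle_association_edges <- function(sig, fg, universe, annotations, fdr) {
  out <- list()
  for (a in sig) {
    a_genes <- unique(annotations$gene_id[annotations$term == a])
    uni2 <- setdiff(universe, a_genes)
    fg2 <- intersect(fg, uni2)
    ann2 <- annotations[annotations$gene_id %in% uni2, , drop = FALSE]
    still <- if (length(fg2) && nrow(ann2)) {
      oracle_enrich_sig(fg2, uni2, ann2, fdr)
    } else character()
    for (b in setdiff(setdiff(sig, a), still)) {
      out[[length(out) + 1L]] <- data.frame(from = a, to = b)
    }
  }
  if (length(out) == 0L) return(data.frame(from = character(),
                                           to = character()))
  do.call(rbind, out)
}
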