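# Independent straight-line oracles used to pin expected values. These are
# deliberately written as direct transcriptions of the definitions, sharing
# no code with the package internals they check.

# Trim-and-weight scale factor for one sample vs a reference, written out
# step by step with order() indexing (the package uses rank-based keeps).
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, abs_trim = 0.05) {
  both <- obs > 0 & ref > 0
  o <- obs[both]; r <- ref[both]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- 1 / ((n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r))
  n <- length(M)
  keep_M <- rep(FALSE, n)
  keep_M[order(M)[(floor(n * logratio_trim) + 1):(n - floor(n * logratio_trim))]] <- TRUE
  keep_A <- rep(FALSE, n)
  keep_A[order(A)[(floor(n * abs_trim) + 1):(n - floor(n * abs_trim))]] <- TRUE
  keep <- keep_M & keep_A
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(p[o][i:n] * n / (i:n)))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Four-predicate divergence evaluator on one gene's (lfc, fdr) triplets.
oracle_divergence <- function(lfc12, fdr12, lfc24, fdr24, lfcut, fdrut,
                              lfc_thr = 1, fdr_thr = 0.01) {
  c1 <- abs(lfcut) > lfc_thr && fdrut < fdr_thr
  c2 <- !(abs(lfc12) > lfc_thr && fdr12 < fdr_thr)
  c3 <- abs(lfc24) < abs(lfcut)
  c4 <- sign(lfc24) == sign(lfcut) && sign(lfc24) != 0
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, passes = c1 && c2 && c3 && c4)
}

# Hypergeometric upper tail including k, by combinatorial summation.
oracle_hyper_upper <- function(k, N, K, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# GSEA running sum walked gene by gene.
oracle_gsea_es <- function(scores, hit, p = 1) {
  n <- length(scores)
  w <- abs(scores)^p
  denom <- sum(w[hit])
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) w[i] / denom else -1 / (n - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# Naive complete-linkage agglomeration returning the cophenetic matrix:
# repeatedly merge the two clusters with the smallest maximum pairwise
# distance.
oracle_complete_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    a <- clusters[[best[2]]]; b <- clusters[[best[3]]]
    coph[a, b] <- best[1]; coph[b, a] <- best[1]
    clusters[[best[2]]] <- c(a, b)
    clusters[[best[3]]] <- NULL
  }
  coph
}

# Equal-effective-library factor table so pooled counts equal raw counts in
# exact_test (lets tests feed exact pooled totals).
unit_factors <- function(samples, lib = 1e6) {
  tibble::tibble(sample = samples, lib_size = lib, tmm_factor = 1,
                 effective_lib_size = lib)
}

# Tiny DE-table constructor for filter tests.
de_table <- function(gene, lfc, fdr, contrast = "AO vs NM") {
  tibble::tibble(gene = gene, log2fc = lfc, pvalue = fdr, fdr = fdr,
                 significant = abs(lfc) > 1 & fdr < 0.01,
                 contrast = contrast)
}
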