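#' Read and write GMT gene-set files
#'
#' One set per line: term id, description, then member genes,
#' tab-delimited.
#'
#' @param path File path.
#' @param gene_sets Tibble as returned by `read_gmt()` (`term`,
#'   `description`, list-column `genes`).
#' @return `read_gmt()`: tibble with `term`, `description` and list-column
#'   `genes`; `write_gmt()`: the input, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop("GMT line ", bad[1], " has fewer than 3 fields", call. = FALSE)
  }
  tibble::tibble(term = vapply(parts, `[`, "", 1),
                 description = vapply(parts, `[`, "", 2),
                 genes = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(c(gene_sets$term[i], gene_sets$description[i],
            gene_sets$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(gene_sets)
}

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the study set hits the term more often than
#' expected by sampling without replacement from the background of all
#' annotated genes: with `N` background genes, `K` of them in the term,
#' `n` study genes and `k` hits, `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` (upper tail including the observed
#' count), then Benjamini-Hochberg across terms.
#'
#' Term memberships are intersected with the background before counting;
#' terms with no background member are skipped with a message. Study genes
#' must all be in the background.
#'
#' @param study_genes Character vector, the gene list to test.
#' @param gene_sets Tibble from [read_gmt()] or a named list of gene id
#'   vectors.
#' @param background_genes Character vector: all annotated genes.
#' @return Tibble sorted by p: `term`, `description`, `k`, `n`, `K`, `N`,
#'   `pvalue`, `fdr`.
#' @export
#' @examples
#' sets <- list(T1 = paste0("g", 1:5))
#' hypergeometric_enrichment(paste0("g", 1:4), sets, paste0("g", 1:10))
hypergeometric_enrichment <- function(study_genes, gene_sets,
                                      background_genes) {
  background <- unique(background_genes)
  study <- unique(study_genes)
  stray <- setdiff(study, background)
  if (length(stray)) {
    stop("study genes absent from background: ",
         paste(head(stray, 5), collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(gene_sets)) {
    sets <- setNames(gene_sets$genes, gene_sets$term)
    desc <- setNames(gene_sets$description, gene_sets$term)
  } else {
    sets <- gene_sets
    desc <- setNames(rep(NA_character_, length(sets)), names(sets))
  }
  N <- length(background)
  n <- length(study)
  rows <- purrr::map_dfr(names(sets), function(term) {
    members <- intersect(unique(sets[[term]]), background)
    K <- length(members)
    if (K == 0) return(tibble::tibble())
    k <- length(intersect(study, members))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = term, description = unname(desc[term]),
                   k = k, n = n, K = K, N = N, pvalue = p)
  })
  skipped <- length(sets) - nrow(rows)
  if (skipped > 0) {
    message(skipped, " term(s) with no background member skipped")
  }
  if (!nrow(rows)) return(dplyr::mutate(rows, fdr = numeric(0)))
  rows$fdr <- bh_adjust(rows$pvalue)
  dplyr::arrange(rows, .data$pvalue)
}

#' Preranked gene-set enrichment (weighted running-sum)
#'
#' Walks down the score-ranked gene list accumulating
#' `|score|^weight_exponent / sum_hits |score|^weight_exponent` at each
#' gene-set member and `-1/(N - N_hits)` at each non-member; the enrichment
#' score (ES) is the running sum's signed extremum of maximal absolute
#' value, bounded in `[-1, 1]`. The permutation p-value shuffles gene
#' labels `n_perm` times and compares same-sign extrema.
#'
#' @param ranked Tibble with `gene` and `score`, or a named numeric vector;
#'   unique genes, sorted by descending score (sorted internally if not).
#' @param gene_set Character vector of member genes; must overlap the list.
#' @param weight_exponent Exponent on `|score|` for hit increments
#'   (0 = unweighted Kolmogorov-Smirnov; default 1).
#' @param n_perm Number of gene-label permutations (0 skips the p-value).
#' @param seed Optional seed for the permutations.
#' @return Object of class `llr_gsea`: list with `es`, `pvalue`,
#'   `running_sum` tibble (`position`, `gene`, `score`, `hit`,
#'   `running_sum`), `leading_edge`, `n_perm`.
#' @export
#' @examples
#' ranked <- tibble::tibble(gene = c("a", "b", "c"), score = c(3, 2, 1))
#' gsea_preranked(ranked, "a", weight_exponent = 0, n_perm = 0)$es
gsea_preranked <- function(ranked, gene_set, weight_exponent = 1,
                           n_perm = 1000, seed = NULL) {
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- tibble::tibble(gene = names(ranked), score = unname(ranked))
  }
  if (anyDuplicated(ranked$gene)) {
    stop("ranked list contains duplicate genes", call. = FALSE)
  }
  ord <- order(ranked$score, decreasing = TRUE)
  ranked <- ranked[ord, ]
  hits <- ranked$gene %in% gene_set
  if (!any(hits)) stop("gene set does not overlap the ranked list", call. = FALSE)
  if (all(hits)) stop("gene set covers the whole ranked list", call. = FALSE)
  if (weight_exponent > 0 && all(ranked$score == 0)) {
    stop("all-zero scores cannot be weighted (weight_exponent > 0)",
         call. = FALSE)
  }
  n <- nrow(ranked)
  w <- abs(ranked$score)^weight_exponent

  es_from_hits <- function(hit) {
    inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - sum(hit)))
    run <- cumsum(inc)
    i <- which.max(abs(run))
    list(es = run[i], run = run, i = i)
  }
  obs <- es_from_hits(hits)

  pos <- seq_len(n)
  leading <- if (obs$es >= 0) {
    ranked$gene[hits & pos <= obs$i]
  } else {
    ranked$gene[hits & pos >= obs$i]
  }

  pvalue <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    nh <- sum(hits)
    perm_es <- vapply(seq_len(n_perm), function(b) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      es_from_hits(h)$es
    }, numeric(1))
    pvalue <- if (obs$es >= 0) {
      (1 + sum(perm_es >= obs$es)) / (n_perm + 1)
    } else {
      (1 + sum(perm_es <= obs$es)) / (n_perm + 1)
    }
  }

  structure(list(
    es = obs$es, pvalue = pvalue, n_perm = n_perm,
    leading_edge = leading,
    running_sum = tibble::tibble(position = pos, gene = ranked$gene,
                                 score = ranked$score, hit = hits,
                                 running_sum = obs$run),
    weight_exponent = weight_exponent
  ), class = "llr_gsea")
}

#' @export
print.llr_gsea <- function(x, ...) {
  cat("GSEA: ES = ", format(x$es, digits = 4),
      if (!is.na(x$pvalue)) paste0(", permutation p = ",
                                   format(x$pvalue, digits = 4),
                                   " (", x$n_perm, " perms)"),
      ", leading edge ", length(x$leading_edge), " genes\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.llr_gsea <- function(x, ...) x$running_sum

#' @exportS3Method generics::glance
glance.llr_gsea <- function(x, ...) {
  tibble::tibble(es = x$es, pvalue = x$pvalue, n_perm = x$n_perm,
                 n_leading_edge = length(x$leading_edge),
                 weight_exponent = x$weight_exponent)
}
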