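#' TMM scale factors (trimmed mean of M-values)
#'
#' Between-sample scale factors for count data by the trimmed mean of
#' M-values: for each sample against a reference, per-gene log ratios
#' `M = log2((y_s/N_s)/(y_r/N_r))` and average abundances
#' `A = (log2(y_s/N_s) + log2(y_r/N_r))/2` are formed over genes expressed
#' in both samples, the tails of M (`logratio_trim` each side) and of A
#' (`abs_trim` each side) are discarded, and the factor is two to the
#' weighted mean of the surviving M, with inverse asymptotic-variance
#' weights `1/((N_s - y_s)/(N_s y_s) + (N_r - y_r)/(N_r y_r))`. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Counts tibble (`gene` column + one column per sample) or a
#'   numeric matrix with gene rownames.
#' @param ref_sample Reference sample id. Default: the sample whose
#'   75th-percentile count fraction is closest to the mean across samples.
#' @param logratio_trim Fraction of the M distribution trimmed from each
#'   tail (default 0.3).
#' @param abs_trim Fraction of the A distribution trimmed from each tail
#'   (default 0.05).
#'
#' @return A tibble with `sample`, `lib_size`, `tmm_factor` and
#'   `effective_lib_size` (= lib_size * factor).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, seed = 1))
#' tmm_factors(sim$counts)
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, abs_trim = 0.05) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  if (ncol(m) < 2) stop("need at least two samples", call. = FALSE)
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[lib == 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(ref_sample)) {
    f75 <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
    ref_sample <- colnames(m)[which.min(abs(f75 - mean(f75)))]
  }
  if (!ref_sample %in% colnames(m)) {
    stop("ref_sample '", ref_sample, "' not found", call. = FALSE)
  }
  f <- vapply(colnames(m), function(s) {
    tmm_pair(m[, s], m[, ref_sample], lib[s], lib[ref_sample],
             logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample = colnames(m), lib_size = unname(lib),
                 tmm_factor = unname(f),
                 effective_lib_size = unname(lib * f))
}

# One sample against the reference; both as raw count vectors.
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep0 <- obs > 0 & ref > 0
  if (!any(keep0)) {
    warning("no genes expressed in both sample and reference; factor set to 1")
    return(1)
  }
  o <- obs[keep0]; r <- ref[keep0]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  fin <- is.finite(M) & is.finite(A) & is.finite(v)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (!length(M)) {
    warning("no usable genes after filtering; factor set to 1")
    return(1)
  }
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1;      hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) {
    warning("no genes survive trimming; factor set to 1")
    return(1)
  }
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Transcripts per million from counts and gene lengths
#'
#' Length-normalized abundance: per sample, `rate = count / length` on
#' effective-library-scaled counts, then rates are rescaled to sum to 1e6.
#' The optional TMM factors set the effective library scaling; every column
#' sums to 1e6 regardless.
#'
#' @inheritParams tmm_factors
#' @param gene_lengths Tibble with `gene` and `length` (bp), or a named
#'   numeric vector. Every gene in `counts` must have a positive length.
#' @param factors Optional output of [tmm_factors()].
#' @return Tibble with `gene` plus one TPM column per sample.
#' @export
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10L, 30L))
#' lengths <- tibble::tibble(gene = c("g1", "g2"), length = c(100, 300))
#' compute_tpm(counts, lengths)
compute_tpm <- function(counts, gene_lengths, factors = NULL) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  len <- if (is.data.frame(gene_lengths)) {
    setNames(gene_lengths$length, gene_lengths$gene)
  } else gene_lengths
  missing <- setdiff(rownames(m), names(len))
  if (length(missing)) {
    stop("missing gene length for: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  len <- len[rownames(m)]
  if (any(!is.finite(len) | len <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  scale <- rep(1, ncol(m))
  if (!is.null(factors)) {
    f <- setNames(factors$effective_lib_size, factors$sample)
    scale <- mean(f[colnames(m)]) / f[colnames(m)]
  }
  rate <- sweep(m, 2, scale, `*`) / len
  tpm <- sweep(rate, 2, colSums(rate), `/`) * 1e6
  matrix_to_tibble(tpm)
}

#' Log2 expression with pseudocount
#'
#' @param tpm TPM tibble from [compute_tpm()] (or any gene x sample tibble).
#' @param pseudocount Added before the log2 (default 1, so zeros map to 0).
#' @return Tibble of the same shape.
#' @export
log_expression <- function(tpm, pseudocount = 1) {
  m <- as_count_matrix(tpm)
  matrix_to_tibble(log2(m + pseudocount))
}

#' Pairwise Euclidean distances between samples
#'
#' @param expr Gene x sample expression tibble (typically
#'   [log_expression()] output).
#' @return Symmetric numeric matrix of distances with sample dimnames.
#' @export
sample_distances <- function(expr) {
  m <- as_count_matrix(expr)
  if (anyNA(m) || any(!is.finite(m))) {
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)
  }
  as.matrix(dist(t(m), method = "euclidean"))
}

#' Hierarchical clustering of samples
#'
#' Agglomerates the sample distance matrix with [stats::hclust()]
#' (complete linkage by default) and renders the dendrogram as a Newick
#' string via \pkg{ape}. Merge heights and order follow hclust's
#' deterministic tie handling.
#'
#' @param dmat Symmetric distance matrix from [sample_distances()].
#' @param linkage One of "complete", "single", "average".
#' @return An object of class `llr_hclust`: list with the `hclust` fit,
#'   a `merges` tibble (merge pairs + heights) and `newick`.
#' @export
cluster_samples <- function(dmat, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  hc <- hclust(stats::as.dist(dmat), method = linkage)
  merges <- tibble::tibble(step = seq_len(nrow(hc$merge)),
                           left = hc$merge[, 1], right = hc$merge[, 2],
                           height = hc$height)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, merges = merges, newick = newick,
                 linkage = linkage),
            class = "llr_hclust")
}

#' @export
print.llr_hclust <- function(x, ...) {
  cat("Sample dendrogram (", x$linkage, " linkage, ",
      length(x$hclust$labels), " samples)\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}
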