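#' Exact conditional count test between two sample groups
#'
#' Within each group, counts are rescaled to the common effective library
#' size (geometric mean of `lib_size * tmm_factor` over the tested samples),
#' rounded, and pooled into per-gene totals `y_A`, `y_B` with offsets
#' `N_A`, `N_B` proportional to group size. Conditional on `t = y_A + y_B`:
#'
#' * `mode = "binomial"`: under the null `y_A ~ Binomial(t, N_A/(N_A+N_B))`;
#'   the two-sided p-value doubles the smaller tail (capped at 1).
#' * `mode = "nb"`: the null conditional law of the split of `t` is the
#'   renormalized product of two negative-binomial masses with means
#'   `t*pi`, `t*(1-pi)` and common dispersion `phi`; the two-sided p-value
#'   sums the probability of all splits no more likely than the observed
#'   one. `phi = 0` reduces exactly to the binomial conditional.
#'
#' `log2fc = log2((y_A + prior)/N_A) - log2((y_B + prior)/N_B)`; the prior
#' count guards against infinite fold changes and is never used in testing.
#' Swapping the groups negates `log2fc` and leaves every p-value unchanged.
#'
#' @param counts Counts tibble or matrix.
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   ids (columns of `counts`).
#' @param mode `"binomial"` or `"nb"`.
#' @param dispersion NB dispersion phi for `mode = "nb"`; `NULL` estimates
#'   it with [estimate_common_dispersion()] on the two groups.
#' @param prior_count Added to pooled group counts for the fold change only.
#' @param factors Optional [tmm_factors()] output for the whole matrix;
#'   computed on the tested columns when missing.
#' @param contrast Label stored in the result (default "A vs B" built from
#'   the group names).
#' @param lfc_threshold,fdr_threshold Significance rule for the
#'   `significant` column: `|log2fc| > lfc_threshold` and
#'   `fdr < fdr_threshold`, both strict.
#' @param enum_limit Largest pooled total enumerated exhaustively in nb
#'   mode; larger totals use a windowed enumeration around the conditional
#'   mean (+- 20 sd), whose excluded outcomes carry negligible mass.
#'
#' @return A tibble of class `llr_de` with `gene`, `log2fc`, `pvalue`,
#'   `fdr`, `significant`, `contrast`.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, seed = 3))
#' a <- sim$metadata$sample_id[sim$metadata$condition == "AO_untreated"]
#' b <- sim$metadata$sample_id[sim$metadata$condition == "NM_untreated"]
#' exact_test(sim$counts, a, b, mode = "binomial")
exact_test <- function(counts, group_a, group_b,
                       mode = c("nb", "binomial"),
                       dispersion = NULL, prior_count = 0.5,
                       factors = NULL, contrast = NULL,
                       lfc_threshold = 1, fdr_threshold = 0.01,
                       enum_limit = 10000) {
  mode <- match.arg(mode)
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) {
    stop("samples not in counts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(dispersion) && (!is.finite(dispersion) || dispersion < 0)) {
    stop("dispersion must be finite and >= 0", call. = FALSE)
  }
  sub <- m[, c(group_a, group_b), drop = FALSE]
  if (is.null(factors)) factors <- tmm_factors(sub)
  eff <- setNames(factors$effective_lib_size, factors$sample)
  eff <- eff[colnames(sub)]
  common <- exp(mean(log(eff)))
  scaled <- round(sweep(sub, 2, common / eff, `*`))
  yA <- rowSums(scaled[, group_a, drop = FALSE])
  yB <- rowSums(scaled[, group_b, drop = FALSE])
  nA <- length(group_a) * common
  nB <- length(group_b) * common
  pi_a <- nA / (nA + nB)
  t <- yA + yB

  if (mode == "nb" && is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(
      sub, groups = list(A = group_a, B = group_b))
  }

  if (mode == "binomial" || (mode == "nb" && dispersion == 0)) {
    pvalue <- binomial_exact_p(yA, t, pi_a, double_tail = mode == "binomial")
  } else {
    # pooled count of n iid NB(mu, phi) replicates is NB with size n/phi
    size_a <- length(group_a) / dispersion
    size_b <- length(group_b) / dispersion
    pvalue <- vapply(seq_along(t), function(i) {
      nb_conditional_p(yA[i], t[i], pi_a, size_a, size_b, enum_limit)
    }, numeric(1))
  }
  log2fc <- log2((yA + prior_count) / nA) - log2((yB + prior_count) / nB)
  log2fc[t == 0] <- 0

  fdr <- bh_adjust(pvalue)
  if (is.null(contrast)) contrast <- "A vs B"
  out <- tibble::tibble(gene = rownames(m), log2fc = unname(log2fc),
                        pvalue = unname(pvalue), fdr = unname(fdr),
                        significant = abs(log2fc) > lfc_threshold &
                          fdr < fdr_threshold,
                        contrast = contrast)
  class(out) <- c("llr_de", class(out))
  attr(out, "mode") <- mode
  attr(out, "dispersion") <- if (mode == "nb") dispersion else NA_real_
  out
}

# Two-sided binomial p by tail doubling; when double_tail = FALSE (nb mode
# at phi = 0) the minimum-likelihood summation is used instead, on the same
# binomial conditional masses.
binomial_exact_p <- function(yA, t, pi_a, double_tail = TRUE) {
  p <- rep(1, length(yA))
  pos <- t > 0
  if (double_tail) {
    lower <- pbinom(yA[pos], t[pos], pi_a)
    upper <- pbinom(yA[pos] - 1, t[pos], pi_a, lower.tail = FALSE)
    p[pos] <- pmin(1, 2 * pmin(lower, upper))
  } else {
    p[pos] <- vapply(which(pos), function(i) {
      mass <- dbinom(0:t[i], t[i], pi_a)
      min_likelihood_p(mass, yA[i] + 1)
    }, numeric(1))
  }
  p
}

# Sum of (renormalized) masses no larger than the observed one. Sorting
# before summation makes the result invariant to the support's ordering,
# so swapping the two groups reproduces the p-value bit for bit.
min_likelihood_p <- function(mass, obs_index) {
  obs <- mass[obs_index]
  sel <- mass <= obs * (1 + 1e-12)
  sum(sort(mass[sel])) / sum(sort(mass))
}

# Conditional NB split test for one gene: mass of s given s + (t - s) = t
# where the two pooled group counts are NB with the given sizes.
# Enumerates s = 0..t (windowed around the conditional mean for very
# large t).
nb_conditional_p <- function(yA, t, pi_a, size_a, size_b,
                             enum_limit = 10000) {
  if (t == 0) return(1)
  if (t <= enum_limit) {
    s <- 0:t
  } else {
    muA <- t * pi_a
    halfw <- ceiling(20 * sqrt(muA + muA^2 / size_a))
    s <- max(0, floor(muA - halfw)):min(t, ceiling(muA + halfw))
    if (!yA %in% s) s <- sort(c(yA, s))
  }
  lm <- dnbinom(s, mu = t * pi_a, size = size_a, log = TRUE) +
    dnbinom(t - s, mu = t * (1 - pi_a), size = size_b, log = TRUE)
  mass <- exp(lm - max(lm))
  min_likelihood_p(mass, match(yA, s))
}

#' Method-of-moments common dispersion
#'
#' Counts are scaled to the mean library size; within every group with at
#' least two replicates the per-gene `(s^2 - mu)/mu^2` is computed and the
#' estimate is the across-gene (and across-group) mean, floored at 0.
#' Genes with scaled mean below `min_mean` are ignored as uninformative.
#'
#' @inheritParams exact_test
#' @param groups A list of character vectors of sample ids, or a metadata
#'   tibble with `sample_id` and `condition` (grouped by condition).
#' @param min_mean Minimum within-group scaled mean for a gene to
#'   contribute.
#' @return A single non-negative dispersion estimate. Returns 0 with a
#'   warning when no group has replication.
#' @export
estimate_common_dispersion <- function(counts, groups, min_mean = 1) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  if (is.data.frame(groups)) {
    groups <- split(groups$sample_id, groups$condition)
  }
  groups <- lapply(groups, intersect, colnames(m))
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (!length(groups)) {
    warning("no group has >= 2 replicates; returning dispersion 0")
    return(0)
  }
  lib <- colSums(m)
  norm <- sweep(m, 2, mean(lib) / lib, `*`)
  phis <- unlist(lapply(groups, function(g) {
    sub <- norm[, g, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    keep <- mu >= min_mean
    ((v - mu) / mu^2)[keep]
  }))
  max(0, mean(phis))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control:
#' `q_(i) = min over j >= i of p_(j) * n / j`, order-preserving and in
#' `[0, 1]`.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be numeric in [0, 1] with no missing values",
         call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Classify genes by the fold-change / FDR significance rule
#'
#' A gene is differentially expressed when `|log2fc| > lfc_threshold` and
#' `fdr < fdr_threshold`, both inequalities strict; the direction of the
#' fold change splits the significant genes into up and down.
#'
#' @param de An `llr_de` tibble from [exact_test()].
#' @param lfc_threshold,fdr_threshold Strict thresholds (default 1 and
#'   0.01, i.e. more than 2-fold change at FDR below 1%).
#' @return The input with `significant` recomputed and a `label` column in
#'   `{up, down, ns}`; counts available via [glance()].
#' @export
classify_de <- function(de, lfc_threshold = 1, fdr_threshold = 0.01) {
  if (lfc_threshold <= 0 || fdr_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  de$significant <- abs(de$log2fc) > lfc_threshold & de$fdr < fdr_threshold
  de$label <- dplyr::case_when(
    de$significant & de$log2fc > 0 ~ "up",
    de$significant & de$log2fc < 0 ~ "down",
    .default = "ns"
  )
  attr(de, "lfc_threshold") <- lfc_threshold
  attr(de, "fdr_threshold") <- fdr_threshold
  if (!inherits(de, "llr_de")) class(de) <- c("llr_de", class(de))
  de
}

#' @exportS3Method generics::glance
glance.llr_de <- function(x, ...) {
  if (!"label" %in% names(x)) x <- classify_de(x, ...)
  tibble::tibble(contrast = x$contrast[1],
                 n_up = sum(x$label == "up"),
                 n_down = sum(x$label == "down"),
                 n_ns = sum(x$label == "ns"))
}

#' Log2 fold-change profiles relative to the reference epithelium
#'
#' Runs [exact_test()] of each organ x timepoint condition against the
#' reference organ (EP) and assembles the per-gene vector of six log2 fold
#' changes — the coordinate system the divergence-distance and
#' co-expression analyses work in.
#'
#' @inheritParams exact_test
#' @param metadata Sample metadata tibble (`sample_id`, `condition`).
#' @param reference_organ Condition label of the reference (default "EP").
#' @param conditions Conditions to profile (default the six organ x
#'   timepoint groups).
#' @return Tibble with `gene` plus one log2FC column per condition.
#' @export
fold_change_to_reference <- function(counts, metadata,
                                     reference_organ = "EP",
                                     conditions = ll_profile_conditions(),
                                     mode = "binomial", dispersion = NULL,
                                     factors = NULL, prior_count = 0.5) {
  need <- c(conditions, reference_organ)
  absent <- setdiff(need, unique(metadata$condition))
  if (length(absent)) {
    stop("conditions missing from metadata: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ref_samples <- metadata$sample_id[metadata$condition == reference_organ]
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(m)
  profiles <- tibble::tibble(gene = rownames(m))
  for (cond in conditions) {
    grp <- metadata$sample_id[metadata$condition == cond]
    de <- exact_test(m, grp, ref_samples, mode = mode,
                     dispersion = dispersion, prior_count = prior_count,
                     factors = factors,
                     contrast = paste(cond, "vs", reference_organ))
    profiles[[cond]] <- de$log2fc
  }
  profiles
}
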