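#' Genes with increasing expression divergence along regeneration
#'
#' Applies the four-criterion filter to AO-vs-NM differential-expression
#' tables at 12 hpt, 24 hpt and untreated (mature), all oriented the same
#' way (positive log2FC = higher in AO). A gene passes when, simultaneously:
#'
#' 1. it is significantly different between untreated organs
#'    (`|log2FC| > lfc_threshold` and `FDR < fdr_threshold`, strict);
#' 2. it shows no difference at 12 hpt — by default, failing the same
#'    significance rule (`null_rule = "not-significant"`); with
#'    `null_rule = "fdr-only"` only `FDR >= fdr_threshold` is required;
#' 3. the 24 hpt fold change is smaller in magnitude than the untreated
#'    one (`|log2FC_24| < |log2FC_ut|`);
#' 4. the 24 hpt and untreated fold changes agree in sign (both organs
#'    ordered the same way at both times; a zero fold change at 24 hpt has
#'    no sign and fails).
#'
#' Passing genes are labeled `AO_high` or `NM_high` by the sign of the
#' untreated fold change.
#'
#' @param de_12h,de_24h,de_untreated `llr_de` tibbles over the same gene
#'   universe and the same AO-vs-NM orientation.
#' @param lfc_threshold,fdr_threshold Strict significance thresholds
#'   (default 1 and 0.01).
#' @param null_rule How "no difference at 12 hpt" is operationalized.
#' @return Tibble of class `llr_divergence`: `gene`, the three fold
#'   changes, criterion flags `c1_sig_untreated`, `c2_null_at_12h`,
#'   `c3_shrinking_back_in_time`, `c4_sign_consistent`, `passes`, and
#'   `direction` (`NA` unless passing).
#' @export
#' @examples
#' de <- function(lfc, fdr) tibble::tibble(gene = "g", log2fc = lfc,
#'                                         pvalue = fdr, fdr = fdr)
#' divergence_filter(de(0.1, 0.9), de(0.8, 0.2), de(2.0, 0.001))
divergence_filter <- function(de_12h, de_24h, de_untreated,
                              lfc_threshold = 1, fdr_threshold = 0.01,
                              null_rule = c("not-significant", "fdr-only")) {
  null_rule <- match.arg(null_rule)
  check_universe <- function(a, b, la, lb) {
    only_a <- setdiff(a$gene, b$gene)
    only_b <- setdiff(b$gene, a$gene)
    if (length(only_a) || length(only_b)) {
      stop("gene universes differ between ", la, " and ", lb, ": ",
           length(only_a), " only in ", la,
           " (e.g. ", paste(head(only_a, 3), collapse = ", "), "), ",
           length(only_b), " only in ", lb,
           " (e.g. ", paste(head(only_b, 3), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  check_universe(de_12h, de_24h, "12 hpt", "24 hpt")
  check_universe(de_12h, de_untreated, "12 hpt", "untreated")

  pick <- function(de, suffix) {
    out <- tibble::tibble(gene = de$gene, lfc = de$log2fc, fdr = de$fdr)
    names(out)[2:3] <- paste0(c("lfc_", "fdr_"), suffix)
    out
  }
  d <- dplyr::left_join(pick(de_12h, "12h"), pick(de_24h, "24h"), by = "gene")
  d <- dplyr::left_join(d, pick(de_untreated, "ut"), by = "gene")

  sig <- function(lfc, fdr) abs(lfc) > lfc_threshold & fdr < fdr_threshold
  c1 <- sig(d$lfc_ut, d$fdr_ut)
  c2 <- if (null_rule == "not-significant") {
    !sig(d$lfc_12h, d$fdr_12h)
  } else {
    d$fdr_12h >= fdr_threshold
  }
  c3 <- abs(d$lfc_24h) < abs(d$lfc_ut)
  c4 <- sign(d$lfc_24h) == sign(d$lfc_ut) & sign(d$lfc_24h) != 0
  passes <- c1 & c2 & c3 & c4

  out <- dplyr::mutate(
    d,
    c1_sig_untreated = c1, c2_null_at_12h = c2,
    c3_shrinking_back_in_time = c3, c4_sign_consistent = c4,
    passes = passes,
    direction = dplyr::if_else(
      passes, dplyr::if_else(.data$lfc_ut > 0, "AO_high", "NM_high"),
      NA_character_)
  )
  class(out) <- c("llr_divergence", class(out))
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "null_rule") <- null_rule
  out
}

#' @exportS3Method generics::glance
glance.llr_divergence <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 n_pass = sum(x$passes),
                 n_ao_high = sum(x$direction == "AO_high", na.rm = TRUE),
                 n_nm_high = sum(x$direction == "NM_high", na.rm = TRUE))
}

#' Euclidean distance between two group fold-change profiles
#'
#' The between-group distance on the log2FC-to-reference scale:
#' `sqrt(sum((a_g - b_g)^2))` over a shared, identically ordered gene
#' universe.
#'
#' @param a,b Equal-length numeric vectors of per-gene log2 fold changes;
#'   when both are named the names must match elementwise.
#' @return A single non-negative number; 0 iff the profiles are identical.
#' @export
#' @examples
#' group_distance(c(0, 0, 0), c(1, 2, 2))
group_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    stop("profile gene names disagree", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("profiles contain missing or non-finite values", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

#' AO-NM profile distances per timepoint
#'
#' Convenience wrapper computing [group_distance()] between the AO and NM
#' log2FC-to-reference profiles at each regeneration timepoint.
#'
#' @param profiles Output of [fold_change_to_reference()].
#' @return Tibble with `timepoint` and `distance`.
#' @export
organ_distances <- function(profiles) {
  tp <- c("12hpt", "24hpt", "untreated")
  dist <- vapply(tp, function(t) {
    group_distance(profiles[[paste0("AO_", t)]], profiles[[paste0("NM_", t)]])
  }, numeric(1))
  tibble::tibble(timepoint = tp, distance = unname(dist))
}
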