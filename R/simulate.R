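#' Simulation configuration for planted-signal count data
#'
#' Builds the parameter set for [simulate_counts()]. The defaults describe
#' the study design the simulator emulates: seven tissue groups (AO and NM
#' at 12 hpt, 24 hpt and untreated, plus EP) with two replicates each,
#' negative-binomial gene counts, and six planted gene classes. Divergent
#' genes follow the minimal trajectory that an "increasing divergence"
#' filter should recover: the AO-NM log2 difference is 0 at 12 hpt, half
#' the planted effect at 24 hpt, and the full effect `divergence_delta` in
#' the untreated (mature) organs.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_reps Replicates per condition (>= 1).
#' @param lib_size_mean Expected total counts per sample. `NULL` (default)
#'   leaves gene means on their natural scale so the expected total is the
#'   sum of the baseline condition means.
#' @param lib_size_cv Coefficient of variation of the per-sample library
#'   size factors (log-normal, mean 1). 0 gives identical libraries.
#' @param dispersion Negative-binomial dispersion phi, with
#'   `variance = mu + phi * mu^2`. 0 gives Poisson counts.
#' @param baseline_logmean_mu,baseline_logmean_sigma Log-normal parameters
#'   (meanlog, sdlog) of the per-gene baseline mean.
#' @param baseline_min Floor applied to baseline means; keeps every gene in
#'   the moderately-to-well-measured regime the pipeline is aimed at.
#' @param class_fractions Named proportions of the six gene classes
#'   (`background`, `common_enriched`, `ao_specific`, `nm_specific`,
#'   `divergent_ao`, `divergent_nm`); must sum to 1.
#' @param effect_lfc Planted log2 fold change versus EP for the
#'   organ-specific and common sensory-enriched classes.
#' @param divergence_delta Planted untreated AO-NM log2 difference for the
#'   divergent classes (positive; sign is set by the class).
#' @param seed Integer RNG seed; identical seeds give identical output.
#'
#' @return A list of class `llr_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' cfg$dispersion
sim_config <- function(n_genes = 10000,
                       n_reps = 2,
                       lib_size_mean = NULL,
                       lib_size_cv = 0.2,
                       dispersion = 0.1,
                       baseline_logmean_mu = log(500),
                       baseline_logmean_sigma = 1,
                       baseline_min = 200,
                       class_fractions = c(background = 0.895,
                                           common_enriched = 0.05,
                                           ao_specific = 0.02,
                                           nm_specific = 0.02,
                                           divergent_ao = 0.01,
                                           divergent_nm = 0.005),
                       effect_lfc = 2,
                       divergence_delta = 3,
                       seed = NULL) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(n_genes) || n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (!num_ok(n_reps) || n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (!num_ok(dispersion) || dispersion < 0) {
    stop("dispersion must be a finite number >= 0", call. = FALSE)
  }
  if (!num_ok(lib_size_cv) || lib_size_cv < 0) {
    stop("lib_size_cv must be a finite number >= 0", call. = FALSE)
  }
  if (!is.null(lib_size_mean) && (!num_ok(lib_size_mean) || lib_size_mean <= 0)) {
    stop("lib_size_mean must be a positive finite number or NULL", call. = FALSE)
  }
  if (!num_ok(effect_lfc) || !num_ok(divergence_delta)) {
    stop("effect sizes must be finite", call. = FALSE)
  }
  if (!num_ok(baseline_logmean_mu) || !num_ok(baseline_logmean_sigma) ||
      baseline_logmean_sigma < 0 || !num_ok(baseline_min) || baseline_min < 0) {
    stop("baseline parameters must be finite (sigma, min >= 0)", call. = FALSE)
  }
  cls <- ll_gene_classes()
  if (is.null(names(class_fractions)) || !all(names(class_fractions) %in% cls)) {
    stop("class_fractions must be named with: ", paste(cls, collapse = ", "),
         call. = FALSE)
  }
  fr <- setNames(numeric(length(cls)), cls)
  fr[names(class_fractions)] <- class_fractions
  if (!num_ok(fr) || any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("class_fractions must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
                 dispersion = dispersion,
                 baseline_logmean_mu = baseline_logmean_mu,
                 baseline_logmean_sigma = baseline_logmean_sigma,
                 baseline_min = baseline_min,
                 class_fractions = fr,
                 effect_lfc = effect_lfc,
                 divergence_delta = divergence_delta,
                 seed = seed),
            class = "llr_sim_config")
}

# Largest-remainder apportionment of n_genes across classes so the counts
# are deterministic and sum exactly to n_genes.
class_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Per-class condition mean multipliers on the log2 scale, relative to the
# gene's baseline (EP) mean. Columns follow ll_conditions().
class_log2_multipliers <- function(effect_lfc, delta) {
  conds <- ll_conditions()
  m <- matrix(0, nrow = 6, ncol = length(conds),
              dimnames = list(ll_gene_classes(), conds))
  ao <- c("AO_12hpt", "AO_24hpt", "AO_untreated")
  nm <- c("NM_12hpt", "NM_24hpt", "NM_untreated")
  m["common_enriched", c(ao, nm)] <- effect_lfc
  m["ao_specific", ao] <- effect_lfc
  m["nm_specific", nm] <- effect_lfc
  # divergence trajectory 0 -> delta/2 -> delta along 12hpt/24hpt/untreated
  m["divergent_ao", c("AO_24hpt", "AO_untreated")] <- c(delta / 2, delta)
  m["divergent_nm", c("NM_24hpt", "NM_untreated")] <- c(delta / 2, delta)
  m
}

#' Simulate a planted-signal count matrix with its truth table
#'
#' Draws independent negative-binomial counts per gene and sample
#' (`variance = mu + phi * mu^2`), scaled by log-normal per-sample library
#' factors. Gene classes plant: sensory enrichment common to both organs,
#' organ-specific enrichment, and divergence trajectories whose AO-NM
#' log2 difference grows 0 -> delta/2 -> delta across the time course.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{counts}{tibble, `gene` column plus one integer column per sample.}
#'     \item{metadata}{tibble with `sample_id`, `organ`, `timepoint`,
#'       `replicate`, `condition`.}
#'     \item{truth}{tibble with gene class, per-condition true means
#'       (`mean_<condition>`), and the true AO-NM log2 difference at each
#'       timepoint (`true_lfc_<timepoint>`).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, seed = 42))
#' dim(sim$counts)
simulate_counts <- function(config) {
  if (!inherits(config, "llr_sim_config")) {
    stop("config must come from sim_config()", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_genes
  conds <- ll_conditions()
  genes <- sprintf("gene%05d", seq_len(n))

  n_class <- class_counts(n, config$class_fractions)
  class <- rep(ll_gene_classes(), times = n_class)

  baseline <- pmax(rlnorm(n, config$baseline_logmean_mu,
                          config$baseline_logmean_sigma),
                   config$baseline_min)
  mult <- class_log2_multipliers(config$effect_lfc, config$divergence_delta)
  mu <- baseline * 2^mult[class, , drop = FALSE]
  dimnames(mu) <- list(genes, conds)

  if (!is.null(config$lib_size_mean)) {
    mu <- mu * config$lib_size_mean / mean(colSums(mu))
  }

  meta <- tidyr::expand_grid(condition = conds,
                             replicate = seq_len(config$n_reps))
  meta <- dplyr::mutate(
    meta,
    organ = ifelse(.data$condition == "EP", "EP",
                   sub("_.*$", "", .data$condition)),
    timepoint = ifelse(.data$condition == "EP", "na",
                       sub("^[A-Z]+_", "", .data$condition)),
    sample_id = paste0(.data$condition, "_", .data$replicate)
  )
  meta <- dplyr::select(meta, "sample_id", "organ", "timepoint",
                        "replicate", "condition")

  cv <- config$lib_size_cv
  sdlog <- sqrt(log1p(cv^2))
  lib_factor <- rlnorm(nrow(meta), meanlog = -sdlog^2 / 2, sdlog = sdlog)

  counts <- matrix(0L, nrow = n, ncol = nrow(meta),
                   dimnames = list(genes, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    mu_j <- mu[, meta$condition[j]] * lib_factor[j]
    counts[, j] <- if (config$dispersion == 0) {
      rpois(n, lambda = mu_j)
    } else {
      rnbinom(n, mu = mu_j, size = 1 / config$dispersion)
    }
  }

  tp <- c("12hpt", "24hpt", "untreated")
  true_lfc <- sapply(tp, function(t) {
    log2(mu[, paste0("AO_", t)]) - log2(mu[, paste0("NM_", t)])
  })
  truth <- tibble::tibble(gene = genes, class = class)
  for (cc in conds) truth[[paste0("mean_", cc)]] <- unname(mu[, cc])
  for (t in tp) truth[[paste0("true_lfc_", t)]] <- unname(true_lfc[, t])

  list(counts = matrix_to_tibble(counts),
       metadata = meta,
       truth = truth,
       config = config)
}

#' Read and write pipeline tables as plain TSV
#'
#' Counts are genes x samples with a header of sample ids and a leading
#' `gene` column; metadata and truth tables round-trip as written.
#' `read_counts()` validates that every count cell is a non-negative whole
#' number and that gene ids are unique; with `expected_samples` it also
#' checks the header.
#'
#' @param counts,metadata,truth Tibbles as produced by [simulate_counts()].
#' @param path File path.
#' @param expected_samples Optional character vector of sample ids the
#'   header must contain.
#' @return The written tibble (writers, invisibly) or the parsed tibble
#'   (readers).
#' @name sim_io
NULL

#' @rdname sim_io
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(counts)
}

#' @rdname sim_io
#' @export
read_counts <- function(path, expected_samples = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"gene" %in% names(x)) stop("counts file lacks a 'gene' column", call. = FALSE)
  samp <- setdiff(names(x), "gene")
  if (!is.null(expected_samples)) {
    missing <- setdiff(expected_samples, samp)
    if (length(missing)) {
      stop("counts file is missing expected sample columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(x$gene)) {
    dup <- unique(x$gene[duplicated(x$gene)])
    stop("duplicate gene ids: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(x[samp])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer count at gene '%s', sample '%s': %s",
                 x$gene[bad[1, 1]], samp[bad[1, 2]], m[bad[1, , drop = FALSE]]),
         call. = FALSE)
  }
  x[samp] <- lapply(x[samp], as.integer)
  x
}

#' @rdname sim_io
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(truth)
}

#' @rdname sim_io
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), class = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname sim_io
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(metadata)
}

#' @rdname sim_io
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    replicate = readr::col_integer(), .default = readr::col_character()
  ), progress = FALSE)
}
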