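#' Peptide length filter
#'
#' Keeps predicted peptides strictly longer than `min_length` amino acids
#' (the "longer than 100 aa" triage applied before ortholog annotation;
#' 100 aa corresponds to an ORF longer than 300 bp, stop codon excluded).
#'
#' @param peptides Tibble with `id` and `length` (aa), or a named numeric
#'   vector of lengths.
#' @param min_length Strict lower bound in amino acids (default 100).
#' @return The kept rows (tibble in, tibble out; vector in, named vector
#'   out).
#' @export
#' @examples
#' filter_peptides(c(a = 50, b = 100, c = 101, d = 500))
filter_peptides <- function(peptides, min_length = 100) {
  if (is.data.frame(peptides)) {
    if (!all(c("id", "length") %in% names(peptides))) {
      stop("peptides tibble needs 'id' and 'length' columns", call. = FALSE)
    }
    return(peptides[peptides$length > min_length, , drop = FALSE])
  }
  peptides[peptides > min_length]
}

blast6_cols <- c("query", "subject", "identity", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular hits (outfmt 6)
#'
#' Parses the standard 12-column tabular format, optionally with a 13th
#' `qlen` column; query lengths can instead come from a sidecar table.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param qlen Optional tibble with `query` and `qlen` giving query
#'   lengths (aa) when the file has only 12 columns.
#' @return Tibble with the outfmt-6 columns plus `qlen` when available.
#' @export
read_blast_hits <- function(path, qlen = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       show_col_types = FALSE)
  if (ncol(x) < 12) {
    stop("expected >= 12 tab-separated columns (outfmt 6), got ", ncol(x),
         call. = FALSE)
  }
  names(x)[1:12] <- blast6_cols
  if (ncol(x) >= 13) names(x)[13] <- "qlen"
  if (!is.null(qlen)) {
    if (!all(c("query", "qlen") %in% names(qlen))) {
      stop("qlen table needs 'query' and 'qlen' columns", call. = FALSE)
    }
    x <- dplyr::left_join(x[setdiff(names(x), "qlen")], qlen, by = "query")
  }
  x
}

#' Filter BLAST hits by coverage and identity
#'
#' Keeps hits with query coverage strictly above `min_coverage` and percent
#' identity strictly above `min_identity`; query coverage is alignment
#' length over query length (capped at 1 in the reported column). With
#' `best_per_query`, only the surviving hit with the highest bitscore is
#' retained per query (ties broken by lowest e-value, then lexicographic
#' subject id).
#'
#' @param hits Tibble with at least `query`, `subject`, `identity`,
#'   `length`, `qlen`, `evalue`, `bitscore` (see [read_blast_hits()]).
#' @param min_coverage Strict lower bound on query coverage (default 0.70).
#' @param min_identity Strict lower bound on percent identity
#'   (default 50).
#' @param best_per_query Keep only the best surviving hit per query.
#' @return Filtered tibble with an added `coverage` column.
#' @export
filter_blast_hits <- function(hits, min_coverage = 0.70, min_identity = 50,
                              best_per_query = TRUE) {
  need <- c("query", "subject", "identity", "length", "qlen",
            "evalue", "bitscore")
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    stop("hit table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(hits$qlen <= 0 | hits$length <= 0)) {
    stop("alignment and query lengths must be positive", call. = FALSE)
  }
  cov <- hits$length / hits$qlen
  out <- dplyr::mutate(hits, coverage = pmin(cov, 1))
  out <- out[cov > min_coverage & out$identity > min_identity, , drop = FALSE]
  if (best_per_query && nrow(out)) {
    out <- dplyr::arrange(out, .data$query, dplyr::desc(.data$bitscore),
                          .data$evalue, .data$subject)
    out <- dplyr::slice_head(dplyr::group_by(out, .data$query), n = 1)
    out <- dplyr::ungroup(out)
  }
  out
}

#' Merge two ortholog annotation sources
#'
#' Unions two query-to-gene maps (e.g. Swiss-Prot and sterlet orthologs)
#' keeping provenance. A query annotated by both sources to the same gene
#' collapses to one entry with both tags; a query mapped to different genes
#' keeps both labels, flagged as a conflict (and reported via message).
#'
#' @param source_a,source_b Tibbles with `query` and `gene`, or named
#'   character vectors (names = query ids).
#' @param source_names Length-2 character vector of provenance tags.
#' @return Tibble with `query`, `gene`, `sources` (comma-joined tags) and
#'   `conflict` (TRUE when the query's sources disagree on the gene).
#' @export
#' @examples
#' a <- tibble::tibble(query = c("q1", "q2"), gene = c("gA", "gB"))
#' b <- tibble::tibble(query = c("q2", "q3"), gene = c("gB", "gC"))
#' merge_annotations(a, b)
merge_annotations <- function(source_a, source_b,
                              source_names = c("a", "b")) {
  as_map <- function(x, tag) {
    if (is.data.frame(x)) {
      tibble::tibble(query = x$query, gene = x$gene, source = tag)
    } else {
      tibble::tibble(query = names(x), gene = unname(x), source = tag)
    }
  }
  long <- dplyr::bind_rows(as_map(source_a, source_names[1]),
                           as_map(source_b, source_names[2]))
  if (!nrow(long)) {
    return(tibble::tibble(query = character(), gene = character(),
                          sources = character(), conflict = logical()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$query, .data$gene),
    sources = paste(sort(unique(.data$source)), collapse = ","),
    .groups = "drop")
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$query),
    conflict = dplyr::n() > 1)
  out <- dplyr::ungroup(out)
  n_conf <- length(unique(out$query[out$conflict]))
  if (n_conf > 0) {
    message(n_conf, " quer(ies) map to different genes in the two sources; ",
            "both labels retained")
  }
  dplyr::arrange(out, .data$query, .data$gene)
}
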