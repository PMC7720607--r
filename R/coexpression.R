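#' Pearson correlation of fold-change profiles
#'
#' Pairwise Pearson correlation between gene profiles (rows of the
#' log2FC-to-reference table). Genes with zero profile variance have no
#' defined correlation; they are dropped with a warning and recorded in the
#' `excluded` attribute.
#'
#' @param profiles Output of [fold_change_to_reference()] (tibble with
#'   `gene` plus numeric profile columns).
#' @param genes Optional subset of gene ids to correlate.
#' @return Symmetric correlation matrix with gene dimnames, unit diagonal.
#' @export
profile_correlation <- function(profiles, genes = NULL) {
  m <- as_count_matrix(profiles)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      stop("genes not in profiles: ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 3) stop("profiles need at least 3 dimensions", call. = FALSE)
  v <- apply(m, 1, var)
  excluded <- rownames(m)[v == 0]
  if (length(excluded)) {
    warning(length(excluded),
            " constant profile(s) excluded (undefined correlation): ",
            paste(head(excluded, 5), collapse = ", "))
    m <- m[v > 0, , drop = FALSE]
  }
  r <- cor(t(m))
  attr(r, "excluded") <- excluded
  r
}

#' Threshold co-expression network from a correlation matrix
#'
#' Connects gene pairs whose squared correlation exceeds `r2_threshold`
#' (strict). Node weight is the sum of `|r|` over incident edges — the
#' quantity used to size network nodes.
#'
#' @param r Symmetric correlation matrix (genes as dimnames).
#' @param r2_threshold Strict lower bound on `r^2` for an edge
#'   (default 0.7).
#' @param groups Optional named character vector or tibble
#'   (`gene`, `group`) labeling nodes (e.g. AO_high / NM_high / regulator).
#' @return An object of class `llr_network`: list with `nodes` (gene,
#'   group, degree, weight), `edges` (from, to, r, r2) and the threshold.
#' @export
#' @examples
#' r <- diag(3); dimnames(r) <- list(letters[1:3], letters[1:3])
#' r["a", "b"] <- r["b", "a"] <- -0.9
#' build_network(r)$edges
build_network <- function(r, r2_threshold = 0.7, groups = NULL) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  genes <- rownames(r)
  idx <- which(upper.tri(r) & r^2 > r2_threshold, arr.ind = TRUE)
  rv <- r[idx]
  edges <- tibble::tibble(from = genes[idx[, 1]], to = genes[idx[, 2]],
                          r = rv, r2 = rv^2)
  weight <- setNames(numeric(length(genes)), genes)
  degree <- setNames(integer(length(genes)), genes)
  if (nrow(edges)) {
    for (side in c("from", "to")) {
      agg <- tapply(abs(edges$r), edges[[side]], sum)
      weight[names(agg)] <- weight[names(agg)] + agg
      deg <- table(edges[[side]])
      degree[names(deg)] <- degree[names(deg)] + as.integer(deg)
    }
  }
  nodes <- tibble::tibble(gene = genes, degree = unname(degree),
                          weight = unname(weight))
  if (!is.null(groups)) {
    if (is.data.frame(groups)) groups <- setNames(groups$group, groups$gene)
    nodes$group <- unname(groups[nodes$gene])
  }
  structure(list(nodes = nodes, edges = edges, r2_threshold = r2_threshold),
            class = "llr_network")
}

#' @export
print.llr_network <- function(x, ...) {
  cat("Co-expression network: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (r^2 > ", x$r2_threshold, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.llr_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.llr_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_isolated = sum(x$nodes$degree == 0),
                 r2_threshold = x$r2_threshold)
}

#' Convert to an igraph object
#'
#' @param network An `llr_network`.
#' @return An undirected \pkg{igraph} graph with `r`, `r2` edge attributes
#'   and `weight` (and `group`, if present) node attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "llr_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Write a network as GraphML and/or edge-list TSV
#'
#' @param network An `llr_network`.
#' @param graphml,edges Output paths; `NULL` skips that format.
#' @return The network, invisibly.
#' @export
write_network <- function(network, graphml = NULL, edges = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(network), graphml, format = "graphml")
  }
  if (!is.null(edges)) readr::write_tsv(network$edges, edges)
  invisible(network)
}

#' Correlation of focal genes against gene groups
#'
#' For each focal gene (e.g. a candidate transcriptional regulator) and
#' each gene group (e.g. AO-high / NM-high divergence genes), summarizes
#' the distribution of pairwise correlations by the first quartile, median
#' and third quartile (linear-interpolation quantiles, R type 7). A focal
#' gene belonging to a group is excluded from its own summary.
#'
#' @param r Correlation matrix from [profile_correlation()].
#' @param focal_genes Character vector of focal gene ids.
#' @param groups Named list of character vectors of gene ids.
#' @return Tibble: `focal`, `group`, `n`, `q1`, `median`, `q3`.
#' @export
correlation_summary <- function(r, focal_genes, groups) {
  genes <- rownames(r)
  missing <- setdiff(focal_genes, genes)
  if (length(missing)) {
    stop("focal genes not in correlation matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list", call. = FALSE)
  }
  purrr::map_dfr(focal_genes, function(f) {
    purrr::map_dfr(names(groups), function(gname) {
      members <- setdiff(intersect(groups[[gname]], genes), f)
      if (!length(members)) {
        stop("group '", gname, "' is empty within the correlation matrix",
             call. = FALSE)
      }
      vals <- r[f, members]
      q <- quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      tibble::tibble(focal = f, group = gname, n = length(vals),
                     q1 = q[1], median = q[2], q3 = q[3])
    })
  })
}
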