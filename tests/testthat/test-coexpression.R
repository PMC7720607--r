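profiles_from_matrix <- function(m) {
  tibble::as_tibble(cbind(data.frame(gene = rownames(m)), m))
}

test_that("profile correlations match the definition", {
  x <- c(-2, -1, 0, 1, 2, 3)
  m <- rbind(a = x, b = 2 * x, c = -x, d = c(5, 1, 4, 2, 8, 0))
  colnames(m) <- ll_profile_conditions()
  r <- profile_correlation(profiles_from_matrix(m))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(r, t(r))
  # definition oracle: covariance over product of standard deviations
  ad <- sum((m["a", ] - mean(m["a", ])) * (m["d", ] - mean(m["d", ]))) /
    ((length(x) - 1) * sd(m["a", ]) * sd(m["d", ]))
  expect_equal(r["a", "d"], ad, tolerance = 1e-12)
})

test_that("constant profiles are excluded with a warning", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6), flat = rep(2, 6),
             b = c(2, 1, 3, 6, 4, 5))
  colnames(m) <- ll_profile_conditions()
  expect_warning(r <- profile_correlation(profiles_from_matrix(m)),
                 "constant")
  expect_equal(sort(rownames(r)), c("a", "b"))
  expect_equal(attr(r, "excluded"), "flat")
})

test_that("network edges obey the strict r^2 threshold", {
  genes <- c("a", "b", "c", "d")
  r <- diag(4); dimnames(r) <- list(genes, genes)
  r["a", "b"] <- r["b", "a"] <- 0.85   # r^2 = 0.7225 -> edge
  r["a", "c"] <- r["c", "a"] <- 0.83   # r^2 = 0.6889 -> no edge
  r["b", "d"] <- r["d", "b"] <- -0.9   # r^2 = 0.81   -> edge (sign-free)
  net <- build_network(r)
  expect_equal(nrow(net$edges), 2)
  key <- paste(net$edges$from, net$edges$to)
  expect_setequal(key, c("a b", "b d"))
  # node weights are sums of |r| over incident edges
  w <- setNames(net$nodes$weight, net$nodes$gene)
  expect_equal(unname(w[c("a", "b", "c", "d")]),
               c(0.85, 0.85 + 0.9, 0, 0.9))
  # a pair sitting exactly on the threshold is excluded (strict inequality)
  at_boundary <- build_network(r, r2_threshold = 0.85^2)
  expect_equal(paste(at_boundary$edges$from, at_boundary$edges$to), "b d")
})

test_that("network matches exhaustive pair enumeration on random matrices", {
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 6), n,
                dimnames = list(paste0("g", 1:n), ll_profile_conditions()))
    r <- profile_correlation(profiles_from_matrix(m))
    thr <- runif(1, 0.3, 0.9)
    net <- build_network(r, r2_threshold = thr)
    expected <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (r[i, j]^2 > thr) expected <- expected + 1
    }
    expect_equal(nrow(net$edges), expected)
    for (g in rownames(r)) {
      others <- setdiff(rownames(r), g)
      expect_equal(net$nodes$weight[net$nodes$gene == g],
                   sum(abs(r[g, others])[r[g, others]^2 > thr]))
    }
  }
})

test_that("edge count is monotone non-increasing in the threshold", {
  set.seed(82)
  m <- matrix(rnorm(60), 10,
              dimnames = list(paste0("g", 1:10), ll_profile_conditions()))
  r <- profile_correlation(profiles_from_matrix(m))
  counts <- vapply(seq(0.1, 0.9, by = 0.1),
                   function(t) nrow(build_network(r, t)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("removing a gene removes exactly its incident contributions", {
  set.seed(83)
  m <- matrix(rnorm(42), 7,
              dimnames = list(paste0("g", 1:7), ll_profile_conditions()))
  r <- profile_correlation(profiles_from_matrix(m))
  net <- build_network(r, 0.4)
  drop <- "g3"
  net2 <- build_network(r[rownames(r) != drop, colnames(r) != drop], 0.4)
  lost <- net$edges[net$edges$from == drop | net$edges$to == drop, ]
  expect_equal(nrow(net2$edges), nrow(net$edges) - nrow(lost))
  for (g in setdiff(rownames(r), drop)) {
    contrib <- sum(abs(lost$r[lost$from == g | lost$to == g]))
    expect_equal(net2$nodes$weight[net2$nodes$gene == g],
                 net$nodes$weight[net$nodes$gene == g] - contrib)
  }
})

test_that("networks export to igraph, GraphML and edge-list TSV", {
  r <- diag(3); dimnames(r) <- list(letters[1:3], letters[1:3])
  r["a", "b"] <- r["b", "a"] <- 0.95
  net <- build_network(r, groups = c(a = "AO_high", b = "NM_high",
                                     c = "regulator"))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
  dir <- withr::local_tempdir()
  write_network(net, graphml = file.path(dir, "net.graphml"),
                edges = file.path(dir, "edges.tsv"))
  back <- igraph::read_graph(file.path(dir, "net.graphml"),
                             format = "graphml")
  expect_equal(igraph::ecount(back), 1)
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           show_col_types = FALSE)
  expect_equal(edges$r, 0.95)
  expect_equal(glance(net)$n_edges, 1)
  expect_equal(nrow(tidy(net)), 1)
})

test_that("correlation summaries use type-7 quartiles", {
  genes <- c("f", paste0("m", 1:4))
  r <- diag(5); dimnames(r) <- list(genes, genes)
  r["f", paste0("m", 1:4)] <- r[paste0("m", 1:4), "f"] <- c(0.2, 0.4, 0.6, 0.8)
  s <- correlation_summary(r, "f", list(grp = paste0("m", 1:4)))
  expect_equal(s$median, 0.5)
  expect_equal(s$q1, 0.35)
  expect_equal(s$q3, 0.65)

  # focal gene identical to every member: median r = 1
  x <- c(1, 2, 3, 1, 2, 3)
  m <- rbind(f = x, m1 = x, m2 = x)
  colnames(m) <- ll_profile_conditions()
  r2 <- profile_correlation(profiles_from_matrix(m))
  s2 <- correlation_summary(r2, "f", list(grp = c("m1", "m2")))
  expect_equal(s2$median, 1)

  expect_error(correlation_summary(r, "f", list(grp = "zz")), "empty")
  expect_error(correlation_summary(r, "nope", list(grp = "m1")), "nope")
})

test_that("planted regulators correlate positively with their own class", {
  sim <- simulate_counts(sim_config(n_genes = 3000, seed = 85))
  prof <- fold_change_to_reference(sim$counts, sim$metadata)
  truth <- sim$truth
  ao <- truth$gene[truth$class == "divergent_ao"]
  nm <- truth$gene[truth$class == "divergent_nm"]
  r <- profile_correlation(prof, genes = c(ao, nm))
  # use the first divergent_ao gene as a stand-in regulator sharing the
  # AO trajectory
  s <- correlation_summary(r, ao[1], list(ao = ao[-1], nm = nm))
  expect_gt(s$median[s$group == "ao"], 0)
  expect_lt(s$median[s$group == "nm"], 0)
})
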