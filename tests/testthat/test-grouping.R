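fit_four_groups <- function(n = 30, means = c(1, 1, 1, 1), sd = 0.5,
                            seed = 1) {
  set.seed(seed)
  f <- make_features(n, means = means, sd = sd)
  names(f)[names(f) == "y"] <- "resting"
  fit_condition_model(f, "resting", random = character(0), lambda = 1)
}

test_that("four conditions give six Tukey comparisons with adjusted >= raw", {
  fit <- fit_four_groups(25, means = c(1, 1.2, 2, 1.1), seed = 3)
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 6)
  expect_true(all(ct$p_adj >= ct$p_raw))
  expect_true(all(ct$p_adj <= 1 & ct$p_raw >= 0))
  expect_setequal(
    ct$contrast,
    c("NCM460.control - NCM460.DFMO", "NCM460.control - HT29.control",
      "NCM460.control - HT29.DFMO", "NCM460.DFMO - HT29.control",
      "NCM460.DFMO - HT29.DFMO", "HT29.control - HT29.DFMO"))
})

test_that("contrasts agree with the emmeans reference implementation", {
  skip_if_not_installed("emmeans")
  cfg <- calcium_sim_config(cells_per_coverslip = 8L, seed = 17)
  sim <- simulate_calcium(cfg)
  f <- extract_features(sim$traces, default_protocol(cfg$phase_times))
  fit <- fit_condition_model(f, "resting", lambda = 1)
  ct <- pairwise_contrasts(fit)
  emm <- emmeans::emmeans(fit$model, ~ line * treatment,
                          lmer.df = "satterthwaite")
  ref <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  expect_equal(sort(abs(ct$estimate)), sort(abs(ref$estimate)),
               tolerance = 1e-8)
  expect_equal(sort(ct$p_adj), sort(ref$p.value), tolerance = 1e-4)
})

test_that("family-wise error rate is near nominal under the null", {
  n_sim <- 1000
  fwer <- 0
  for (r in seq_len(n_sim)) {
    fit <- fit_four_groups(12, seed = 5000 + r)
    ct <- pairwise_contrasts(fit)
    if (any(ct$p_adj < 0.05)) fwer <- fwer + 1
  }
  expect_gte(fwer / n_sim, 0.03)
  expect_lte(fwer / n_sim, 0.07)
})

test_that("similarity graph edges follow the adjusted p rule", {
  fit <- fit_four_groups(20, seed = 9)
  ct <- pairwise_contrasts(fit)
  # force specific p patterns
  ct$p_adj <- c(0.5, 0.01, 0.01, 0.01, 0.01, 0.5)
  g <- build_similarity_graph(ct, alpha = 0.05)
  expect_true(g$adj["NCM460.control", "NCM460.DFMO"])
  expect_true(g$adj["HT29.control", "HT29.DFMO"])
  expect_false(g$adj["NCM460.control", "HT29.control"])
  expect_true(isSymmetric(g$adj))
  expect_false(any(diag(g$adj)))

  ct$p_adj <- rep(0.01, 6)
  expect_equal(sum(build_similarity_graph(ct, 0.05)$adj), 0)
  ct$p_adj <- rep(0.9, 6)
  expect_equal(sum(build_similarity_graph(ct, 0.05)$adj), 12)
  expect_error(build_similarity_graph(ct[-1, ], 0.05), "every unordered pair")
})

test_that("maximal cliques handle canonical small graphs", {
  k4 <- matrix(TRUE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(k4) <- FALSE
  expect_equal(maximal_cliques(k4), list(c("a", "b", "c", "d")))
  empty <- matrix(FALSE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(maximal_cliques(empty),
               list("a", "b", "c", "d"))
  path <- matrix(FALSE, 3, 3, dimnames = list(c("x", "y", "z"),
                                              c("x", "y", "z")))
  path["x", "y"] <- path["y", "x"] <- TRUE
  path["y", "z"] <- path["z", "y"] <- TRUE
  expect_equal(maximal_cliques(path), list(c("x", "y"), c("y", "z")))
})

test_that("clique enumeration matches brute force and igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    adj <- matrix(runif(n * n) < runif(1, 0.2, 0.8), n, n)
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    mine <- maximal_cliques(adj)
    expect_identical(mine, bf_cliques(adj))
    g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
    ig <- lapply(igraph::max_cliques(g), function(v) sort(names(v)))
    ig <- ig[order(vapply(ig, paste, "", collapse = "\r"))]
    expect_identical(mine, ig)
  }
})

test_that("letters follow clique order and the path graph yields 'ab'", {
  means <- c(low = 1, mid = 2, high = 3)
  path <- matrix(FALSE, 3, 3, dimnames = list(names(means), names(means)))
  path["low", "mid"] <- path["mid", "low"] <- TRUE
  path["mid", "high"] <- path["high", "mid"] <- TRUE
  ld <- assign_letters(maximal_cliques(path), means)
  expect_equal(ld$letters[ld$condition == "low"], "a")
  expect_equal(ld$letters[ld$condition == "mid"], "ab")
  expect_equal(ld$letters[ld$condition == "high"], "b")

  complete <- matrix(TRUE, 3, 3, dimnames = list(names(means), names(means)))
  diag(complete) <- FALSE
  ldc <- assign_letters(maximal_cliques(complete), means)
  expect_true(all(ldc$letters == "a"))

  edgeless <- matrix(FALSE, 3, 3,
                     dimnames = list(names(means), names(means)))
  lde <- assign_letters(maximal_cliques(edgeless),
                        c(high = 3, low = 1, mid = 2))
  expect_equal(lde$letters[lde$condition == "low"], "a")
  expect_equal(lde$letters[lde$condition == "mid"], "b")
  expect_equal(lde$letters[lde$condition == "high"], "c")
})

test_that("two conditions share a letter exactly when the graph has the edge", {
  set.seed(123)
  for (i in 1:30) {
    n <- sample(3:7, 1)
    nodes <- sprintf("c%d", 1:n)
    adj <- matrix(runif(n * n) < 0.5, n, n)
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    dimnames(adj) <- list(nodes, nodes)
    means <- setNames(runif(n), nodes)
    ld <- assign_letters(maximal_cliques(adj), means)
    lab <- strsplit(setNames(ld$letters, ld$condition), "")
    for (a in nodes) for (b in nodes) if (a < b) {
      share <- length(intersect(lab[[a]], lab[[b]])) > 0
      expect_equal(share, unname(adj[a, b]))
    }
  }
})

test_that("permuting condition order changes letters but not the partition", {
  nodes <- c("p", "q", "r", "s")
  adj <- matrix(FALSE, 4, 4, dimnames = list(nodes, nodes))
  adj["p", "q"] <- adj["q", "p"] <- TRUE
  means <- c(p = 1, q = 2, r = 3, s = 4)
  ld1 <- assign_letters(maximal_cliques(adj), means)
  perm <- c("s", "q", "p", "r")
  ld2 <- assign_letters(maximal_cliques(adj[perm, perm]), means[perm])
  part <- function(ld) {
    lab <- strsplit(setNames(ld$letters, ld$condition), "")
    groups <- list()
    for (letter in unique(unlist(lab)))
      groups[[length(groups) + 1]] <-
        sort(names(lab)[vapply(lab, function(x) letter %in% x, TRUE)])
    groups[order(vapply(groups, paste, "", collapse = "+"))]
  }
  expect_identical(part(ld1), part(ld2))
})
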