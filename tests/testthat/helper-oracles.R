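# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Brute-force maximal cliques: enumerate every vertex subset, keep the
# complete ones that no outside vertex extends. Vectorized over subsets.
bf_cliques <- function(adj) {
  n <- nrow(adj)
  A <- (adj != 0) * 1
  diag(A) <- 0
  M <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  M <- M[rowSums(M) > 0, , drop = FALSE]
  inn <- M %*% A                       # neighbours inside the subset
  k <- rowSums(M)
  edges_in <- rowSums(inn * M) / 2
  is_clique <- edges_in == k * (k - 1) / 2
  extendable <- rowSums((inn == k) & (M == 0)) > 0
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  cl <- lapply(which(is_clique & !extendable),
               function(i) sort(nodes[M[i, ] == 1]))
  cl[order(vapply(cl, paste, "", collapse = "\r"))]
}

# Literal Benjamini-Hochberg step-up from the definition:
# q(i) = min over ranks j >= rank(i) of n * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Plain trapezoid sum, written as an explicit loop.
trap_oracle <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# Minimal single-cell trace data.frame for feature tests.
make_trace <- function(times, ratios, cell_id = "c1", line = "HT29",
                       treatment = "control", day = "d1",
                       coverslip = "cs1") {
  data.frame(cell_id = cell_id, day = day, coverslip = coverslip,
             line = line, treatment = treatment, time_s = times,
             ratio = ratios, stringsAsFactors = FALSE)
}

# Balanced four-condition feature table with Gaussian noise, for the
# grouping/mixed-model tests that do not need full trace simulation.
make_features <- function(n_per_condition, means = c(1, 1, 1, 1), sd = 1,
                          n_days = 2) {
  conds <- data.frame(line = c("NCM460", "NCM460", "HT29", "HT29"),
                      treatment = c("control", "DFMO", "control", "DFMO"),
                      mu = means, stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    data.frame(line = conds$line[i], treatment = conds$treatment[i],
               day = rep_len(sprintf("d%d", seq_len(n_days)),
                             n_per_condition),
               coverslip = rep_len(c("c1", "c2"), n_per_condition),
               y = stats::rnorm(n_per_condition, conds$mu[i], sd),
               stringsAsFactors = FALSE)
  }))
  rows
}

slim_de <- function(tab) tab[, c("gene", "q", "logFC")]
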