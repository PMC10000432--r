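#' Tukey-adjusted pairwise comparisons of condition marginal means
#'
#' Computes all pairwise differences of the condition marginal means of a
#' fitted condition model. Each difference carries its standard error,
#' Satterthwaite degrees of freedom (residual df for a fixed-effects fit),
#' raw two-sided p-value, and the Tukey-Kramer single-step adjusted p-value
#' from the studentized-range distribution with \code{k} means.
#'
#' @param fit A \code{ca_mixed_fit} from [fit_condition_model()].
#' @param alpha Significance level recorded for downstream grouping.
#' @return data.frame of class \code{ca_contrasts} with one row per
#'   unordered pair: \code{cond_a}, \code{cond_b}, \code{contrast},
#'   \code{estimate} (transformed scale, a minus b), \code{SE}, \code{df},
#'   \code{t}, \code{p_raw}, \code{p_adj}. Attributes: \code{alpha},
#'   \code{conditions}, \code{means} (back-transformed marginal means).
#' @export
pairwise_contrasts <- function(fit, alpha = 0.05) {
  L <- fit$L
  k <- nrow(L)
  if (k < 2) stop("need at least 2 conditions")
  if (any(!is.finite(fit$V)) ||
      inherits(try(solve(fit$V), silent = TRUE), "try-error"))
    stop("covariance of the marginal means is singular")
  pairs <- utils::combn(k, 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    Lc <- L[i1, ] - L[i2, ]
    if (fit$type == "lmer") {
      ct <- lmerTest::contest1D(fit$model, Lc)
      est <- ct[["Estimate"]]; se <- ct[["Std. Error"]]
      df <- ct[["df"]]; tval <- ct[["t value"]]
    } else {
      est <- drop(Lc %*% stats::coef(fit$model))
      se <- sqrt(drop(t(Lc) %*% stats::vcov(fit$model) %*% Lc))
      df <- stats::df.residual(fit$model)
      tval <- est / se
    }
    rows[[j]] <- data.frame(
      cond_a = rownames(L)[i1], cond_b = rownames(L)[i2],
      contrast = paste(rownames(L)[i1], "-", rownames(L)[i2]),
      estimate = est, SE = se, df = df, t = tval,
      p_raw = 2 * stats::pt(-abs(tval), df),
      p_adj = stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = df,
                            lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "conditions") <- rownames(L)
  means <- fit$emmeans$response_mean
  names(means) <- fit$emmeans$condition
  attr(out, "means") <- means
  class(out) <- c("ca_contrasts", "data.frame")
  out
}

#' Similarity graph of experimental conditions
#'
#' Conditions are nodes; an undirected edge joins two conditions when their
#' Tukey-adjusted p-value is at least \code{alpha}, i.e. when the comparison
#' failed to find a difference and the two conditions belong to the same
#' group.
#'
#' @param contrasts A \code{ca_contrasts} table covering all pairs.
#' @param alpha Significance level (default the one recorded on the table).
#' @return List of class \code{ca_simgraph} with \code{nodes} (character)
#'   and \code{adj} (logical adjacency matrix, no self loops).
#' @export
build_similarity_graph <- function(contrasts, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(contrasts, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  nodes <- attr(contrasts, "conditions")
  if (is.null(nodes)) nodes <- sort(unique(c(contrasts$cond_a,
                                             contrasts$cond_b)))
  k <- length(nodes)
  expected <- k * (k - 1) / 2
  key <- paste(pmin(contrasts$cond_a, contrasts$cond_b),
               pmax(contrasts$cond_a, contrasts$cond_b))
  if (nrow(contrasts) != expected || anyDuplicated(key))
    stop("contrast table must contain every unordered pair exactly once")
  adj <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(contrasts))) {
    e <- contrasts$p_adj[r] >= alpha
    adj[contrasts$cond_a[r], contrasts$cond_b[r]] <- e
    adj[contrasts$cond_b[r], contrasts$cond_a[r]] <- e
  }
  structure(list(nodes = nodes, adj = adj), class = "ca_simgraph")
}

#' All maximal cliques of a simple undirected graph
#'
#' Bron-Kerbosch enumeration with pivoting. Isolated vertices form singleton
#' maximal cliques, so an edgeless graph yields one clique per node. Cliques
#' are returned with members sorted in node order and the clique list in
#' lexicographic order, so the output is canonical.
#'
#' @param graph A \code{ca_simgraph}, or a logical/0-1 adjacency matrix with
#'   dimnames.
#' @return List of character vectors, one per maximal clique.
#' @export
maximal_cliques <- function(graph) {
  adj <- if (inherits(graph, "ca_simgraph")) graph$adj else as.matrix(graph)
  if (!isTRUE(all.equal(adj, t(adj))))
    stop("adjacency matrix must be symmetric")
  adj <- adj != 0
  diag(adj) <- FALSE
  n <- nrow(adj)
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  found <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      found[[length(found) + 1L]] <<- sort(R)
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    cand <- c(P, X)
    deg <- vapply(cand, function(u) sum(adj[u, P]), 0L)
    u <- cand[which.max(deg)]
    for (v in P[!adj[u, P]]) {
      nv <- which(adj[v, ])
      bk(c(R, v), intersect(P, nv), intersect(X, nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible()
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques <- lapply(found, function(ix) nodes[ix])
  keys <- vapply(cliques, paste, "", collapse = "\r")
  cliques[order(keys)]
}

#' Compact letter display from maximal cliques
#'
#' Orders the maximal cliques by the ascending mean of their members'
#' marginal means and assigns letters a, b, c, ... in that order. Each
#' condition receives the letters of every clique containing it, so two
#' conditions share a letter exactly when some maximal clique (a group of
#' mutually indistinguishable conditions) contains both.
#'
#' @param cliques List of character vectors from [maximal_cliques()].
#' @param means Named numeric of per-condition means (used only for
#'   ordering), e.g. \code{attr(contrasts, "means")} or
#'   \code{fit$emmeans$response_mean}.
#' @return data.frame of class \code{ca_letters} with columns
#'   \code{condition}, \code{mean}, \code{letters}; the ordered cliques are
#'   attached as attribute \code{"cliques"}.
#' @export
assign_letters <- function(cliques, means) {
  conds <- names(means)
  if (is.null(conds)) stop("means must be named by condition")
  covered <- unique(unlist(cliques))
  if (!all(conds %in% covered))
    stop("internal error: conditions ",
         paste(setdiff(conds, covered), collapse = ", "),
         " missing from every clique")
  cl_means <- vapply(cliques, function(cl) mean(means[cl]), 0)
  cliques <- cliques[order(cl_means)]
  if (length(cliques) > 26) stop("more than 26 cliques are not supported")
  letters_used <- letters[seq_along(cliques)]
  lab <- vapply(conds, function(cd) {
    paste(letters_used[vapply(cliques, function(cl) cd %in% cl, TRUE)],
          collapse = "")
  }, "")
  out <- data.frame(condition = conds, mean = unname(means),
                    letters = unname(lab), stringsAsFactors = FALSE)
  attr(out, "cliques") <- cliques
  class(out) <- c("ca_letters", "data.frame")
  out
}

#' One-call letter display for a fitted condition model
#'
#' Convenience wrapper: pairwise Tukey contrasts, similarity graph at
#' \code{alpha}, Bron-Kerbosch maximal cliques, and letter assignment.
#'
#' @param fit A \code{ca_mixed_fit}.
#' @param alpha Significance level (default 0.05).
#' @return A \code{ca_letters} table (see [assign_letters()]); the contrast
#'   table is attached as attribute \code{"contrasts"}.
#' @export
letter_display <- function(fit, alpha = 0.05) {
  ct <- pairwise_contrasts(fit, alpha = alpha)
  g <- build_similarity_graph(ct, alpha = alpha)
  cl <- maximal_cliques(g)
  out <- assign_letters(cl, attr(ct, "means"))
  attr(out, "contrasts") <- ct
  out
}
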