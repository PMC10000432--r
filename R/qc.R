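#' Sample-level principal component analysis
#'
#' PCA with samples as observations and genes as variables, on centered
#' (not gene-standardized) log2 data. Returns the scores, the ordered
#' variance fractions, and the number of leading components needed to
#' explain at least 70 percent of the variance (the PC70 rule).
#'
#' @param mat Normalized log2 matrix, genes x samples.
#' @param pc_threshold Cumulative variance target (default 0.70).
#' @return List: \code{scores} (samples x PCs), \code{var_explained}
#'   (fractions summing to 1), \code{n_pc} (minimal k with cumulative
#'   variance >= threshold), \code{threshold}.
#' @export
pca_scores <- function(mat, pc_threshold = 0.70) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) stop("constant matrix: no variance to decompose")
  ve <- pc$sdev^2 / tot
  n_pc <- which(cumsum(ve) >= pc_threshold)[1]
  list(scores = pc$x, var_explained = ve, n_pc = n_pc,
       threshold = pc_threshold)
}

#' Robust Mahalanobis outlier flags within class
#'
#' Within each class (the four line x treatment groups in practice),
#' estimates a robust center and scatter of the retained principal-component
#' scores by the minimum covariance determinant and flags samples whose
#' squared robust distance exceeds the chi-square quantile at
#' \code{coverage} with as many degrees of freedom as retained components.
#' Classes too small for the MCD fall back to the classical estimator with
#' a warning.
#'
#' @param pca Output of [pca_scores()] (or a scores matrix).
#' @param class_labels Factor/character, one label per sample.
#' @param n_pc Number of leading PCs to use; defaults to the PC70 choice.
#' @param coverage Chi-square coverage (default 0.975).
#' @return data.frame: \code{sample}, \code{class}, \code{dist2} (squared
#'   robust distance), \code{flag}, \code{estimator} ("mcd" or "classical").
#' @export
robust_outliers <- function(pca, class_labels, n_pc = NULL,
                            coverage = 0.975) {
  scores <- if (is.list(pca)) pca$scores else as.matrix(pca)
  if (is.null(n_pc)) n_pc <- if (is.list(pca)) pca$n_pc else ncol(scores)
  S <- scores[, seq_len(n_pc), drop = FALSE]
  cls <- factor(class_labels)
  if (length(cls) != nrow(S)) stop("one class label per sample is required")
  cut2 <- stats::qchisq(coverage, df = n_pc)
  out <- vector("list", nlevels(cls))
  for (i in seq_along(levels(cls))) {
    lv <- levels(cls)[i]
    rows <- which(cls == lv)
    sub <- S[rows, , drop = FALSE]
    est <- "mcd"
    rob <- tryCatch({
      # the MCD keeps ~half the points; below ~2(p+1) samples the discarded
      # half is always at extreme distance and every class flags spuriously
      if (nrow(sub) < 2 * (n_pc + 1)) stop("class too small for MCD")
      MASS::cov.rob(sub, method = "mcd")
    }, error = function(e) {
      warning("class ", lv, ": ", conditionMessage(e),
              "; falling back to the classical estimator", call. = FALSE)
      NULL
    })
    if (is.null(rob)) {
      est <- "classical"
      ctr <- colMeans(sub)
      cv <- stats::cov(sub)
    } else {
      ctr <- rob$center
      cv <- rob$cov
    }
    d2 <- stats::mahalanobis(sub, ctr, cv)
    out[[i]] <- data.frame(sample = rownames(S)[rows], class = lv,
                           dist2 = d2, flag = d2 > cut2, estimator = est,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ward hierarchical clustering on retained principal components
#'
#' Ward linkage (ward.D2, i.e. on squared Euclidean distances) over the
#' retained PC scores.
#'
#' @param pca Output of [pca_scores()] (or a scores matrix).
#' @param n_pc Number of leading PCs (defaults to the PC70 choice).
#' @param n_clusters Optional number of clusters at which to cut the tree.
#' @return List: \code{tree} (an \code{hclust}), \code{labels} (cluster
#'   labels when \code{n_clusters} is given, else NULL), \code{n_pc}.
#' @export
ward_clustering <- function(pca, n_pc = NULL, n_clusters = NULL) {
  scores <- if (is.list(pca)) pca$scores else as.matrix(pca)
  if (nrow(scores) < 2) stop("need at least 2 samples")
  if (is.null(n_pc)) n_pc <- if (is.list(pca)) pca$n_pc else ncol(scores)
  S <- scores[, seq_len(n_pc), drop = FALSE]
  tree <- stats::hclust(stats::dist(S), method = "ward.D2")
  labels <- if (!is.null(n_clusters)) stats::cutree(tree, k = n_clusters)
            else NULL
  list(tree = tree, labels = labels, n_pc = n_pc)
}

#' Relative log expression summaries per sample
#'
#' RLE values are the per-gene median-centered log2 intensities; a
#' well-behaved sample has an RLE distribution centered on 0. Samples whose
#' absolute median RLE exceeds the threshold are flagged.
#'
#' @param mat Normalized log2 matrix, genes x samples.
#' @param threshold Flag threshold on |median RLE| (default 0.1).
#' @return data.frame: \code{sample}, \code{rle_median}, \code{rle_iqr},
#'   \code{flag}.
#' @export
rle_stats <- function(mat, threshold = 0.1) {
  mat <- as.matrix(mat)
  med <- apply(mat, 1, stats::median)
  rle <- mat - med
  out <- data.frame(sample = colnames(mat),
                    rle_median = apply(rle, 2, stats::median),
                    rle_iqr = apply(rle, 2, stats::IQR),
                    stringsAsFactors = FALSE)
  out$flag <- abs(out$rle_median) > threshold
  rownames(out) <- NULL
  out
}

#' Full sample quality-control report
#'
#' PCA with PC70 selection, within-class robust Mahalanobis outlier flags,
#' Ward clustering, and RLE summaries, bundled into one report.
#'
#' @param mat Normalized log2 matrix, genes x samples.
#' @param sheet Sample sheet (\code{sample_id}, \code{line},
#'   \code{treatment}); classes are the line x treatment groups.
#' @param coverage,rle_threshold Passed through.
#' @return List of class \code{ca_qc_report}: \code{pca}, \code{outliers},
#'   \code{clustering}, \code{rle}, \code{flagged_samples}.
#' @export
qc_run <- function(mat, sheet, coverage = 0.975, rle_threshold = 0.1) {
  sheet <- sheet[match(colnames(mat), sheet$sample_id), ]
  classes <- paste(sheet$line, sheet$treatment, sep = ".")
  pca <- pca_scores(mat)
  outl <- robust_outliers(pca, classes, coverage = coverage)
  clus <- ward_clustering(pca, n_clusters = length(unique(classes)))
  rle <- rle_stats(mat, threshold = rle_threshold)
  flagged <- union(outl$sample[outl$flag], rle$sample[rle$flag])
  out <- list(pca = pca, outliers = outl, clustering = clus, rle = rle,
              flagged_samples = flagged)
  class(out) <- "ca_qc_report"
  out
}
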