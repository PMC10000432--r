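#' Quantile normalization of a log2 expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' reference distribution is the row-wise mean of the sorted columns, and
#' each column's values are replaced by the reference values at their ranks.
#' Ties within a column receive the mean of the reference values at the tied
#' ranks. The operation is idempotent.
#'
#' @param mat Numeric matrix, genes x samples, no missing values.
#' @return Normalized matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples")
  if (anyNA(mat)) stop("missing values are not allowed; refusing to impute")
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(x) {
    r <- rank(x, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Non-specific IQR filter with calcium-panel retention
#'
#' Keeps the genes whose interquartile range across samples is strictly
#' larger than the median of all IQRs — the usual non-specific variance
#' filter — but always retains the genes of the calcium-transport panel,
#' since those are the genes the analysis is about regardless of their
#' variability.
#'
#' @param mat Normalized log2 matrix, genes in rownames.
#' @param panel Optional panel data.frame (column \code{gene}) whose genes
#'   are never dropped.
#' @return List: \code{matrix} (filtered), \code{report} (named counts:
#'   \code{n_in}, \code{n_kept}, \code{n_dropped}, \code{n_panel_rescued}).
#' @export
iqr_filter <- function(mat, panel = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0) stop("empty expression matrix")
  iqrs <- apply(mat, 1, stats::IQR)
  keep <- iqrs > stats::median(iqrs)
  rescued <- rep(FALSE, nrow(mat))
  if (!is.null(panel)) {
    in_panel <- rownames(mat) %in% panel$gene
    rescued <- in_panel & !keep
    keep <- keep | in_panel
  }
  list(matrix = mat[keep, , drop = FALSE],
       report = c(n_in = nrow(mat), n_kept = sum(keep),
                  n_dropped = sum(!keep), n_panel_rescued = sum(rescued)))
}

validate_sample_sheet <- function(mat, sheet) {
  need <- c("sample_id", "line", "treatment", "day")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  if (is.null(colnames(mat)))
    stop("expression matrix needs sample ids as column names")
  if (!all(colnames(mat) %in% sheet$sample_id))
    stop("every sample in the matrix needs a sample-sheet row")
  sheet <- sheet[match(colnames(mat), sheet$sample_id), ]
  sheet$line <- factor(sheet$line, levels = c("NCM460", "HT29"))
  sheet$treatment <- factor(sheet$treatment, levels = c("control", "DFMO"))
  sheet$day <- factor(sheet$day)
  if (anyNA(sheet$line) || anyNA(sheet$treatment))
    stop("line must be NCM460/HT29 and treatment control/DFMO")
  tab <- table(sheet$day, sheet$line, sheet$treatment)
  if (any(tab > 1))
    stop("each day may contain at most one replicate per condition")
  sheet
}

#' Gene-wise factorial linear model fits
#'
#' Fits, by least squares and gene by gene, the model
#' \code{log2Expression ~ line + treatment + line:treatment + day}, with day
#' as a fixed blocking factor (one replicate per condition per day makes
#' the fixed-block fit the identifiable standard choice). Returns the four
#' contrasts of interest with their unscaled standard errors, the per-gene
#' residual variance and its degrees of freedom.
#'
#' Contrast sign conventions: \code{line} is HT29 minus NCM460 (in control
#' cells), \code{treatment_NCM460} and \code{treatment_HT29} are DFMO minus
#' control within the named line, and \code{interaction} is the difference
#' of the two treatment effects.
#'
#' @param mat log2 expression matrix, genes x samples.
#' @param sheet Sample sheet (\code{sample_id}, \code{line},
#'   \code{treatment}, \code{day}), one row per matrix column.
#' @return List of class \code{ca_genefits}: \code{est} (genes x 4 contrast
#'   estimates), \code{u} (length-4 unscaled SEs), \code{s2} (per-gene
#'   residual variance), \code{df} (residual df), \code{design},
#'   \code{contrasts} (coefficient-to-contrast matrix), \code{genes}.
#' @export
fit_gene_linear_models <- function(mat, sheet) {
  mat <- as.matrix(mat)
  sheet <- validate_sample_sheet(mat, sheet)
  X <- stats::model.matrix(~ line * treatment + day, data = sheet)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; confounded columns: ",
         paste(dropped, collapse = ", "))
  }
  if (nrow(X) - ncol(X) < 1) stop("design leaves no residual df")
  Y <- t(mat)                               # samples x genes
  beta <- qr.coef(qrX, Y)                   # p x G
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df

  cn <- colnames(X)
  Cmat <- matrix(0, nrow = ncol(X), ncol = 4,
                 dimnames = list(cn, c("line", "treatment_NCM460",
                                       "treatment_HT29", "interaction")))
  Cmat["lineHT29", "line"] <- 1
  Cmat["treatmentDFMO", "treatment_NCM460"] <- 1
  Cmat["treatmentDFMO", "treatment_HT29"] <- 1
  Cmat["lineHT29:treatmentDFMO", "treatment_HT29"] <- 1
  Cmat["lineHT29:treatmentDFMO", "interaction"] <- 1

  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(cn, cn)
  u <- sqrt(diag(t(Cmat) %*% XtXinv %*% Cmat))
  est <- t(t(Cmat) %*% beta)                # G x 4
  rownames(est) <- rownames(mat)
  out <- list(est = est, u = u, s2 = s2, df = df, design = X,
              contrasts = Cmat, genes = rownames(mat))
  class(out) <- "ca_genefits"
  out
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (!is.finite(x) || x <= 0) return(0.5 + 1 / yi)
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, 0)
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Shrinks the per-gene residual variances toward a common prior, in the
#' moderated t-statistic tradition. The prior degrees of freedom \code{d0}
#' and prior variance \code{s0^2} are estimated by moment matching of
#' \code{log(s_g^2)} to a scaled-F model via the digamma/trigamma moment
#' equations; the posterior variance is
#' \code{(d0 s0^2 + d s_g^2) / (d0 + d)} and moderated t-statistics use
#' \code{d0 + d} degrees of freedom. When the observed log-variances are no
#' more dispersed than chi-square sampling predicts, \code{d0} is infinite
#' and every posterior variance equals \code{s0^2} (normal reference).
#'
#' @param fits A \code{ca_genefits} from [fit_gene_linear_models()].
#' @param d0,s0 Optional manual overrides for the prior df and prior SD
#'   (\code{d0 = 0} reproduces ordinary t-statistics exactly).
#' @return List of class \code{ca_moderated}: everything in \code{fits} plus
#'   \code{d0}, \code{s02}, \code{s2_post} (per gene), \code{df_total},
#'   \code{t} and \code{p} (genes x 4 matrices).
#' @export
ebayes_moderate <- function(fits, d0 = NULL, s0 = NULL) {
  s2 <- fits$s2
  d <- fits$df
  if (length(s2) < 10 && is.null(d0))
    stop("need at least 10 genes to estimate the variance prior")
  ok <- s2 > 0
  if (is.null(d0) || is.null(s0)) {
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.null(d0)) {
      if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
      } else {
        warning("log-variances underdispersed; using an infinite prior df")
        d0 <- Inf
      }
    }
    if (is.null(s0)) {
      s02 <- if (is.finite(d0) && d0 > 0)
        exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      else exp(mean(e))
    } else s02 <- s0^2
  } else s02 <- s0^2

  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  tmat <- fits$est / (outer(sqrt(s2_post), fits$u))
  pmat <- if (is.infinite(df_total))
    2 * stats::pnorm(-abs(tmat))
  else
    2 * stats::pt(-abs(tmat), df = df_total)
  out <- c(fits, list(d0 = d0, s02 = s02, s2_post = s2_post,
                      df_total = df_total, t = tmat, p = pmat))
  class(out) <- "ca_moderated"
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity; the input order is
#' preserved.
#'
#' @param pvals Numeric vector of p-values in \code{[0, 1]}.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pvals)
  if (n == 0) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * pvals[o]))
  q[ro]
}

#' Per-contrast differential-expression tables
#'
#' Builds, for each of the four contrasts, a table with the log2 fold
#' change, its confidence interval, moderated t, raw p, BH q-value and a
#' significance flag at the chosen FDR. Panel genes are annotated with
#' their category; \code{panel_only = TRUE} restricts the table to the
#' panel.
#'
#' @param moderated A \code{ca_moderated} from [ebayes_moderate()].
#' @param panel Optional panel data.frame (\code{gene}, \code{category}).
#' @param fdr FDR threshold for the significance flag (default 0.05).
#' @param panel_only Restrict output to panel genes.
#' @param conf_level Confidence level for the logFC interval.
#' @return Named list of data.frames (one per contrast), class
#'   \code{ca_de_tables}. Sign conventions: line is HT29 - NCM460,
#'   treatment contrasts are DFMO - control.
#' @export
make_contrast_tables <- function(moderated, panel = NULL, fdr = 0.05,
                                 panel_only = FALSE, conf_level = 0.95) {
  genes <- moderated$genes
  cats <- rep(NA_character_, length(genes))
  if (!is.null(panel))
    cats <- as.character(panel$category[match(genes, panel$gene)])
  tq <- if (is.infinite(moderated$df_total))
    stats::qnorm(1 - (1 - conf_level) / 2)
  else stats::qt(1 - (1 - conf_level) / 2, df = moderated$df_total)
  out <- lapply(colnames(moderated$est), function(cn) {
    se <- sqrt(moderated$s2_post) * moderated$u[[cn]]
    tab <- data.frame(gene = genes, category = cats,
                      logFC = moderated$est[, cn],
                      CI_low = moderated$est[, cn] - tq * se,
                      CI_high = moderated$est[, cn] + tq * se,
                      t_mod = moderated$t[, cn],
                      p = moderated$p[, cn],
                      q = bh_fdr(moderated$p[, cn]),
                      stringsAsFactors = FALSE)
    tab$significant <- tab$q < fdr
    if (panel_only) tab <- tab[!is.na(tab$category), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
  names(out) <- colnames(moderated$est)
  class(out) <- c("ca_de_tables", class(out))
  out
}

#' Full differential-expression run on one platform
#'
#' Quantile normalization, IQR filtering with panel retention, gene-wise
#' factorial fits, empirical-Bayes moderation, and per-contrast tables.
#'
#' @param mat log2 expression matrix, genes x samples.
#' @param sheet Sample sheet.
#' @param panel Optional gene panel.
#' @param normalize,filter Toggle the preprocessing steps.
#' @param fdr FDR threshold for significance flags.
#' @return List: \code{tables} (per-contrast DE tables), \code{moderated},
#'   \code{filter_report}.
#' @export
de_run <- function(mat, sheet, panel = NULL, normalize = TRUE,
                   filter = TRUE, fdr = 0.05) {
  if (normalize) mat <- quantile_normalize(mat)
  report <- NULL
  if (filter) {
    fl <- iqr_filter(mat, panel)
    mat <- fl$matrix
    report <- fl$report
  }
  fits <- fit_gene_linear_models(mat, sheet)
  mod <- ebayes_moderate(fits)
  list(tables = make_contrast_tables(mod, panel, fdr = fdr),
       moderated = mod, filter_report = report)
}
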