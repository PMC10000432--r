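#' Per-sample delta-Ct values
#'
#' For every gene and sample, averages the replicate threshold cycles and
#' subtracts the housekeeping gene's replicate mean from the same sample:
#' \code{dCt = mean(Ct_gene) - mean(Ct_housekeeping)}. Relative abundance is
#' \code{2^(-dCt)} (Livak convention: lower Ct means more template).
#'
#' @param ct_table data.frame with columns \code{gene}, \code{group},
#'   \code{sample}, \code{replicate}, \code{ct}.
#' @param housekeeping Housekeeping gene id (default \code{"RP18S"}), which
#'   must be measured in every sample.
#' @param aggregate Replicate aggregation, \code{"mean"} (default) or
#'   \code{"median"}.
#' @return data.frame: \code{gene}, \code{group}, \code{sample},
#'   \code{delta_ct}, \code{rel_abundance}.
#' @export
delta_ct <- function(ct_table, housekeeping = "RP18S",
                     aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  need <- c("gene", "group", "sample", "replicate", "ct")
  if (!all(need %in% names(ct_table)))
    stop("Ct table must have columns ", paste(need, collapse = ", "))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  agg <- if (aggregate == "mean") mean else stats::median
  hk <- ct_table[ct_table$gene == housekeeping, ]
  if (nrow(hk) == 0)
    stop("housekeeping gene ", housekeeping, " not found in the table")
  hk_mean <- tapply(hk$ct, hk$sample, agg)
  tg <- ct_table[ct_table$gene != housekeeping, ]
  if (!all(tg$sample %in% names(hk_mean)))
    stop("housekeeping gene missing for samples: ",
         paste(setdiff(unique(tg$sample), names(hk_mean)), collapse = ", "))
  key <- paste(tg$gene, tg$group, tg$sample, sep = "\r")
  gene_mean <- tapply(tg$ct, key, agg)
  parts <- do.call(rbind, strsplit(names(gene_mean), "\r", fixed = TRUE))
  out <- data.frame(gene = parts[, 1], group = parts[, 2],
                    sample = parts[, 3],
                    delta_ct = as.vector(gene_mean) -
                      as.vector(hk_mean[parts[, 3]]),
                    stringsAsFactors = FALSE)
  out$rel_abundance <- 2^(-out$delta_ct)
  out <- out[order(out$gene, out$group, out$sample), ]
  rownames(out) <- NULL
  out
}

#' Delta-delta-Ct fold change between two groups
#'
#' \code{ddCt = mean(dCt_test) - mean(dCt_calibrator)}; the reported log2
#' fold change is \code{-ddCt}, so 0 means no change, positive values mean
#' higher expression in the test group, and negative values lower.
#'
#' @param dct_test,dct_calibrator Numeric vectors of per-sample delta-Ct
#'   values for the test and calibrator groups.
#' @return List: \code{ddct}, \code{log2_fold} (= -ddct), \code{fold}
#'   (= 2^-ddct), \code{sem} (standard error of the difference).
#' @export
ddct_fold_change <- function(dct_test, dct_calibrator) {
  if (length(dct_test) == 0 || length(dct_calibrator) == 0)
    stop("both groups must be non-empty")
  ddct <- mean(dct_test) - mean(dct_calibrator)
  sem <- sqrt(stats::var(dct_test) / length(dct_test) +
                stats::var(dct_calibrator) / length(dct_calibrator))
  if (length(dct_test) < 2 || length(dct_calibrator) < 2) sem <- NA_real_
  list(ddct = ddct, log2_fold = -ddct, fold = 2^(-ddct), sem = sem)
}

#' Two-sample t-test on delta-Ct values with Bonferroni correction
#'
#' Student's t-test (equal variances) for two independent samples of
#' delta-Ct values; the p-value is multiplied by the number of genes tested
#' in the experiment and capped at 1.
#'
#' @param dct_test,dct_calibrator Numeric vectors, each of length >= 2.
#' @param n_genes_tested Bonferroni multiplier (number of genes on the
#'   plate, default 1).
#' @return List: \code{p}, \code{p_adjusted}, \code{t}, \code{df}.
#' @export
ddct_test <- function(dct_test, dct_calibrator, n_genes_tested = 1) {
  if (length(dct_test) < 2 || length(dct_calibrator) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(dct_test) == 0 && stats::sd(dct_calibrator) == 0) {
    sep <- mean(dct_test) != mean(dct_calibrator)
    p <- if (sep) 0 else 1
    return(list(p = p, p_adjusted = min(1, p * n_genes_tested),
                t = if (sep) Inf else 0,
                df = length(dct_test) + length(dct_calibrator) - 2))
  }
  tt <- stats::t.test(dct_test, dct_calibrator, var.equal = TRUE)
  list(p = tt$p.value,
       p_adjusted = min(1, tt$p.value * n_genes_tested),
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Full delta-delta-Ct analysis of a Ct table
#'
#' Housekeeping-normalized delta-Ct per sample, delta-delta-Ct fold change
#' of every gene between a test and a calibrator group, and Student's
#' t-tests with Bonferroni correction across the genes tested.
#'
#' @param ct_table As in [delta_ct()].
#' @param test_group,calibrator_group Group labels to compare.
#' @param housekeeping Housekeeping gene id (default \code{"RP18S"}).
#' @param n_genes_tested Bonferroni multiplier; defaults to the number of
#'   non-housekeeping genes in the table.
#' @param aggregate Replicate aggregation passed to [delta_ct()].
#' @return data.frame per gene: \code{gene}, \code{ddct}, \code{log2_fold},
#'   \code{sem}, \code{p}, \code{p_adjusted}, \code{significant} (at 0.05
#'   after correction).
#' @export
qpcr_run <- function(ct_table, test_group, calibrator_group,
                     housekeeping = "RP18S", n_genes_tested = NULL,
                     aggregate = "mean") {
  dct <- delta_ct(ct_table, housekeeping = housekeeping,
                  aggregate = aggregate)
  genes <- sort(unique(dct$gene))
  if (is.null(n_genes_tested)) n_genes_tested <- length(genes)
  rows <- lapply(genes, function(g) {
    dt <- dct$delta_ct[dct$gene == g & dct$group == test_group]
    dc <- dct$delta_ct[dct$gene == g & dct$group == calibrator_group]
    fc <- ddct_fold_change(dt, dc)
    ts <- ddct_test(dt, dc, n_genes_tested = n_genes_tested)
    data.frame(gene = g, ddct = fc$ddct, log2_fold = fc$log2_fold,
               sem = fc$sem, p = ts$p, p_adjusted = ts$p_adjusted,
               significant = ts$p_adjusted < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
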