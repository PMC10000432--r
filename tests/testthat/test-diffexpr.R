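make_sheet <- function(n_days = 4) {
  sheet <- expand.grid(line = c("NCM460", "HT29"),
                       treatment = c("control", "DFMO"),
                       day = sprintf("d%d", seq_len(n_days)),
                       stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("s%02d", seq_len(nrow(sheet)))
  sheet[, c("sample_id", "line", "treatment", "day")]
}

test_that("quantile normalization matches the hand-computed reference", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 6, 8))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 4, 5.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 4, 5.5))
  # identical columns are unchanged
  m2 <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2)
  # postcondition: all columns share one sorted vector, exactly
  set.seed(4)
  m3 <- matrix(rnorm(600), 100, 6)
  qn3 <- quantile_normalize(m3)
  sorted <- apply(qn3, 2, sort)
  expect_true(all(sorted == sorted[, 1]))
  expect_error(quantile_normalize(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("quantile normalization is idempotent and matches limma", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- matrix(rnorm(1200), 200, 6)
  qn <- quantile_normalize(m)
  # tie-free data: exactly idempotent
  expect_identical(quantile_normalize(qn), qn)
  expect_equal(qn, limma::normalizeQuantiles(m, ties = TRUE),
               tolerance = 1e-10)
  # duplicated rows create within-column ties; the tie rule (tied entries
  # share the mean of the reference at the tied ranks) matches limma exactly
  m2 <- m
  m2[5, ] <- m2[7, ]
  expect_equal(quantile_normalize(m2),
               limma::normalizeQuantiles(m2, ties = TRUE),
               tolerance = 1e-10)
})

test_that("IQR filter keeps high-variance genes and rescues panel genes", {
  m <- rbind(g1 = 0 * c(0, 1, 2, 3), g2 = 1 * c(0, 1, 2, 3),
             g3 = 2 * c(0, 1, 2, 3), g4 = 3 * c(0, 1, 2, 3))
  colnames(m) <- paste0("s", 1:4)
  fl <- iqr_filter(m)
  expect_equal(rownames(fl$matrix), c("g3", "g4"))
  expect_equal(unname(fl$report["n_kept"]), 2)

  # constant panel gene survives
  m2 <- rbind(m, TRPV6 = rep(5, 4))
  fl2 <- iqr_filter(m2, panel = data.frame(gene = "TRPV6"))
  expect_true("TRPV6" %in% rownames(fl2$matrix))
  expect_equal(unname(fl2$report["n_panel_rescued"]), 1)

  # all-identical IQRs: strict inequality keeps only panel genes
  m3 <- matrix(rep(c(0, 1, 2, 3), each = 5), 5, 4,
               dimnames = list(paste0("h", 1:5), paste0("s", 1:4)))
  fl3 <- iqr_filter(m3, panel = data.frame(gene = "h2"))
  expect_equal(rownames(fl3$matrix), "h2")
  expect_error(iqr_filter(m3[0, ]), "empty")
})

test_that("gene-wise fits recover planted coefficients and match OLS", {
  sheet <- make_sheet()
  # noiseless planted matrix
  a <- 1.5; cc <- -2
  is_h <- as.numeric(sheet$line == "HT29")
  is_d <- as.numeric(sheet$treatment == "DFMO")
  gene1 <- 6 + a * is_h + cc * is_h * is_d
  m <- rbind(gene1 = gene1, gene2 = rep(3, 16))
  colnames(m) <- sheet$sample_id
  fits <- fit_gene_linear_models(m, sheet)
  expect_equal(unname(fits$est["gene1", ]),
               c(a, 0, cc, cc), tolerance = 1e-10)
  expect_equal(fits$df, 16 - 7)

  # random genes against an explicit normal-equations oracle
  set.seed(12)
  m2 <- matrix(rnorm(50 * 16, 7), 50, 16,
               dimnames = list(sprintf("g%02d", 1:50), sheet$sample_id))
  fits2 <- fit_gene_linear_models(m2, sheet)
  X <- model.matrix(~ line * treatment + day,
                    transform(sheet,
                              line = factor(line, c("NCM460", "HT29")),
                              treatment = factor(treatment,
                                                 c("control", "DFMO")),
                              day = factor(day)))
  XtXi <- solve(t(X) %*% X)
  for (g in c(1, 17, 50)) {
    beta <- XtXi %*% t(X) %*% m2[g, ]
    expect_equal(unname(fits2$est[g, "line"]),
                 unname(beta["lineHT29", 1]), tolerance = 1e-8)
    expect_equal(unname(fits2$est[g, "treatment_HT29"]),
                 unname(beta["treatmentDFMO", 1] +
                          beta["lineHT29:treatmentDFMO", 1]),
                 tolerance = 1e-8)
    res <- m2[g, ] - drop(X %*% beta)
    expect_equal(unname(fits2$s2[g]), sum(res^2) / (16 - 7),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are refused with the confounded column", {
  sheet <- make_sheet(2)
  # make day coincide with line: d1 carries all NCM460, d2 all HT29
  sheet$day <- ifelse(sheet$line == "NCM460", "d1", "d2")
  sheet <- sheet[!duplicated(paste(sheet$line, sheet$treatment, sheet$day)), ]
  m <- matrix(rnorm(10 * nrow(sheet)), 10,
              dimnames = list(NULL, sheet$sample_id))
  expect_error(fit_gene_linear_models(m, sheet), "rank deficient")
})

test_that("duplicate condition-day replicates are refused", {
  sheet <- make_sheet(2)
  sheet$day <- "d1"
  m <- matrix(rnorm(5 * nrow(sheet)), 5,
              dimnames = list(NULL, sheet$sample_id))
  expect_error(fit_gene_linear_models(m, sheet), "at most one replicate")
})

test_that("moderation limits: d0 = 0 gives ordinary t, equal s2 gives normal", {
  sheet <- make_sheet()
  set.seed(3)
  m <- matrix(rnorm(100 * 16), 100, 16,
              dimnames = list(sprintf("g%03d", 1:100), sheet$sample_id))
  fits <- fit_gene_linear_models(m, sheet)
  stopifnot(fits$df == 9)
  mod0 <- ebayes_moderate(fits, d0 = 0)
  t_ord <- fits$est / outer(sqrt(fits$s2), fits$u)
  expect_equal(mod0$t, t_ord, tolerance = 1e-12)
  expect_equal(mod0$df_total, fits$df)

  # identical variances: infinite prior df branch, t = contrast / (u * s0)
  mod_inf <- suppressWarnings(ebayes_moderate({
    f2 <- fits
    f2$s2 <- rep(0.04, 100)
    f2
  }))
  expect_true(is.infinite(mod_inf$d0))
  expect_equal(mod_inf$t,
               fits$est / outer(rep(sqrt(mod_inf$s02), 100), fits$u),
               tolerance = 1e-12)
})

test_that("moderation recovers a known variance prior and matches limma", {
  skip_if_not_installed("limma")
  sheet <- make_sheet()
  set.seed(21)
  G <- 600
  d0_true <- 8
  s2_g <- 0.05 * d0_true / rchisq(G, d0_true)   # s0^2 = 0.05, d0 = 8
  m <- matrix(rnorm(G * 16, 0, rep(sqrt(s2_g), 16)), G, 16,
              dimnames = list(sprintf("g%03d", 1:G), sheet$sample_id))
  m <- m + 7
  fits <- fit_gene_linear_models(m, sheet)
  mod <- ebayes_moderate(fits)
  expect_gt(mod$d0, 4)
  expect_lt(mod$d0, 16)
  expect_equal(mod$s02, 0.05, tolerance = 0.3)

  X <- fits$design
  lf <- limma::lmFit(m, X)
  cm <- matrix(0, ncol(X), 1, dimnames = list(colnames(X), "th"))
  cm["treatmentDFMO", 1] <- 1
  cm["lineHT29:treatmentDFMO", 1] <- 1
  lf2 <- limma::eBayes(limma::contrasts.fit(lf, cm))
  expect_equal(mod$d0, lf2$df.prior, tolerance = 0.15)
  expect_equal(mod$s02, lf2$s2.prior, tolerance = 0.05)
  expect_equal(unname(mod$t[, "treatment_HT29"]), unname(lf2$t[, 1]),
               tolerance = 0.02)
})

test_that("BH adjustment matches the worked example and stays monotone", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(5)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_gte(min(q), min(p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("contrast tables flag planted genes with the right sign", {
  sheet <- make_sheet()
  set.seed(30)
  panel <- calcium_gene_panel()
  G <- 200
  genes <- c("TRPV6", sprintf("g%03d", 1:(G - 1)))
  m <- matrix(rnorm(G * 16, 7, 0.2), G, 16,
              dimnames = list(genes, sheet$sample_id))
  up <- as.numeric(sheet$line == "HT29" & sheet$treatment == "DFMO")
  m["TRPV6", ] <- m["TRPV6", ] + 3 * up
  fits <- fit_gene_linear_models(m, sheet)
  mod <- suppressWarnings(ebayes_moderate(fits))
  tabs <- make_contrast_tables(mod, panel)
  th <- tabs$treatment_HT29
  expect_true(th$significant[th$gene == "TRPV6"])
  expect_gt(th$logFC[th$gene == "TRPV6"], 0)
  expect_equal(th$category[th$gene == "TRPV6"], "TRP")
  expect_false(any(th$significant[th$gene != "TRPV6"] &
                     abs(th$logFC[th$gene != "TRPV6"]) > 1))
  # q threshold 0 flags nothing
  tabs0 <- make_contrast_tables(mod, panel, fdr = 0)
  expect_false(any(tabs0$treatment_HT29$significant))
  expect_true(all(th$q >= th$p))
})
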