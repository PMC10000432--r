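#' Configuration for the paired-platform expression simulator
#'
#' Emulates the transcriptomic arm of the experiment: a 2 x 2 factorial
#' (cell line x treatment) with one replicate of every condition processed
#' on each of \code{n_days} days (a random day block), measured by two
#' pseudo-technologies. Platform A draws each gene from the factorial linear
#' model with Gaussian noise; platform B observes the same underlying truth
#' through a gain/offset distortion plus independent noise, emulating a
#' second technology at the summary-statistics level.
#'
#' The default planted truth mirrors the study outcome over the calcium
#' panel: 17 panel genes carry a DFMO effect in the cancer line only, 11 of
#' which reverse a nonzero cancer-vs-normal effect (opposite signs), the
#' remaining 6 being treatment-affected without reversal. Additionally a
#' fraction of background genes carry a line (cancer) effect and a smaller
#' fraction an HT29-only treatment effect, reproducing the strong treatment
#' selectivity for cancer cells. The treatment never affects the normal
#' line in the default truth.
#'
#' @param n_genes Total genes, panel included (default 2000).
#' @param n_days Days = replicates per condition (default 4).
#' @param effect_line Magnitude of background cancer effects (log2 units,
#'   default 1.5).
#' @param effect_panel Magnitude of planted panel effects (default 2).
#' @param fraction_de Fraction of background genes with a line effect
#'   (default 0.2).
#' @param fraction_interaction Fraction of background genes with an
#'   HT29-only treatment effect (default 0.1).
#' @param sigma_a Residual SD of platform A (default 0.25).
#' @param sigma_day SD of the day block effect (default 0.15).
#' @param gain,offset,sigma_b Platform B distortion: observed value is
#'   \code{gain * truth + offset + N(0, sigma_b)} (defaults 1.1, 0.3, 0.3).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 abundance
#'   distribution (defaults 7, 1.5).
#' @param panel Gene panel data.frame (default [calcium_gene_panel()]).
#' @param reversal_genes Panel genes planted as reversals; warned about and
#'   kept if not in the panel.
#' @param affected_genes Panel genes with a treatment effect but no
#'   reversal requirement.
#' @param seed Integer seed.
#' @return List of class \code{expr_sim_config}.
#' @export
expr_sim_config <- function(n_genes = 2000L,
                            n_days = 4L,
                            effect_line = 1.5,
                            effect_panel = 2,
                            fraction_de = 0.2,
                            fraction_interaction = 0.1,
                            sigma_a = 0.25,
                            sigma_day = 0.15,
                            gain = 1.1,
                            offset = 0.3,
                            sigma_b = 0.3,
                            baseline_mean = 7,
                            baseline_sd = 1.5,
                            panel = calcium_gene_panel(),
                            reversal_genes = NULL,
                            affected_genes = NULL,
                            seed = 1L) {
  if (is.null(reversal_genes))
    reversal_genes <- c("CRACR2A", "ORMDL3", "SEPTIN6", "SEPTIN7",
                        "SEPTIN8", "SEPTIN11", "TRPC5", "TRPV6",
                        "PMCA4", "SPCA2", "VDAC3")
  if (is.null(affected_genes))
    affected_genes <- c("STIM1", "STIM2", "MCU", "TRPC1", "TRPP1", "TRPP2")
  if (any(c(fraction_de, fraction_interaction) < 0) ||
      any(c(fraction_de, fraction_interaction) > 1))
    stop("fractions must lie in [0, 1]")
  missing_panel <- setdiff(c(reversal_genes, affected_genes), panel$gene)
  if (length(missing_panel) > 0)
    warning("planted genes not in the panel (kept): ",
            paste(missing_panel, collapse = ", "))
  if (length(intersect(reversal_genes, affected_genes)) > 0)
    stop("reversal and affected gene lists must be disjoint")
  if (n_genes < nrow(panel))
    stop("n_genes must be at least the panel size")
  cfg <- list(n_genes = as.integer(n_genes), n_days = as.integer(n_days),
              effect_line = effect_line, effect_panel = effect_panel,
              fraction_de = fraction_de,
              fraction_interaction = fraction_interaction,
              sigma_a = sigma_a, sigma_day = sigma_day,
              gain = gain, offset = offset, sigma_b = sigma_b,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              panel = panel, reversal_genes = reversal_genes,
              affected_genes = affected_genes, seed = as.integer(seed))
  class(cfg) <- "expr_sim_config"
  cfg
}

# Gene status from planted coefficients (b is the NCM460 treatment effect,
# b + c the HT29 one; b = 0 throughout the default truth).
truth_status <- function(a, b, c) {
  treat_ht29 <- b + c
  status <- rep("null", length(a))
  status[a != 0] <- "DE-cancer"
  status[treat_ht29 != 0] <- "DE-treatment"
  status[a != 0 & treat_ht29 != 0 & sign(a) == -sign(treat_ht29)] <-
    "reversed"
  status
}

#' Simulate a paired-platform expression experiment
#'
#' Draws both platforms from a shared planted truth under the configured
#' design (see [expr_sim_config()]). Platform A is the factorial
#' linear-model draw; platform B is \code{gain * truth + offset} plus its
#' own noise, sharing the design, the day effects and the planted
#' coefficients.
#'
#' @param config An [expr_sim_config()].
#' @return List: \code{platform_a}, \code{platform_b} (genes x samples log2
#'   matrices), \code{sheet} (sample sheet: \code{sample_id}, \code{line},
#'   \code{treatment}, \code{day}), \code{truth} (per-gene data.frame with
#'   the planted \code{a} (line), \code{b} (treatment in NCM460), \code{c}
#'   (interaction) coefficients and \code{status} in null / DE-cancer /
#'   DE-treatment / reversed).
#' @export
simulate_expression_pair <- function(config) {
  set.seed(config$seed)
  panel_genes <- config$panel$gene
  n_bg <- config$n_genes - length(panel_genes)
  genes <- c(panel_genes,
             sprintf("gene%05d", seq_len(max(0, n_bg))))

  sheet <- expand.grid(line = c("NCM460", "HT29"),
                       treatment = c("control", "DFMO"),
                       day = sprintf("d%d", seq_len(config$n_days)),
                       stringsAsFactors = FALSE)
  sheet <- sheet[order(sheet$day, sheet$line, sheet$treatment), ]
  sheet$sample_id <- sprintf("s%02d", seq_len(nrow(sheet)))
  sheet <- sheet[, c("sample_id", "line", "treatment", "day")]
  rownames(sheet) <- NULL

  G <- length(genes)
  a <- b <- cc <- stats::setNames(numeric(G), genes)

  # planted panel truth: 11 reversals (opposite-sign line and interaction
  # effects) and 6 treatment-affected genes without reversal
  eff <- config$effect_panel
  down_in_cancer <- c("CRACR2A", "ORMDL3", "SEPTIN6", "SEPTIN7", "SEPTIN8",
                      "SEPTIN11", "PMCA4", "VDAC3")
  for (g in intersect(config$reversal_genes, genes)) {
    a[g] <- if (g %in% down_in_cancer) -eff else eff
    cc[g] <- -a[g]
  }
  same_sign_affected <- c("STIM1", "STIM2", "MCU")
  for (g in intersect(config$affected_genes, genes)) {
    if (g %in% same_sign_affected) {
      a[g] <- eff
      cc[g] <- eff
    } else {
      a[g] <- 0
      cc[g] <- if (g %in% c("TRPC1", "TRPP1")) -eff else eff
    }
  }

  # background truth: line effects and HT29-only treatment effects
  bg <- setdiff(genes, c(config$reversal_genes, config$affected_genes,
                         panel_genes))
  n_line <- round(config$fraction_de * length(bg))
  n_int <- round(config$fraction_interaction * length(bg))
  line_bg <- sample(bg, n_line)
  a[line_bg] <- config$effect_line *
    sample(c(-1, 1), n_line, replace = TRUE)
  int_bg <- sample(bg, n_int)
  cc[int_bg] <- config$effect_panel *
    sample(c(-1, 1), n_int, replace = TRUE)

  mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  is_ht29 <- as.numeric(sheet$line == "HT29")
  is_dfmo <- as.numeric(sheet$treatment == "DFMO")
  day_idx <- as.integer(factor(sheet$day))
  day_eff <- stats::rnorm(config$n_days, 0, config$sigma_day)

  truth_mat <- outer(mu, rep(1, nrow(sheet))) +
    outer(a, is_ht29) + outer(b, is_dfmo) + outer(cc, is_ht29 * is_dfmo) +
    outer(rep(1, G), day_eff[day_idx])
  dimnames(truth_mat) <- list(genes, sheet$sample_id)

  platform_a <- truth_mat +
    matrix(stats::rnorm(length(truth_mat), 0, config$sigma_a), nrow = G)
  platform_b <- config$gain * truth_mat + config$offset +
    matrix(stats::rnorm(length(truth_mat), 0, config$sigma_b), nrow = G)
  dimnames(platform_a) <- dimnames(platform_b) <- dimnames(truth_mat)

  truth <- data.frame(gene = genes, a = unname(a), b = unname(b),
                      c = unname(cc),
                      status = truth_status(a, b, cc),
                      in_panel = genes %in% panel_genes,
                      stringsAsFactors = FALSE)
  list(platform_a = platform_a, platform_b = platform_b, sheet = sheet,
       truth = truth)
}

#' Simulate a qPCR Ct table
#'
#' Ct values follow \code{Ct = baseline - log2(relative abundance) + noise};
#' the housekeeping gene has constant unit abundance in every group, target
#' genes have unit abundance in the calibrator group and the configured fold
#' change in the test group.
#'
#' @param fold_changes Named numeric: true test-vs-calibrator fold change
#'   per gene (must be positive). Default mirrors the validated panel: a
#'   2-fold induction of the extrusion genes and 2-fold repression of the
#'   entry genes after treatment.
#' @param groups Length-2 character: calibrator and test group labels.
#' @param baseline_ct Baseline Ct of the target genes (default 25).
#' @param hk_gene,hk_ct Housekeeping gene id and its baseline Ct
#'   (defaults \code{"RP18S"}, 12).
#' @param n_samples Samples per group (default 3).
#' @param n_replicates Technical replicates per sample (default 3).
#' @param sigma Replicate noise SD in cycles (default 0.2).
#' @param seed Integer seed.
#' @return List: \code{ct_table} (gene, group, sample, replicate, ct) and
#'   \code{truth} (gene, fold, log2_fold).
#' @export
simulate_qpcr <- function(fold_changes = c(PMCA4 = 2, VDAC3 = 2, MCU = 2,
                                           TRPV6 = 0.5, TRPP1 = 0.5,
                                           SPCA2 = 0.5, TRPC5 = 1,
                                           SEPTIN6 = 1, ORMDL3 = 1),
                          groups = c("control", "DFMO"),
                          baseline_ct = 25, hk_gene = "RP18S", hk_ct = 12,
                          n_samples = 3L, n_replicates = 3L, sigma = 0.2,
                          seed = 1L) {
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  if (length(groups) != 2) stop("exactly two groups are required")
  set.seed(seed)
  genes <- c(names(fold_changes), hk_gene)
  rows <- expand.grid(replicate = seq_len(n_replicates),
                      sample = seq_len(n_samples),
                      group = groups, gene = genes,
                      stringsAsFactors = FALSE)
  abundance <- ifelse(rows$gene == hk_gene, 1,
                      ifelse(rows$group == groups[2],
                             fold_changes[rows$gene], 1))
  base <- ifelse(rows$gene == hk_gene, hk_ct, baseline_ct)
  rows$ct <- base - log2(abundance) +
    stats::rnorm(nrow(rows), 0, sigma)
  rows$sample <- paste0(rows$group, "_s", rows$sample)
  ct_table <- rows[, c("gene", "group", "sample", "replicate", "ct")]
  truth <- data.frame(gene = names(fold_changes),
                      fold = unname(fold_changes),
                      log2_fold = log2(unname(fold_changes)),
                      stringsAsFactors = FALSE)
  list(ct_table = ct_table, truth = truth)
}
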