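#' Pipeline run configuration
#'
#' Bundles the seeds, thresholds, and per-module options of an end-to-end
#' run. Thresholds are validated up front so an invalid configuration is
#' refused before any stage executes. All randomness is derived from the
#' single \code{seed}: each generator receives a fixed small offset of it.
#'
#' @param seed Master integer seed.
#' @param alpha Significance level for calcium contrasts and letter groups.
#' @param alpha1,alpha2 Strict / relaxed levels of the cross-platform
#'   concordance rule (\code{alpha1 < alpha2}).
#' @param fdr FDR threshold for differential-expression flags.
#' @param responses Calcium features to analyse (default all five).
#' @param select_structure Select the random structure by information
#'   criterion (default TRUE); otherwise use day + coverslip intercepts.
#' @param calcium Optional [calcium_sim_config()] override (its seed is
#'   replaced by the derived one).
#' @param expression Optional [expr_sim_config()] override.
#' @param baseline_mode Reversal baseline, \code{"combined"} or
#'   \code{"microarray_only"}.
#' @return List of class \code{ca_run_config}.
#' @export
run_config <- function(seed = 1L, alpha = 0.05, alpha1 = 0.05, alpha2 = 0.1,
                       fdr = 0.05,
                       responses = c("resting", "store_dmax", "store_auc",
                                     "soce_dmax", "soce_auc"),
                       select_structure = TRUE,
                       calcium = NULL, expression = NULL,
                       baseline_mode = "combined") {
  if (!(alpha > 0 && alpha < 1) || !(fdr > 0 && fdr < 1) ||
      !(alpha1 > 0 && alpha1 < 1) || !(alpha2 > 0 && alpha2 < 1))
    stop("thresholds must lie in (0, 1)")
  if (alpha1 >= alpha2) stop("alpha1 must be smaller than alpha2")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (is.null(calcium)) calcium <- calcium_sim_config()
  calcium$seed <- (seed * 11L) %% 2147483629L + 1L
  if (is.null(expression)) expression <- expr_sim_config()
  expression$seed <- (seed * 13L) %% 2147483629L + 1L
  cfg <- list(seed = seed, alpha = alpha, alpha1 = alpha1, alpha2 = alpha2,
              fdr = fdr, responses = responses,
              select_structure = select_structure,
              calcium = calcium, expression = expression,
              qpcr_seed = (seed * 17L) %% 2147483629L + 1L,
              baseline_mode = baseline_mode)
  class(cfg) <- "ca_run_config"
  cfg
}

run_stage <- function(report, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) e)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (inherits(value, "error")) {
    report$stages[[name]] <- list(status = "failed", elapsed = elapsed,
                                  message = conditionMessage(value))
    report$failed <- name
  } else {
    report$stages[[name]] <- list(status = "ok", elapsed = elapsed)
    report$values[[name]] <- value
  }
  report
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order: simulate calcium traces,
#' extract features, fit the condition model and compute letter displays
#' for each response; simulate the paired-platform expression experiment,
#' run QC and per-platform differential expression, combine platforms with
#' the concordance rule, classify reversals, and summarize treatment
#' selectivity; simulate and analyse the qPCR validation panel. Any stage
#' failure halts the run, and the report names the failed stage. Identical
#' configurations (including seed) give identical reports.
#'
#' @param config A [run_config()].
#' @return List of class \code{ca_run_report}: \code{stages} (status and
#'   elapsed time per stage), \code{letters} (per-response
#'   \code{ca_letters}), \code{contrast_tables}, \code{de_counts},
#'   \code{selectivity}, \code{reversals}, \code{qc}, \code{qpcr},
#'   \code{truth}, \code{seed}, \code{failed} (NULL on success).
#' @export
run_all <- function(config = run_config()) {
  if (!inherits(config, "ca_run_config"))
    stop("config must be built by run_config() or read_run_config()")
  report <- list(stages = list(), values = list(), failed = NULL,
                 seed = config$seed)

  report <- run_stage(report, "simulate_calcium",
                      simulate_calcium(config$calcium))
  if (is.null(report$failed))
    report <- run_stage(report, "extract_features", {
      prot <- default_protocol(config$calcium$phase_times)
      extract_features(report$values$simulate_calcium$traces, prot)
    })
  if (is.null(report$failed))
    report <- run_stage(report, "calcium_stats", {
      feats <- report$values$extract_features
      out <- list()
      for (resp in config$responses) {
        fit <- if (config$select_structure)
          select_random_structure(feats, resp)$fit
        else
          fit_condition_model(feats, resp)
        out[[resp]] <- letter_display(fit, alpha = config$alpha)
      }
      out
    })

  if (is.null(report$failed))
    report <- run_stage(report, "simulate_expression",
                        simulate_expression_pair(config$expression))
  if (is.null(report$failed))
    report <- run_stage(report, "qc", {
      sim <- report$values$simulate_expression
      qc_run(quantile_normalize(sim$platform_a), sim$sheet)
    })
  if (is.null(report$failed))
    report <- run_stage(report, "diffexpr", {
      sim <- report$values$simulate_expression
      panel <- config$expression$panel
      list(a = de_run(sim$platform_a, sim$sheet, panel, fdr = config$fdr),
           b = de_run(sim$platform_b, sim$sheet, panel, fdr = config$fdr))
    })
  if (is.null(report$failed))
    report <- run_stage(report, "concordance_reversal", {
      de <- report$values$diffexpr
      panel <- config$expression$panel
      slim <- function(tab) tab[, c("gene", "q", "logFC")]
      cancer <- call_cross_platform_de(slim(de$a$tables$line),
                                       slim(de$b$tables$line),
                                       alpha1 = config$alpha1,
                                       alpha2 = config$alpha2)
      baseline <- if (config$baseline_mode == "combined") cancer
                  else slim(de$a$tables$line)
      rev <- classify_reversal(baseline, slim(de$a$tables$treatment_HT29),
                               alpha = config$fdr,
                               baseline_mode = config$baseline_mode)
      sel <- summarize_selectivity(de$a$tables$treatment_NCM460,
                                   de$a$tables$treatment_HT29,
                                   panel, rev, alpha = config$fdr)
      list(cancer = cancer, reversals = rev, selectivity = sel)
    })

  if (is.null(report$failed))
    report <- run_stage(report, "qpcr", {
      sim <- simulate_qpcr(seed = config$qpcr_seed)
      list(table = qpcr_run(sim$ct_table, test_group = "DFMO",
                            calibrator_group = "control"),
           truth = sim$truth)
    })

  out <- list(stages = report$stages,
              seed = config$seed,
              failed = report$failed)
  v <- report$values
  if (!is.null(v$calcium_stats)) out$letters <- v$calcium_stats
  if (!is.null(v$diffexpr)) {
    cnt <- function(tab) sum(tab$significant)
    out$de_counts <- list(
      a = vapply(v$diffexpr$a$tables, cnt, 0L),
      b = vapply(v$diffexpr$b$tables, cnt, 0L))
  }
  if (!is.null(v$concordance_reversal)) {
    out$selectivity <- v$concordance_reversal$selectivity
    out$reversals <- v$concordance_reversal$reversals
    out$concordance <- v$concordance_reversal$cancer
  }
  if (!is.null(v$qc))
    out$qc <- list(n_pc = v$qc$pca$n_pc,
                   flagged_samples = v$qc$flagged_samples)
  if (!is.null(v$qpcr)) out$qpcr <- v$qpcr$table
  if (!is.null(v$simulate_expression))
    out$truth <- v$simulate_expression$truth
  class(out) <- "ca_run_report"
  out
}

#' @export
print.ca_run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-22s %-7s %6.1fs\n", nm, st$status, st$elapsed))
  }
  if (!is.null(x$failed)) {
    cat("FAILED at stage:", x$failed, "\n")
  } else if (!is.null(x$selectivity)) {
    cat(sprintf(paste0("Treatment affected %d genes in HT29 vs %d in ",
                       "NCM460; %d panel genes affected, %d reversed\n"),
                x$selectivity$n_affected_HT29,
                x$selectivity$n_affected_NCM460,
                x$selectivity$panel_affected_HT29,
                x$selectivity$panel_reversed))
  }
  invisible(x)
}
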