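#' Cross-platform differential-expression calls
#'
#' Applies the dual-technology concordance rule: a gene is differentially
#' expressed if at least one platform reports it at the strict significance
#' level \code{alpha1}, or both platforms do at the relaxed level
#' \code{alpha2}, provided the log fold changes of the two platforms point
#' in the same direction. Discordant signs veto the call regardless of
#' significance, and a zero log fold change is sign-indeterminate. Genes
#' measured on only one platform are recorded as \code{insufficient}, never
#' silently treated as not differentially expressed.
#'
#' Significance is judged on the FDR scale (q-values) by default, matching
#' the definition of significance used by the per-platform analyses; raw
#' p-values can be supplied in the \code{q} column if desired.
#'
#' @param a,b data.frames with columns \code{gene}, \code{q}, \code{logFC}
#'   (one row per gene, one per platform).
#' @param alpha1 Strict single-platform level (default 0.05).
#' @param alpha2 Relaxed both-platform level (default 0.1); must exceed
#'   \code{alpha1}.
#' @return data.frame with one row per gene of the union: \code{gene},
#'   \code{decision} (\code{DE_up} / \code{DE_down} / \code{not_DE}),
#'   \code{basis} (\code{both_0.05}, \code{single_0.05}, \code{both_0.10},
#'   \code{discordant_sign}, \code{insufficient}), plus the per-platform
#'   \code{q_a}, \code{q_b}, \code{logFC_a}, \code{logFC_b}.
#' @export
call_cross_platform_de <- function(a, b, alpha1 = 0.05, alpha2 = 0.1) {
  if (alpha1 >= alpha2)
    stop("alpha1 must be smaller than alpha2")
  need <- c("gene", "q", "logFC")
  if (!all(need %in% names(a)) || !all(need %in% names(b)))
    stop("platform tables need columns gene, q, logFC")
  genes <- union(a$gene, b$gene)
  ia <- match(genes, a$gene)
  ib <- match(genes, b$gene)
  qa <- a$q[ia]; qb <- b$q[ib]
  fa <- a$logFC[ia]; fb <- b$logFC[ib]

  decision <- rep("not_DE", length(genes))
  basis <- rep("insufficient", length(genes))
  shared <- !is.na(ia) & !is.na(ib)

  meets <- shared & ((qa < alpha1 | qb < alpha1) |
                       (qa < alpha2 & qb < alpha2))
  concord <- sign(fa) == sign(fb) & sign(fa) != 0
  concord[is.na(concord)] <- FALSE

  basis[meets & !concord] <- "discordant_sign"
  de <- meets & concord
  decision[de] <- ifelse(fa[de] > 0, "DE_up", "DE_down")
  basis[de & qa < alpha1 & qb < alpha1] <- "both_0.05"
  basis[de & xor(qa < alpha1, qb < alpha1)] <- "single_0.05"
  basis[de & !(qa < alpha1) & !(qb < alpha1)] <- "both_0.10"

  data.frame(gene = genes, decision = decision, basis = basis,
             q_a = qa, q_b = qb, logFC_a = fa, logFC_b = fb,
             stringsAsFactors = FALSE)
}

#' Classify treatment-induced expression reversals
#'
#' A gene's cancer-associated expression change is "reversed" when (i) the
#' gene is differentially expressed between cancer and normal cells under
#' the chosen baseline, (ii) the treatment contrast in the cancer line is
#' significant at \code{alpha}, and (iii) the two changes have opposite
#' signs. Both baselines used in practice are supported: the cross-platform
#' concordance call (\code{"combined"}) and the single-platform microarray
#' result (\code{"microarray_only"}).
#'
#' @param cancer_de For \code{baseline_mode = "combined"}, the output of
#'   [call_cross_platform_de()]; for \code{"microarray_only"}, a data.frame
#'   with \code{gene}, \code{q}, \code{logFC}.
#' @param treat_de_ht29 data.frame with \code{gene}, \code{q}, \code{logFC}
#'   for the DFMO-vs-control contrast in the cancer line.
#' @param alpha Significance level for the treatment contrast (and for the
#'   microarray baseline), default 0.05.
#' @param baseline_mode \code{"combined"} or \code{"microarray_only"}.
#' @return data.frame per gene of the shared universe: \code{gene},
#'   \code{cancer_sign}, \code{treatment_sign}, \code{cancer_significant},
#'   \code{treatment_significant}, \code{reversed}, \code{baseline_mode}.
#' @export
classify_reversal <- function(cancer_de, treat_de_ht29, alpha = 0.05,
                              baseline_mode = c("combined",
                                                "microarray_only")) {
  baseline_mode <- match.arg(baseline_mode)
  if (baseline_mode == "combined") {
    if (!all(c("decision", "basis") %in% names(cancer_de)))
      stop("combined baseline expects a concordance-call table")
    cancer_sig <- cancer_de$decision %in% c("DE_up", "DE_down")
    cancer_sign <- ifelse(cancer_de$decision == "DE_up", 1L,
                          ifelse(cancer_de$decision == "DE_down", -1L, 0L))
  } else {
    cancer_sig <- cancer_de$q < alpha & sign(cancer_de$logFC) != 0
    cancer_sign <- as.integer(sign(cancer_de$logFC)) * as.integer(cancer_sig)
  }
  genes <- intersect(cancer_de$gene, treat_de_ht29$gene)
  ic <- match(genes, cancer_de$gene)
  it <- match(genes, treat_de_ht29$gene)
  t_sig <- treat_de_ht29$q[it] < alpha & sign(treat_de_ht29$logFC[it]) != 0
  t_sign <- as.integer(sign(treat_de_ht29$logFC[it])) * as.integer(t_sig)
  reversed <- cancer_sig[ic] & t_sig &
    cancer_sign[ic] == -t_sign & cancer_sign[ic] != 0
  data.frame(gene = genes,
             cancer_sign = cancer_sign[ic],
             treatment_sign = t_sign,
             cancer_significant = cancer_sig[ic],
             treatment_significant = t_sig,
             reversed = reversed,
             baseline_mode = baseline_mode,
             stringsAsFactors = FALSE)
}

#' Treatment-selectivity summary
#'
#' Counts how many genes the treatment affected in each cell line, genome
#' wide and restricted to the calcium panel, plus the number of panel genes
#' whose cancer-associated change was reversed.
#'
#' @param treat_de_ncm460,treat_de_ht29 data.frames with \code{gene},
#'   \code{q} (and optionally \code{logFC}) for the DFMO contrast in each
#'   line, on the same gene universe.
#' @param panel Panel data.frame (column \code{gene}).
#' @param reversals Output of [classify_reversal()].
#' @param alpha Significance level (default 0.05).
#' @return Named list of counts: \code{n_affected_NCM460},
#'   \code{n_affected_HT29}, \code{panel_affected_NCM460},
#'   \code{panel_affected_HT29}, \code{panel_reversed}.
#' @export
summarize_selectivity <- function(treat_de_ncm460, treat_de_ht29, panel,
                                  reversals, alpha = 0.05) {
  aff <- function(tab) tab$gene[!is.na(tab$q) & tab$q < alpha]
  a_n <- aff(treat_de_ncm460)
  a_h <- aff(treat_de_ht29)
  rev_panel <- reversals$gene[reversals$reversed &
                                reversals$gene %in% panel$gene]
  list(n_affected_NCM460 = length(a_n),
       n_affected_HT29 = length(a_h),
       panel_affected_NCM460 = sum(a_n %in% panel$gene),
       panel_affected_HT29 = sum(a_h %in% panel$gene),
       panel_reversed = length(rev_panel),
       reversed_genes = sort(rev_panel))
}
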