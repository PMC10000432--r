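#' Curated calcium-transport gene panel
#'
#' Returns the 89-gene panel of intracellular Ca2+ transport genes used
#' throughout the pipeline, split into six functional categories:
#' voltage-operated Ca2+ channels (VOCC, 10 genes), SOCE players and
#' modulators (23), TRP channels (27), ER Ca2+ release channels (6),
#' Ca2+ pumps and exchangers (12), and mitochondrial Ca2+ transporters (11).
#'
#' Gene symbols follow the channel-protein naming common in the calcium
#' signalling literature (e.g. \code{CAV1.2} for the L-type channel gene,
#' \code{PMCA4} for the plasma-membrane Ca2+ ATPase isoform 4).
#'
#' @return A data.frame with columns \code{gene} (unique identifier) and
#'   \code{category} (factor with the six levels listed above).
#' @export
#' @examples
#' panel <- calcium_gene_panel()
#' table(panel$category)
calcium_gene_panel <- function() {
  vocc <- c("CAV1.1", "CAV1.2", "CAV1.3", "CAV1.4", "CAV2.1", "CAV2.2",
            "CAV2.3", "CAV3.1", "CAV3.2", "CAV3.3")
  soce <- c("ORAI1", "ORAI2", "ORAI3", "STIM1", "STIM2", "CRACR2A",
            "STIMATE", "ORMDL3", "SARAF", "MBP",
            paste0("SEPTIN", c(1:12, 14)))
  trp <- c(paste0("TRPC", c(1, 3:7)),
           paste0("TRPV", 1:6),
           paste0("TRPM", c(1:3, 5:8)),
           "TRPA1",
           paste0("TRPML", 1:3),
           paste0("TRPP", c(1:3, 5)))
  release <- c("IP3R1", "IP3R2", "IP3R3", "RYR1", "RYR2", "RYR3")
  pump <- c(paste0("PMCA", 1:4), paste0("SERCA", 1:3),
            paste0("SPCA", 1:2), paste0("NCX", 1:3))
  mito <- c("MCU", "MCUb", "MICU1", "MICU2", "MICU3", "MCUR1", "EMRE",
            paste0("VDAC", 1:3), "NCLX")
  cats <- c("VOCC", "SOCE", "TRP", "release", "pump_exchanger",
            "mitochondrial")
  out <- data.frame(
    gene = c(vocc, soce, trp, release, pump, mito),
    category = factor(
      rep(cats, times = c(length(vocc), length(soce), length(trp),
                          length(release), length(pump), length(mito))),
      levels = cats),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$gene))
  out
}

#' Read a gene panel table
#'
#' @param path Path to a tab-delimited file with columns \code{gene} and
#'   \code{category}.
#' @return data.frame as from [calcium_gene_panel()].
#' @export
read_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(panel)))
    stop("panel file must have columns 'gene' and 'category'")
  if (anyDuplicated(panel$gene)) stop("panel genes must be unique")
  panel
}
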