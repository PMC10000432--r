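#' Read and write pipeline data files
#'
#' Plain-text readers and writers for the pipeline's interchange formats:
#' long-format trace CSVs, tab-delimited expression matrices with sample
#' sheets, feature tables, and qPCR Ct tables. All writers emit unquoted,
#' rowname-free files that the matching reader round-trips.
#'
#' @param path File path.
#' @param traces,features,mat,sheet,ct_table Objects to write.
#' @return Readers return data.frames (or a numeric matrix for
#'   \code{read_expression_matrix}); writers return the path invisibly.
#' @name calremodel-io
NULL

#' @rdname calremodel-io
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calremodel-io
#' @export
read_traces <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "day", "coverslip", "line", "treatment",
            "time_s", "ratio")
  if (!all(need %in% names(tr)))
    stop("trace file must have columns ", paste(need, collapse = ", "))
  tr
}

#' @rdname calremodel-io
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calremodel-io
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calremodel-io
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be 'gene'")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("missing values are not allowed; refusing to impute")
  mat
}

#' @rdname calremodel-io
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname calremodel-io
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "line", "treatment", "day")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  sheet
}

#' @rdname calremodel-io
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calremodel-io
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "group", "sample", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct file must have columns ", paste(need, collapse = ", "))
  ct
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()] and
#' builds the validated configuration.
#'
#' @param path Path to a YAML file with at least a \code{seed} key.
#' @return A validated \code{ca_run_config} (see [run_config()]).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config must provide a seed")
  do.call(run_config, raw)
}
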