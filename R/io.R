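# Plain-text readers/writers for the pipeline's tabular interfaces.

#' Write a simulated or assembled screen count table to TSV
#'
#' Columns: barcode, gene_id, allele_index, then one column per sample.
#'
#' @param counts Barcodes x samples matrix with dimnames.
#' @param annotation Data frame `barcode`, `gene_id`, `allele_index`.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, annotation, path) {
  i <- match(rownames(counts), annotation$barcode)
  df <- cbind(
    data.frame(barcode = rownames(counts),           # unannotated rows kept
               gene_id = annotation$gene_id[i],      # (gene_id NA)
               allele_index = annotation$allele_index[i]),
    as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a screen count table written by [write_counts_tsv()]
#'
#' @param path TSV path.
#' @return List: `counts` (matrix) and `annotation` (data frame).
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("barcode", "gene_id", "allele_index")
  if (!all(meta %in% names(df)))
    stop("count TSV must have columns barcode, gene_id, allele_index")
  counts <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(counts) <- df$barcode
  ann <- df[!is.na(df$gene_id), meta]
  rownames(ann) <- NULL
  list(counts = counts, annotation = ann)
}

#' Read a screen design from YAML
#'
#' Expected structure: a mapping of screen names to
#' `{condition, replicate, control, treatment}` entries, or a list of
#' such entries.
#'
#' @param path YAML path.
#' @return Data frame `condition`, `replicate`, `control`, `treatment`.
#' @export
read_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(y, function(e) {
    need <- c("condition", "replicate", "control", "treatment")
    if (!all(need %in% names(e))) stop("malformed design entry")
    data.frame(condition = e$condition, replicate = e$replicate,
               control = e$control, treatment = e$treatment,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
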