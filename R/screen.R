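#' Phenotype-ratio bin edges for the pooled screen
#'
#' The pooled barcoded screen assigns each qualified mutant allele a
#' phenotype ratio \eqn{\Phi} (relative abundance after growth under
#' treatment divided by relative abundance under control) and counts
#' alleles in eight half-open bins. The interior edges are
#' 0.0625, 0.125, 0.25, 0.5, 2.0, 4.0, 8.0 and 16.0; each bin is closed
#' on the left and open on the right, the first bin is \eqn{\Phi <
#' 0.0625}, and ratios of 16 or more are clipped into the top bin.
#'
#' @return Numeric vector of the 8 interior edges.
#' @seealso [bin_phi()]
#' @export
phi_bin_edges <- function() {
  c(0.0625, 0.125, 0.25, 0.5, 2.0, 4.0, 8.0, 16.0)
}

#' Convert barcode counts to per-sample relative abundances
#'
#' Columns (samples) are scaled to sum to one so that mutant abundance is
#' comparable across libraries sequenced to different depths.
#'
#' @param counts Integer matrix, barcodes in rows and samples in columns.
#' @return Numeric matrix of the same shape; every column sums to 1.
#' @export
normalize_abundance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("every sample column must have total reads > 0")
  sweep(counts, 2L, tot, "/")
}

#' Compute per-allele phenotype ratios from a control/treatment sample pair
#'
#' \eqn{\Phi} is the treatment relative abundance divided by the control
#' relative abundance of a barcode. A minimum read count (default 50) is
#' required for the phenotype to be calculated; by default the minimum
#' applies to the control sample, since a sparse control denominator makes
#' \eqn{\Phi} unstable while treatment dropout is itself the signal
#' (a qualified allele with zero treatment reads has \eqn{\Phi = 0}).
#'
#' @param counts Integer matrix (barcodes x samples) with dimnames.
#' @param annotation Data frame with columns `barcode`, `gene_id`,
#'   `allele_index`. Barcodes absent from it are flagged unmapped and
#'   dropped (their number is recorded in the `"n_unmapped"` attribute).
#' @param control,treatment Sample (column) names.
#' @param min_reads Read minimum for a phenotype to be calculated.
#' @param min_reads_on Which raw counts the minimum applies to:
#'   `"control"` (default), `"sum"` of the pair, or `"both"` samples.
#' @return Data frame with one row per annotated barcode: `barcode`,
#'   `gene_id`, `allele_index`, `control_reads`, `treatment_reads`,
#'   `phi` (NA when not qualified), `qualified`.
#' @export
compute_phi <- function(counts, annotation, control, treatment,
                        min_reads = 50,
                        min_reads_on = c("control", "sum", "both")) {
  counts <- as.matrix(counts)
  min_reads_on <- match.arg(min_reads_on)
  for (s in c(control, treatment))
    if (!s %in% colnames(counts)) stop("sample not found: ", s)
  rel <- normalize_abundance(counts[, c(control, treatment), drop = FALSE])

  bc <- rownames(counts)
  mapped <- bc %in% annotation$barcode
  n_unmapped <- sum(!mapped)
  bc <- bc[mapped]
  ann <- annotation[match(bc, annotation$barcode), , drop = FALSE]

  cr <- counts[bc, control]
  tr <- counts[bc, treatment]
  qualified <- switch(min_reads_on,
    control = cr >= min_reads,
    sum     = (cr + tr) >= min_reads,
    both    = cr >= min_reads & tr >= min_reads
  )
  phi <- rep(NA_real_, length(bc))
  phi[qualified] <- rel[bc, treatment][qualified] / rel[bc, control][qualified]

  out <- data.frame(
    barcode = bc, gene_id = ann$gene_id, allele_index = ann$allele_index,
    control_reads = unname(cr), treatment_reads = unname(tr),
    phi = phi, qualified = qualified,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Bin a phenotype ratio into the 8 screen bins
#'
#' Bins are half-open (closed left edge): bin 1 is \eqn{\Phi < 0.0625},
#' bin 2 is \eqn{0.0625 \le \Phi < 0.125}, ..., bin 8 is
#' \eqn{8 \le \Phi < 16}. Ratios \eqn{\ge 16} are clipped into bin 8,
#' since the bin list ends at 16. Neutral alleles (\eqn{\Phi \approx 1})
#' fall in bin 5 (\eqn{0.5 \le \Phi < 2}).
#'
#' @param phi Numeric vector of non-negative phenotype ratios.
#' @return Integer vector of bin indices in 1..8.
#' @export
bin_phi <- function(phi) {
  if (any(!is.finite(phi) | phi < 0)) stop("phi must be finite and >= 0")
  idx <- findInterval(phi, phi_bin_edges()) + 1L  # left-closed
  pmin.int(idx, 8L)
}

#' Build a gene's phenotype contingency table against the screen background
#'
#' Counts the gene's qualified alleles in each of the 8 \eqn{\Phi} bins and
#' pairs them with the background table over all qualified insertions in
#' the screen. By default the gene's own alleles are part of the background
#' ("all insertions in the screen"); set `include_gene = FALSE` to remove
#' them.
#'
#' @param phenotypes Data frame from [compute_phi()].
#' @param gene_id Gene to tabulate.
#' @param include_gene Keep the gene's alleles in the background table?
#' @return List with `gene_id`, `gene` (8-vector), `background` (8-vector),
#'   `n_alleles` (qualified alleles of the gene).
#' @export
gene_contingency <- function(phenotypes, gene_id, include_gene = TRUE) {
  q <- phenotypes[phenotypes$qualified, , drop = FALSE]
  g <- q[q$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L)
    stop("gene ", gene_id, " has no qualified alleles")
  tab <- function(phi) tabulate(bin_phi(phi), nbins = 8L)
  gene <- tab(g$phi)
  background <- tab(q$phi)
  if (!include_gene) background <- background - gene
  list(gene_id = gene_id, gene = gene, background = background,
       n_alleles = nrow(g), include_gene = include_gene)
}
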