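#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j} on the sorted p-values.
#' A thin validated wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call screen hits from gene-level p-values
#'
#' BH adjustment is applied only to genes represented by at least
#' `min_alleles` qualified alleles (default 3: gene-level confidence
#' requires multiple independent insertions); a gene is a hit when its
#' q-value is strictly below `fdr` (default 0.3).
#'
#' @param gene_p Data frame with columns `gene_id`, `p`, `n_alleles`.
#' @param fdr FDR threshold (strict less-than).
#' @param min_alleles Minimum qualified alleles for a gene to enter the
#'   FDR correction.
#' @return `gene_p` with added columns `q` (NA for excluded genes) and
#'   `hit` (logical).
#' @export
call_hits <- function(gene_p, fdr = 0.3, min_alleles = 3L) {
  if (nrow(gene_p) == 0L) {
    gene_p$q <- numeric(0); gene_p$hit <- logical(0)
    return(gene_p)
  }
  eligible <- gene_p$n_alleles >= min_alleles
  q <- rep(NA_real_, nrow(gene_p))
  q[eligible] <- bh_fdr(gene_p$p[eligible])
  gene_p$q <- q
  gene_p$hit <- !is.na(q) & q < fdr
  gene_p
}

#' Run the full pooled-screen hit-calling pipeline
#'
#' For every (condition, replicate) control/treatment pair in `design`:
#' compute per-allele \eqn{\Phi}, bin qualified alleles, build each gene's
#' 8-bin contingency table against the all-insertion background, test it
#' with [fisher_gene_p()], and call hits with BH FDR within the screen.
#' Results are invariant to barcode row order and sample column order.
#'
#' @param counts Integer matrix, barcodes x samples (dimnames required).
#' @param annotation Data frame `barcode`, `gene_id`, `allele_index`.
#' @param design Data frame with columns `condition`, `replicate`,
#'   `control`, `treatment` (sample column names).
#' @param min_reads,min_reads_on Passed to [compute_phi()].
#' @param fdr,min_alleles Passed to [call_hits()].
#' @param exact_cap,mc_draws,seed Passed to [fisher_gene_p()].
#' @return Data frame with one row per gene per screen: `condition`,
#'   `replicate`, `gene_id`, `n_alleles`, `p`, `q`, `hit`. Dropped-record
#'   counts are attached as attribute `"dropped"`.
#' @export
run_screen_pipeline <- function(counts, annotation, design,
                                min_reads = 50, min_reads_on = "control",
                                fdr = 0.3, min_alleles = 3L,
                                exact_cap = 12L, mc_draws = 1e5,
                                seed = NULL) {
  need <- c("condition", "replicate", "control", "treatment")
  if (!all(need %in% names(design))) stop("malformed design: need columns ",
                                          paste(need, collapse = ", "))
  missing_s <- setdiff(unique(c(design$control, design$treatment)),
                       colnames(counts))
  if (length(missing_s)) stop("design references unknown samples: ",
                              paste(missing_s, collapse = ", "))
  res <- vector("list", nrow(design))
  dropped <- list(unmapped = 0L, no_qualified_allele = 0L)
  for (i in seq_len(nrow(design))) {
    ph <- compute_phi(counts, annotation, design$control[i],
                      design$treatment[i], min_reads = min_reads,
                      min_reads_on = min_reads_on)
    dropped$unmapped <- dropped$unmapped + attr(ph, "n_unmapped")
    q <- ph[ph$qualified, , drop = FALSE]
    n_gene_all <- length(unique(ph$gene_id))
    if (nrow(q) == 0L) {
      res[[i]] <- data.frame(condition = character(0),
                             replicate = character(0),
                             gene_id = character(0), n_alleles = integer(0),
                             p = numeric(0), q = numeric(0), hit = logical(0))
      dropped$no_qualified_allele <- dropped$no_qualified_allele + n_gene_all
      next
    }
    bins <- bin_phi(q$phi)
    background <- tabulate(bins, nbins = 8L)
    genes <- sort(unique(q$gene_id))
    dropped$no_qualified_allele <-
      dropped$no_qualified_allele + (n_gene_all - length(genes))
    # same background for every gene -> memoise p by the gene's bin vector
    cache <- new.env(parent = emptyenv())
    p <- numeric(length(genes))
    n_all <- integer(length(genes))
    bl <- split(bins, q$gene_id)[genes]
    for (k in seq_along(genes)) {
      gv <- tabulate(bl[[k]], nbins = 8L)
      n_all[k] <- sum(gv)
      key <- paste(gv, collapse = ",")
      if (is.null(cache[[key]])) {
        cache[[key]] <- fisher_gene_p(gv, background,
                                      exact_cap = exact_cap,
                                      mc_draws = mc_draws, seed = seed)$p
      }
      p[k] <- cache[[key]]
    }
    tab <- call_hits(
      data.frame(gene_id = genes, p = p, n_alleles = n_all,
                 stringsAsFactors = FALSE),
      fdr = fdr, min_alleles = min_alleles)
    tab <- cbind(condition = design$condition[i],
                 replicate = design$replicate[i], tab)
    res[[i]] <- tab[, c("condition", "replicate", "gene_id", "n_alleles",
                        "p", "q", "hit")]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
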