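#' Simulate a pooled barcoded mutant fitness screen
#'
#' Emulates competitive growth of a barcoded insertional-mutant pool.
#' Each allele carries a selection coefficient `s` (0 for neutral genes,
#' `selection_coefficient` for all alleles of the planted hit genes).
#' Growth runs for `doublings` discrete doublings: under treatment an
#' allele's abundance grows as \eqn{2^{g(1-s)}}, under control as
#' \eqn{2^g}, so the expected phenotype ratio is \eqn{\Phi = 2^{-g s}}.
#' Reads are drawn multinomially at `read_depth` per sample (exactly
#' conserving depth), or returned as exact expected read counts when
#' `sampling = FALSE` (the deterministic path used to check closed-form
#' expectations). Initial pool abundances are log-normal
#' (`abundance_sdlog`), reflecting the uneven representation of real
#' pooled libraries; it does not affect expected \eqn{\Phi}.
#'
#' As in real pools, a fraction of reads (`unmapped_frac`) comes from an
#' unbarcoded/unmappable component, emitted as an extra count row absent
#' from the annotation. This component also takes up the pool share
#' vacated by depleted mutants, so per-allele relative abundances are not
#' distorted by compositional closure and the expected \eqn{\Phi} of
#' every mapped allele is exactly \eqn{2^{-g s}} (neutral alleles exactly
#' 1), which the deterministic path reproduces to machine precision.
#'
#' @param n_genes Number of genes in the pool.
#' @param alleles_per_gene Alleles (independent insertions) per gene;
#'   scalar or length-`n_genes` vector.
#' @param n_hit_genes Number of genes planted with a fitness defect.
#' @param selection_coefficient Per-doubling fitness deficit `s` in
#'   \[0, 1\] for hit genes.
#' @param doublings Growth duration `g` in doublings (> 0).
#' @param read_depth Total reads per sample (> 0).
#' @param replicates Number of control/treatment replicate pairs.
#' @param seed Integer seed; all randomness flows from it.
#' @param condition Condition label for treatment samples.
#' @param abundance_sdlog Log-normal sd of initial barcode abundances.
#' @param unmapped_frac Fraction of the control pool that is unbarcoded
#'   (emitted as an `unmapped` count row not present in the annotation).
#' @param overdispersion Optional Dirichlet-multinomial concentration;
#'   `NULL` (default) gives pure multinomial reads.
#' @param sampling Draw reads (`TRUE`) or return exact expected counts.
#' @return List: `counts` (barcodes x samples matrix), `annotation`
#'   (barcode, gene_id, allele_index), `sample_info` (sample, condition,
#'   replicate, role), `truth` (gene_id, s, expected_phi), `design`
#'   (ready for [run_screen_pipeline()]).
#' @export
simulate_screen <- function(n_genes, alleles_per_gene = 5L, n_hit_genes = 0L,
                            selection_coefficient = 0.5, doublings = 4,
                            read_depth = 1e7, replicates = 1L, seed = 1L,
                            condition = "osmotic", abundance_sdlog = 0.5,
                            unmapped_frac = 0.1,
                            overdispersion = NULL, sampling = TRUE) {
  stop_if_not_count(n_genes, "n_genes", 1L)
  stop_if_not_count(n_hit_genes, "n_hit_genes", 0L)
  stop_if_not_count(replicates, "replicates", 1L)
  if (n_hit_genes > n_genes) stop("n_hit_genes must be <= n_genes")
  s <- selection_coefficient
  if (s < 0 || s > 1) stop("selection_coefficient must lie in [0, 1]")
  if (doublings <= 0) stop("doublings must be > 0")
  if (read_depth <= 0) stop("read_depth must be > 0")
  apg <- rep_len(as.integer(alleles_per_gene), n_genes)

  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  gene_s <- c(rep(s, n_hit_genes), rep(0, n_genes - n_hit_genes))
  annotation <- data.frame(
    barcode = sprintf("bc_%05d", seq_len(sum(apg))),
    gene_id = rep(gene_id, apg),
    allele_index = unlist(lapply(apg, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  allele_s <- rep(gene_s, apg)
  g <- doublings
  n_bc <- nrow(annotation)

  if (unmapped_frac < 0 || unmapped_frac >= 1)
    stop("unmapped_frac must lie in [0, 1)")
  with_seed(seed, {
    a0 <- stats::rlnorm(n_bc, sdlog = abundance_sdlog)
    # unmapped pool component; absorbs the share vacated by depleted
    # mutants so mapped relative abundances stay free of closure
    sink_ctrl <- sum(a0) * unmapped_frac / (1 - unmapped_frac)
    a_trt <- a0 * 2^(-g * allele_s)              # common 2^g cancels
    sink_trt <- sink_ctrl + sum(a0) - sum(a_trt)
    p_ctrl <- c(a0, sink_ctrl) / (sum(a0) + sink_ctrl)
    p_trt <- c(a_trt, sink_trt) / (sum(a_trt) + sink_trt)

    draw <- function(p) {
      if (!sampling) return(read_depth * p)
      if (!is.null(overdispersion)) {
        w <- stats::rgamma(length(p), shape = overdispersion * p, rate = 1)
        p <- w / sum(w)
      }
      as.numeric(stats::rmultinom(1L, size = read_depth, prob = p))
    }
    samples <- character(0); cols <- list()
    info <- list()
    for (r in seq_len(replicates)) {
      cn <- sprintf("control_r%d", r); tn <- sprintf("treatment_r%d", r)
      cols[[cn]] <- draw(p_ctrl); cols[[tn]] <- draw(p_trt)
      info[[cn]] <- data.frame(sample = cn, condition = condition,
                               replicate = r, role = "control")
      info[[tn]] <- data.frame(sample = tn, condition = condition,
                               replicate = r, role = "treatment")
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- c(annotation$barcode, "unmapped")
    list(
      counts = counts,
      annotation = annotation,
      sample_info = do.call(rbind, c(info, list(make.row.names = FALSE))),
      truth = data.frame(gene_id = gene_id, s = gene_s,
                         expected_phi = 2^(-g * gene_s),
                         stringsAsFactors = FALSE),
      design = data.frame(condition = condition,
                          replicate = seq_len(replicates),
                          control = sprintf("control_r%d", seq_len(replicates)),
                          treatment = sprintf("treatment_r%d", seq_len(replicates)),
                          stringsAsFactors = FALSE)
    )
  })
}
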