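#' Simulate a reciprocal 14N/15N label-swap phosphoproteomics experiment
#'
#' Each replicate is an experimental pair in which treated and control
#' cultures carry opposite metabolic labels. In a *forward* pair the
#' treated sample is grown in the light (14N) medium, so the raw
#' light/heavy peak-area ratio equals treated/control; in a *reverse*
#' pair the labels are swapped and the raw ratio equals control/treated.
#' True phosphorylation changes therefore flip the raw-ratio direction
#' between orientations while label artifacts would not.
#'
#' The first `n_changed` peptides get a treated/control expectation of
#' `true_fold` (a fraction `frac_down` of them inverted to `1/true_fold`);
#' the rest are unchanged (expectation 1). Gaussian noise of sd `noise_sd`
#' is applied on the log2 scale of the raw ratio.
#'
#' @param n_peptides Total peptides.
#' @param n_changed Peptides with a planted change.
#' @param true_fold Planted treated/control fold change (> 0).
#' @param replicates Number of replicate pairs (default 3).
#' @param orientation_pattern Character vector recycled over replicates,
#'   values `"forward"`/`"reverse"`; default alternates starting forward.
#' @param noise_sd Log2-ratio noise sd.
#' @param frac_down Fraction of changed peptides planted as decreases.
#' @param peptides_per_protein Peptides grouped per protein id.
#' @param seed Integer seed.
#' @return List: `measurements` (peptide_id, protein_id, site, replicate,
#'   orientation, raw_ratio) and `truth` (peptide_id, changed,
#'   true_log2fc).
#' @export
simulate_label_swap <- function(n_peptides, n_changed = 0L, true_fold = 4,
                                replicates = 3L,
                                orientation_pattern = c("forward", "reverse"),
                                noise_sd = 0.25, frac_down = 0,
                                peptides_per_protein = 2L, seed = 1L) {
  stop_if_not_count(n_peptides, "n_peptides", 1L)
  stop_if_not_count(n_changed, "n_changed", 0L)
  if (n_changed > n_peptides) stop("n_changed must be <= n_peptides")
  if (true_fold <= 0) stop("true_fold must be > 0")
  if (!all(orientation_pattern %in% c("forward", "reverse")))
    stop("orientation_pattern values must be 'forward' or 'reverse'")
  orientation <- rep_len(orientation_pattern, replicates)

  pep <- sprintf("pep_%04d", seq_len(n_peptides))
  prot <- sprintf("prot_%04d",
                  ceiling(seq_len(n_peptides) / peptides_per_protein))
  l2fc <- rep(0, n_peptides)
  if (n_changed > 0L) {
    sgn <- rep(1, n_changed)
    if (frac_down > 0) sgn[seq_len(floor(frac_down * n_changed))] <- -1
    l2fc[seq_len(n_changed)] <- sgn * log2(true_fold)
  }

  with_seed(seed, {
    rows <- lapply(seq_len(replicates), function(r) {
      fwd <- orientation[r] == "forward"
      raw_l2 <- (if (fwd) l2fc else -l2fc) +
        stats::rnorm(n_peptides, sd = noise_sd)
      data.frame(peptide_id = pep, protein_id = prot,
                 site = sprintf("S%d", seq_len(n_peptides)),
                 replicate = r, orientation = orientation[r],
                 raw_ratio = 2^raw_l2, stringsAsFactors = FALSE)
    })
    list(measurements = do.call(rbind, rows),
         truth = data.frame(peptide_id = pep,
                            changed = seq_len(n_peptides) <= n_changed,
                            true_log2fc = l2fc, stringsAsFactors = FALSE))
  })
}
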