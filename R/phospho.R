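#' Orient a raw light/heavy ratio to the treated/control scale
#'
#' In a forward pair the treated sample carries the light (14N) label, so
#' the raw light/heavy peak-area ratio already is treated/control; in a
#' reverse pair the labels are swapped and the raw ratio is inverted.
#'
#' @param raw_ratio Positive light/heavy peak-area ratio(s).
#' @param orientation `"forward"` or `"reverse"` (recycled).
#' @return Treated/control ratio(s).
#' @export
orient_ratio <- function(raw_ratio, orientation) {
  if (any(!is.finite(raw_ratio) | raw_ratio <= 0))
    stop("raw_ratio must be finite and > 0")
  if (!all(orientation %in% c("forward", "reverse")))
    stop("orientation must be 'forward' or 'reverse'")
  orientation <- rep_len(orientation, length(raw_ratio))
  ifelse(orientation == "forward", raw_ratio, 1 / raw_ratio)
}

#' Call differentially phosphorylated peptides from label-swap replicates
#'
#' A peptide is called when at least `min_reps` replicates show a
#' reciprocal change of `fold` or greater in the same direction: all
#' ratios are first oriented to treated/control, and a replicate passes
#' when its absolute log2 oriented ratio reaches `log2(fold)`. Passing
#' replicates of opposite sign cancel the call. Peptides observed in
#' fewer than `min_reps` replicates cannot be called; missing replicates
#' are otherwise tolerated. With `strict_reciprocal = TRUE` a call
#' additionally requires at least one passing replicate from each label
#' orientation present in the data.
#'
#' @param measurements Data frame with columns `peptide_id`, `protein_id`,
#'   `replicate`, `orientation`, `raw_ratio` (one row per peptide per
#'   replicate; duplicates are an error).
#' @param fold Fold-change threshold (> 1).
#' @param min_reps Minimum passing replicates.
#' @param strict_reciprocal Require passes from both label orientations.
#' @return Data frame, one row per peptide: `peptide_id`, `protein_id`,
#'   `n_obs`, `n_passing`, `direction` (`"up"`, `"down"` or `NA`),
#'   `called`, plus the oriented log2 ratios in list column `log2_ratios`.
#' @export
call_differential <- function(measurements, fold = 2.0, min_reps = 2L,
                              strict_reciprocal = FALSE) {
  need <- c("peptide_id", "protein_id", "replicate", "orientation", "raw_ratio")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns ", paste(need, collapse = ", "))
  if (fold <= 1) stop("fold must be > 1")
  key <- paste(measurements$peptide_id, measurements$replicate)
  if (anyDuplicated(key))
    stop("duplicate (peptide, replicate) measurement rows")

  l2 <- log2(orient_ratio(measurements$raw_ratio, measurements$orientation))
  thr <- log2(fold)
  # stable peptide order: first appearance
  ids <- unique(measurements$peptide_id)
  idx <- split(seq_len(nrow(measurements)), measurements$peptide_id)[ids]
  rows <- lapply(ids, function(pid) {
    i <- idx[[pid]]
    i <- i[order(measurements$replicate[i])]
    x <- l2[i]
    up <- x >= thr; dn <- x <= -thr
    n_up <- sum(up); n_dn <- sum(dn)
    called <- FALSE; direction <- NA_character_
    if (n_up >= min_reps && n_dn == 0L) { called <- TRUE; direction <- "up" }
    if (n_dn >= min_reps && n_up == 0L) { called <- TRUE; direction <- "down" }
    if (called && strict_reciprocal) {
      pass_or <- measurements$orientation[i][if (direction == "up") up else dn]
      orients <- unique(measurements$orientation)
      if (!all(orients %in% pass_or)) { called <- FALSE; direction <- NA_character_ }
    }
    data.frame(peptide_id = pid,
               protein_id = measurements$protein_id[i[1L]],
               n_obs = length(i), n_passing = max(n_up, n_dn),
               direction = direction, called = called,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$log2_ratios <- lapply(ids, function(pid) {
    i <- idx[[pid]]; i <- i[order(measurements$replicate[i])]
    stats::setNames(l2[i], measurements$replicate[i])
  })
  rownames(out) <- NULL
  out
}

#' Relaxed 1.5-fold differential-phosphorylation calls
#'
#' The same reciprocal-change rule as [call_differential()] at a 1.5-fold
#' threshold, the relaxed criterion used for cross-species comparison of
#' phosphorylated proteins. Relaxed calls are always a superset of the
#' strict 2-fold calls.
#'
#' @inheritParams call_differential
#' @export
call_differential_relaxed <- function(measurements, min_reps = 2L,
                                      strict_reciprocal = FALSE) {
  call_differential(measurements, fold = 1.5, min_reps = min_reps,
                    strict_reciprocal = strict_reciprocal)
}

#' Roll peptide calls up to proteins and count directions
#'
#' A protein is called when at least one of its peptides is called; its
#' direction is the majority direction of its called peptides, with exact
#' ties flagged `"ambiguous"`.
#'
#' @param calls Data frame from [call_differential()].
#' @return List: `proteins` (protein_id, n_peptides_called, direction)
#'   and `counts` (named vector: up, down, ambiguous).
#' @export
summarize_directions <- function(calls) {
  called <- calls[calls$called, , drop = FALSE]
  if (nrow(called) == 0L) {
    return(list(proteins = data.frame(protein_id = character(0),
                                      n_peptides_called = integer(0),
                                      direction = character(0)),
                counts = c(up = 0L, down = 0L, ambiguous = 0L)))
  }
  sp <- split(called$direction, called$protein_id)
  proteins <- data.frame(
    protein_id = names(sp),
    n_peptides_called = vapply(sp, length, 1L),
    direction = vapply(sp, function(d) {
      n_up <- sum(d == "up"); n_dn <- sum(d == "down")
      if (n_up > n_dn) "up" else if (n_dn > n_up) "down" else "ambiguous"
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  counts <- c(up = sum(proteins$direction == "up"),
              down = sum(proteins$direction == "down"),
              ambiguous = sum(proteins$direction == "ambiguous"))
  list(proteins = proteins, counts = counts)
}
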