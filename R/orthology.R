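#' Parse tabular BLAST output (outfmt 6)
#'
#' Reads the standard 12-column tab-separated BLAST format (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore). Rows whose e-value or bitscore fail to parse are
#' rejected with a warning naming the offending line numbers; a wrong
#' column count is an error.
#'
#' @param path Path to the TSV file.
#' @return Data frame of typed hits (possibly 0 rows for an empty file).
#' @export
parse_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12L), cols))
    out$evalue <- numeric(0); out$bitscore <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12L))
    stop("expected 12 tab-separated columns; offending line(s): ",
         paste(utils::head(which(nfield != 12L), 5L), collapse = ", "))
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  ev <- suppressWarnings(as.numeric(m[, 11L]))
  bs <- suppressWarnings(as.numeric(m[, 12L]))
  bad <- is.na(ev) | is.na(bs) | ev < 0 | bs <= 0
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad), collapse = ", "))
    m <- m[!bad, , drop = FALSE]; ev <- ev[!bad]; bs <- bs[!bad]
  }
  data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
             pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
             mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
             qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
             sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
             evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

#' Best BLAST hit per query under an e-value threshold
#'
#' Keeps, per query, the subject with the lowest e-value among hits with
#' e-value at or below `emax` (default 1e-10). Ties are broken by higher
#' bitscore, then lexicographically smaller subject id, so the result is
#' invariant to input row order. Queries with no qualifying hit are
#' absent from the output.
#'
#' @param hits Data frame with at least `qseqid`, `sseqid`, `evalue`,
#'   `bitscore` (one search direction).
#' @param emax E-value threshold.
#' @param collapse_pattern Optional regex: query/subject ids are reduced
#'   to gene ids via `sub(collapse_pattern, "", id)` before best-hit
#'   selection (isoform collapsing; default off).
#' @return Data frame `qseqid`, `sseqid`, `evalue`, `bitscore`.
#' @export
best_hits <- function(hits, emax = 1e-10, collapse_pattern = NULL) {
  if (!is.null(collapse_pattern)) {
    hits$qseqid <- sub(collapse_pattern, "", hits$qseqid)
    hits$sseqid <- sub(collapse_pattern, "", hits$sseqid)
  }
  hits <- hits[hits$evalue <= emax, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(hits[, c("qseqid", "sseqid", "evalue", "bitscore")])
  o <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[o, , drop = FALSE]
  best <- hits[!duplicated(hits$qseqid), c("qseqid", "sseqid", "evalue",
                                           "bitscore")]
  rownames(best) <- NULL
  best
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is an RBH ortholog when b is a's best hit in the A-to-B
#' search and a is b's best hit in the B-to-A search. Each gene appears
#' in at most one pair, so the map is a partial bijection;
#' `rbh(ba, ab)` yields the mirrored pair set.
#'
#' @param best_ab,best_ba Data frames from [best_hits()] for the two
#'   search directions.
#' @return Data frame `gene_a`, `gene_b`, `evalue_ab`, `evalue_ba`,
#'   sorted by `gene_a`.
#' @export
rbh <- function(best_ab, best_ba) {
  m <- merge(best_ab, best_ba,
             by.x = c("qseqid", "sseqid"), by.y = c("sseqid", "qseqid"),
             suffixes = c("_ab", "_ba"))
  out <- data.frame(gene_a = m$qseqid, gene_b = m$sseqid,
                    evalue_ab = m$evalue_ab, evalue_ba = m$evalue_ba,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap between two gene sets, with optional ortholog translation
#'
#' Computes the intersection of a query set with a reference set, after
#' translating the query through an ortholog map when the two sets live
#' in different species, and reports the overlap as a percentage of the
#' stated reference set (2-decimal display rounding).
#'
#' @param query Character vector of query gene ids.
#' @param reference Character vector of reference gene ids (the
#'   denominator of the percentage).
#' @param map Optional ortholog map: a data frame whose first two columns
#'   are query-species and reference-species gene ids (e.g. from
#'   [rbh()]), or `NULL` for identity.
#' @return List: `n_query`, `n_reference`, `n_overlap`, `overlap_genes`,
#'   `percentage` (of the reference set, rounded to 2 decimals).
#' @export
overlap_stats <- function(query, reference, map = NULL) {
  if (length(reference) == 0L) stop("reference set is empty")
  query <- unique(query); reference <- unique(reference)
  translated <- if (is.null(map)) query else {
    unique(map[[2L]][map[[1L]] %in% query])
  }
  ov <- intersect(translated, reference)
  list(n_query = length(query), n_reference = length(reference),
       n_overlap = length(ov), overlap_genes = sort(ov),
       percentage = round(100 * length(ov) / length(reference), 2L))
}

#' Fisher enrichment of a category within a gene list
#'
#' Two-sided Fisher's exact test on the 2x2 table (in list / not in list)
#' x (in category / not in category) over a declared gene universe, as
#' used e.g. to test enrichment of ciliary genes among osmotically
#' regulated transcripts.
#'
#' @param gene_list,category Character vectors, both subsets of
#'   `universe`.
#' @param universe Character vector of all genes considered.
#' @return List: `table` (2x2 matrix), `p` (two-sided), `odds_ratio`
#'   (sample odds ratio ad/bc).
#' @export
fisher_enrichment <- function(gene_list, category, universe) {
  universe <- unique(universe)
  gene_list <- unique(gene_list); category <- unique(category)
  if (!all(gene_list %in% universe)) stop("gene_list must be within universe")
  if (!all(category %in% universe)) stop("category must be within universe")
  a <- length(intersect(gene_list, category))
  b <- length(setdiff(gene_list, category))
  c_ <- length(setdiff(category, gene_list))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, c_, b, d), 2L, 2L,
                dimnames = list(in_list = c("yes", "no"),
                                in_category = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (a * d) / (b * c_)
  list(table = tab, p = p, odds_ratio = or)
}
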