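# Independent oracles used by multiple test files. These deliberately take
# the slow/explicit route so they share no code path with the package.

# Brute-force null distribution of the gene-vs-background conditional
# test: enumerate all k^n labelled assignments of n alleles to bins,
# computing each assignment's probability by sequential draws without
# replacement from the background pool, then sum over orderings to get
# the probability of each gene-row outcome (bin-count composition).
oracle_outcomes <- function(background, n) {
  k <- length(background)
  asg <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  prob_of <- function(bins) {
    pool <- background
    N <- sum(pool)
    p <- 1
    for (b in bins) {
      if (pool[b] == 0) return(0)
      p <- p * pool[b] / N
      pool[b] <- pool[b] - 1
      N <- N - 1
    }
    p
  }
  comp_key <- apply(asg, 1, function(b) paste(tabulate(b, k), collapse = ","))
  probs <- apply(asg, 1, prob_of)
  outp <- tapply(probs, comp_key, sum)
  outp[outp > 0]
}

# Two-sided p from the brute-force outcome distribution.
oracle_gene_p <- function(gene, background) {
  outp <- oracle_outcomes(background, sum(gene))
  obs_key <- paste(gene, collapse = ",")
  stopifnot(obs_key %in% names(outp))
  pobs <- outp[[obs_key]]
  sum(outp[outp <= pobs * (1 + 1e-9)])
}

# Step-up BH q-values straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive Kapur threshold: try every cut, recompute entropies naively.
oracle_kapur <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA
  for (t in 0:(length(p) - 1L)) {
    lo <- p[seq_len(t + 1L)]; hi <- p[-seq_len(t + 1L)]
    if (sum(lo) == 0 || sum(hi) == 0) next
    ent <- function(w) { w <- w[w > 0] / sum(w); -sum(w * log(w)) }
    tot <- ent(lo) + ent(hi)
    if (tot > best + 1e-12) { best <- tot; best_t <- t }
  }
  best_t
}

# Two-sided 2x2 hypergeometric p by direct enumeration.
oracle_fisher_2x2 <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Minimal toy plate layout used across plate tests.
toy_layout <- function() {
  data.frame(
    row = rep(1:2, each = 4), col = rep(1:4, 2),
    genotype = c("wt", "wt", "mutA", "mutA", "wt", "mutB", "mutB", "empty"),
    is_wt = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    excluded = FALSE, stringsAsFactors = FALSE
  )
}
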