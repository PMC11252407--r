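# Exact conditional test of a gene's allele-bin vector against the screen
# background. This is the gene-level test of the pooled screen: a 2 x 8
# table (gene alleles vs all other insertions, columns = phi bins) with
# both margins fixed, so the gene row follows a multivariate
# hypergeometric distribution. The two-sided p-value sums the
# probabilities of all gene-row outcomes no more probable than the
# observed one (the standard Fisher r x c convention).

# All compositions of n into k non-negative parts, as an (m x k) matrix.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- vector("list", n + 1L)
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# log multivariate hypergeometric pmf of gene rows K (m x 8) given
# background column margins bg and gene-row total n.
lmvhyper <- function(K, bg, n) {
  N <- sum(bg)
  lp <- rowSums(lchoose(matrix(bg, nrow(K), length(bg), byrow = TRUE), K)) -
    lchoose(N, n)
  lp[apply(K > matrix(bg, nrow(K), length(bg), byrow = TRUE), 1L, any)] <- -Inf
  lp
}

# Draw `draws` gene rows from the multivariate hypergeometric with column
# margins bg and row total n (sequential conditional hypergeometrics).
rmvhyper <- function(draws, bg, n) {
  k <- length(bg)
  K <- matrix(0L, draws, k)
  left <- rep.int(n, draws)
  pool_rest <- rev(cumsum(rev(bg)))  # bg_j + ... + bg_k
  for (j in seq_len(k - 1L)) {
    K[, j] <- stats::rhyper(draws, m = bg[j], n = pool_rest[j + 1L], k = left)
    left <- left - K[, j]
  }
  K[, k] <- left
  K
}

#' Exact gene-vs-background test on the 8-bin phenotype table
#'
#' Tests whether a gene's distribution of allele phenotype ratios over the
#' 8 \eqn{\Phi} bins differs from the distribution over all insertions in
#' the screen. Conditioning on both margins of the 2 x 8 table (gene row
#' vs background-minus-gene row), the gene row is multivariate
#' hypergeometric; the two-sided p-value is the total probability of all
#' gene-row outcomes whose probability does not exceed that of the
#' observed row (ties included, with a 1e-12 relative tolerance).
#'
#' For `n_alleles <= exact_cap` the outcome space (compositions of
#' `n_alleles` into 8 bins, at most 50,388 for the default cap of 12) is
#' enumerated exactly. Above the cap a seeded Monte-Carlo estimate over
#' `mc_draws` gene rows is returned and flagged.
#'
#' @param gene 8-vector of the gene's qualified-allele counts per bin, or
#'   a list from [gene_contingency()] (then `background` is taken from it).
#' @param background 8-vector over all qualified insertions, including the
#'   gene's own alleles.
#' @param exact_cap Largest `n_alleles` handled by exact enumeration.
#' @param mc_draws Monte-Carlo draws used above the cap (minimum 1e5).
#' @param seed Seed for the Monte-Carlo path (ignored on the exact path).
#' @return List: `p`, `method` ("exact" or "monte-carlo"), `n_alleles`,
#'   and for the Monte-Carlo path `draws` and `se`.
#' @export
fisher_gene_p <- function(gene, background = NULL, exact_cap = 12L,
                          mc_draws = 1e5, seed = NULL) {
  if (is.list(gene)) {
    background <- background %||% gene$background
    if (isFALSE(gene$include_gene)) background <- background + gene$gene
    gene <- gene$gene
  }
  gene <- as.integer(gene); background <- as.integer(background)
  if (length(gene) != length(background))
    stop("gene and background vectors must have equal length")
  if (any(gene < 0) || any(background < 0)) stop("counts must be >= 0")
  if (any(gene > background))
    stop("background must include the gene's alleles (gene <= background)")
  if (sum(background) == 0L) stop("background table is empty")
  n <- sum(gene)
  if (n < 1L) stop("gene must have at least one qualified allele")

  lobs <- lmvhyper(matrix(gene, 1L), background, n)
  tol <- 1e-12
  if (n <= exact_cap) {
    K <- compositions(n, length(background))
    lp <- lmvhyper(K, background, n)
    keep <- is.finite(lp)
    p <- sum(exp(lp[keep][lp[keep] <= lobs + tol]))
    list(p = min(p, 1), method = "exact", n_alleles = n)
  } else {
    mc_draws <- max(as.integer(mc_draws), 1e5L)
    K <- with_seed(seed, rmvhyper(mc_draws, background, n))
    hit <- lmvhyper(K, background, n) <= lobs + tol
    p <- mean(hit)
    list(p = p, method = "monte-carlo", n_alleles = n, draws = mc_draws,
         se = sqrt(p * (1 - p) / mc_draws))
  }
}
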