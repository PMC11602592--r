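#' Normalize an isoform count matrix to CPM or TPM
#'
#' CPM: counts scaled to one million per sample. TPM: counts are first
#' divided by isoform length, then scaled so every sample sums to one
#' million (when the sample has any signal). All-zero samples are
#' returned as zeros with a warning.
#'
#' @param counts A [count_matrix()].
#' @param mode `"CPM"` or `"TPM"`.
#' @return A numeric matrix with the same dimnames as `counts$counts`.
#' @export
normalize_counts <- function(counts, mode = c("TPM", "CPM")) {
  mode <- match.arg(mode)
  m <- counts$counts
  if (all(colSums(m) == 0)) stop("all samples have zero total count")
  base <- if (mode == "CPM") m else m / counts$isoform_lengths
  tot <- colSums(base)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s) returned as zeros: ",
            paste(colnames(m)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(base, 2L, tot, "/") * 1e6
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up FDR adjustment; order-preserving and capped at 1.
#' @param p_values Numeric vector of p values in `[0, 1]` (NA allowed).
#' @return Numeric vector of q values.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration over all rank assignments (midranks under ties) when
#' the combined sample size is at most 12; otherwise the normal
#' approximation with the tie-corrected variance, without continuity
#' correction. The statistic is the rank sum of `y` minus its minimum
#' (the Mann-Whitney U of `y`); `alternative = "greater"` tests whether
#' `y` tends to exceed `x`.
#'
#' @param x,y Numeric samples (length >= 1).
#' @param alternative `"two.sided"`, `"greater"` (y > x) or `"less"`.
#' @param exact_max Combined size at or below which exact enumeration is
#'   used.
#' @return A list with `statistic` (U of y), `p_value`, `n`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max = 12L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[(n1 + 1L):n])                   # rank sum of y (midranks)
  U <- W - n2 * (n2 + 1) / 2
  if (n <= exact_max) {
    combs <- utils::combn(n, n2)
    sums <- colSums(matrix(r[combs], nrow = n2))
    eps <- 1e-9
    p_ge <- mean(sums >= W - eps)
    p_le <- mean(sums <= W + eps)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n2 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu) / sqrt(sigma2)
      p <- switch(alternative,
                  greater = stats::pnorm(z, lower.tail = FALSE),
                  less = stats::pnorm(z),
                  two.sided = min(1, 2 * stats::pnorm(-abs(z))))
    }
    method <- "normal-tie-corrected"
  }
  list(statistic = U, p_value = max(p, .Machine$double.xmin), n = n,
       method = method)
}

#' Chi-square test of independence (no continuity correction)
#'
#' Classical Pearson statistic on an r x k table of non-negative counts
#' with expected counts from the margins.
#'
#' @param table Numeric matrix of non-negative counts.
#' @return A list with `statistic`, `df`, `p_value`, `expected`, `n`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("table cells must be non-negative")
  if (sum(table) <= 0) stop("table total must be positive")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0)) stop("zero row margin in row ", which(rs == 0)[1L])
  if (any(cs == 0)) stop("zero column margin in column ", which(cs == 0)[1L])
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected, n = sum(table))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. Constant input returns `NA` with a
#' warning (rank correlation is undefined there).
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need two equal-length samples of size >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Exact two-sided binomial test of a proportion against 0.5
#' @param successes,n Counts.
#' @return The two-sided p value.
#' @export
exact_binomial_p <- function(successes, n) {
  if (n == 0L) return(NA_real_)
  stats::binom.test(successes, n, p = 0.5)$p.value
}

# Welch t test on logit-transformed fractions; the shared stand-in
# engine behind test_switch() and test_ir_usage(). Returns the p value.
# eps guards the transform at 0/1: logit(x) = log((x+eps)/(1-x+eps)).
welch_logit_p <- function(f1, f2, eps = 0.01) {
  f1 <- f1[!is.na(f1)]; f2 <- f2[!is.na(f2)]
  if (length(f1) < 2L || length(f2) < 2L) return(NA_real_)
  l1 <- log((f1 + eps) / (1 - f1 + eps))
  l2 <- log((f2 + eps) / (1 - f2 + eps))
  if (stats::sd(l1) < 1e-12 && stats::sd(l2) < 1e-12) {
    return(if (abs(mean(l1) - mean(l2)) < 1e-12) 1 else .Machine$double.xmin)
  }
  stats::t.test(l2, l1)$p.value
}
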