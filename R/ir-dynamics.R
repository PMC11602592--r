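#' Aggregated IR fraction per gene and sample
#'
#' Counts of IR-labeled isoforms are summed per gene and divided by the
#' gene total, giving the aggregated IR isoform fraction (the non-IR
#' fraction is its complement). Samples where the gene total is 0 are
#' `NA`.
#'
#' @param counts A [count_matrix()].
#' @param design A [sample_design()] data.frame.
#' @param gene_map Named vector isoform_id -> gene_id.
#' @param ir_labels Named logical vector per isoform (from
#'   [find_retained_introns()] non-emptiness), covering every isoform.
#' @return A list of class `aggregated_ir_table`: `ir_fraction` (gene x
#'   sample), `gene_totals`, `design`.
#' @export
aggregate_ir_fraction <- function(counts, design, gene_map, ir_labels) {
  m <- counts$counts[, design$sample_id, drop = FALSE]
  miss <- setdiff(rownames(m), names(ir_labels))
  if (length(miss)) stop("unlabeled isoforms: ",
                         paste(utils::head(miss), collapse = ", "))
  genes <- gene_map[rownames(m)]
  if (anyNA(genes)) stop("isoforms without gene assignment")
  tot <- rowsum(m, group = genes)
  ir <- rowsum(m * ir_labels[rownames(m)], group = genes)
  frac <- ir / tot
  frac[!is.finite(frac)] <- NA
  structure(list(ir_fraction = frac, gene_totals = tot, design = design),
            class = "aggregated_ir_table")
}

#' Aggregated IR dIF between two conditions
#'
#' @param agg An `aggregated_ir_table`.
#' @param condition_pair `c(reference, contrast)`.
#' @return Named numeric vector of per-gene aggregated dIF.
#' @export
aggregate_ir_dif <- function(agg, condition_pair) {
  s1 <- agg$design$sample_id[agg$design$condition == condition_pair[1L]]
  s2 <- agg$design$sample_id[agg$design$condition == condition_pair[2L]]
  rowMeans(agg$ir_fraction[, s2, drop = FALSE], na.rm = TRUE) -
    rowMeans(agg$ir_fraction[, s1, drop = FALSE], na.rm = TRUE)
}

#' Differential IR usage test between two conditions
#'
#' Genes pass the inclusion filters when the gene count is at least
#' `min_gene_expr` in at least `min_samps_gene_expr` samples and the IR
#' aggregate fraction exceeds `min_feature_prop` in at least one sample.
#' Per passing gene, per-replicate aggregated IR fractions are compared
#' between the two conditions with the same logit-Welch engine as
#' [test_switch()]; BH across genes.
#'
#' @param agg An `aggregated_ir_table`.
#' @param condition_pair `c(reference, contrast)`.
#' @param min_gene_expr Minimum gene count (default 10).
#' @param min_samps_gene_expr Number of samples meeting it (default 3).
#' @param min_feature_prop Minimum IR proportion in >= 1 sample
#'   (default 0.01).
#' @param eps Logit offset.
#' @return A data.frame: `gene_id`, `dIF`, `p_value`, `q_value`.
#' @export
test_ir_usage <- function(agg, condition_pair, min_gene_expr = 10,
                          min_samps_gene_expr = 3, min_feature_prop = 0.01,
                          eps = 0.01) {
  keep <- rowSums(agg$gene_totals >= min_gene_expr) >= min_samps_gene_expr &
    apply(agg$ir_fraction, 1L, function(x) any(x > min_feature_prop, na.rm = TRUE))
  if (!any(keep)) {
    warning("all genes removed by the expression/proportion filters")
    return(data.frame(gene_id = character(0), dIF = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  s1 <- agg$design$sample_id[agg$design$condition == condition_pair[1L]]
  s2 <- agg$design$sample_id[agg$design$condition == condition_pair[2L]]
  genes <- rownames(agg$ir_fraction)[keep]
  dif <- aggregate_ir_dif(agg, condition_pair)[genes]
  p <- vapply(genes, function(g) {
    welch_logit_p(agg$ir_fraction[g, s1], agg$ir_fraction[g, s2], eps)
  }, numeric(1))
  data.frame(gene_id = genes, dIF = unname(dif), p_value = unname(p),
             q_value = bh_fdr(unname(p)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare aggregated IR dIF between two gene sets
#'
#' One-sided rank-sum test that set A's aggregated dIF exceeds set B's
#' (e.g. interferon-stimulated genes vs housekeeping genes), with
#' per-set medians and interquartile ranges.
#'
#' @param agg_dif Named numeric vector of per-gene aggregated dIF.
#' @param setA,setB Character vectors of gene ids (>= 3 genes with
#'   defined dIF each).
#' @return A list: `p_value`, `statistic`, `n_A`, `n_B`, `summary`
#'   (data.frame of median and IQR per set).
#' @export
compare_genesets <- function(agg_dif, setA, setB) {
  a <- agg_dif[intersect(setA, names(agg_dif))]
  b <- agg_dif[intersect(setB, names(agg_dif))]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("both gene sets need >= 3 genes with defined aggregated dIF")
  }
  w <- wilcoxon_rank_sum(b, a, alternative = "greater")
  list(p_value = w$p_value, statistic = w$statistic,
       n_A = length(a), n_B = length(b),
       summary = data.frame(
         set = c("A", "B"),
         median = c(stats::median(a), stats::median(b)),
         iqr = c(stats::IQR(a), stats::IQR(b))))
}

#' Screen splicing-factor expression against IR isoform expression
#'
#' Spearman correlation between every (factor gene, IR isoform) pair of
#' expression profiles across samples; pairs at or below
#' `-rho_threshold` are flagged as candidate negative regulators.
#' Factor genes that themselves carry IR-labeled isoforms are excluded.
#' Expression is expected on a variance-stabilized scale, e.g.
#' `log2(CPM + 1)` via [log_cpm()].
#'
#' @param factor_expr Numeric matrix, factor genes x samples.
#' @param ir_expr Numeric matrix, IR isoforms x samples (same columns).
#' @param rho_threshold Flag threshold on -rho (default 0.9).
#' @param exclude_factors Factor gene ids to exclude (those with their
#'   own IR isoforms).
#' @return A data.frame: `factor_gene`, `ir_isoform`, `rho`, `flagged`.
#' @export
correlate_factors <- function(factor_expr, ir_expr, rho_threshold = 0.9,
                              exclude_factors = character(0)) {
  if (ncol(factor_expr) < 4L) stop("need >= 4 samples")
  if (!identical(colnames(factor_expr), colnames(ir_expr))) {
    stop("factor and IR expression matrices must share samples")
  }
  keep <- setdiff(rownames(factor_expr), exclude_factors)
  rows <- list()
  for (f in keep) {
    fx <- factor_expr[f, ]
    if (stats::sd(fx) == 0) {
      message("constant expression for factor ", f, "; skipped")
      next
    }
    for (iso in rownames(ir_expr)) {
      ix <- ir_expr[iso, ]
      if (stats::sd(ix) == 0) next
      rho <- suppressWarnings(spearman_correlation(fx, ix))
      rows[[length(rows) + 1L]] <- data.frame(
        factor_gene = f, ir_isoform = iso, rho = rho,
        flagged = !is.na(rho) && rho <= -rho_threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(factor_gene = character(0), ir_isoform = character(0),
                      rho = numeric(0), flagged = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' log2(CPM + 1) expression
#' @param counts A [count_matrix()].
#' @return A numeric matrix on the log2 scale.
#' @export
log_cpm <- function(counts) {
  log2(normalize_counts(counts, "CPM") + 1)
}
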