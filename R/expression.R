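#' Remove low-expression genes
#'
#' Drops genes whose total count across all samples is strictly below
#' `min_total` (so a row sum equal to `min_total` is kept).
#'
#' @param mat Non-negative integer count matrix (genes x samples).
#' @param min_total Minimum total count.
#' @return Filtered matrix.
#' @export
filter_low_counts <- function(mat, min_total = 10L) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  mat[rowSums(mat) >= min_total, , drop = FALSE]
}

## DESeq-style median-of-ratios size factors
size_factors <- function(mat) {
  logg <- rowMeans(log(mat))
  use <- is.finite(logg)
  if (!any(use))
    return(stats::setNames(rep(1, ncol(mat)), colnames(mat)))
  sf <- apply(mat[use, , drop = FALSE], 2L,
              function(col) exp(stats::median(log(col) - logg[use])))
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' Stand-in differential expression test
#'
#' A documented replacement for a full negative-binomial GLM fit, used
#' when only the downstream integration is of interest: counts are
#' normalised by median-of-ratios size factors, the log2 fold change is
#' `log2((mean normalised drought + 0.5) / (mean normalised control +
#' 0.5))`, and the p-value comes from a Welch two-sample t-test on
#' log2(normalised count + 0.5), Benjamini-Hochberg adjusted across
#' genes. Precomputed DE tables with the same columns can be used
#' anywhere this function's output is accepted.
#'
#' @param mat Count matrix (genes x samples).
#' @param samples Sample sheet data frame.
#' @param group Phenotype group to test (`"tolerant"` or
#'   `"sensitive"`); drought vs control within that group.
#' @return Data frame with `gene_id`, `log2fc`, `pvalue`, `padj`,
#'   `direction` (`up` iff log2fc > 0).
#' @export
standin_de_test <- function(mat, samples, group) {
  sel <- samples[samples$group == group, , drop = FALSE]
  ctrl <- sel$sample_id[sel$treatment == "control"]
  drt <- sel$sample_id[sel$treatment == "drought"]
  if (length(ctrl) < 2L || length(drt) < 2L)
    stop_fmt("need at least 2 samples per condition in group '%s'", group)
  m <- mat[, c(ctrl, drt), drop = FALSE]
  sf <- size_factors(m)
  norm <- sweep(m, 2L, sf, "/")
  nc <- norm[, ctrl, drop = FALSE]; nd <- norm[, drt, drop = FALSE]
  log2fc <- log2((rowMeans(nd) + 0.5) / (rowMeans(nc) + 0.5))
  lc <- log2(nc + 0.5); ld <- log2(nd + 0.5)
  m1 <- rowMeans(lc); m2 <- rowMeans(ld)
  v1 <- apply(lc, 1L, stats::var); v2 <- apply(ld, 1L, stats::var)
  n1 <- ncol(lc); n2 <- ncol(ld)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(m2[se2 == 0] == m1[se2 == 0], 1, 0)
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(mat), log2fc = log2fc, pvalue = p,
             padj = padj, direction = ifelse(log2fc > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `padj < padj_max` and `|log2fc| > lfc_min` (both
#' strict).
#'
#' @param records DE table with `gene_id`, `log2fc`, `padj`.
#' @param padj_max Adjusted-p threshold.
#' @param lfc_min Absolute log2 fold-change threshold.
#' @return Filtered DE table.
#' @export
filter_degs <- function(records, padj_max = 0.05, lfc_min = 1.0) {
  if (!"padj" %in% names(records) || anyNA(records$padj))
    stop_fmt("DE table must have a complete padj column")
  out <- records[records$padj < padj_max & abs(records$log2fc) > lfcmin_chk(lfc_min), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

lfcmin_chk <- function(x) { stopifnot(is.numeric(x), x >= 0); x }

#' DEG set algebra between the two phenotype groups
#'
#' Totals, intersection, group-specific counts, the sensitive:tolerant
#' fold ratio (1 decimal place) and up-regulated proportions (percent,
#' 1 decimal place).
#'
#' @param sensitive,tolerant DEG tables (must contain `gene_id`;
#'   up/down proportions require a `direction` column).
#' @return List with `total_sensitive`, `total_tolerant`, `common`,
#'   `specific_sensitive`, `specific_tolerant`, `fold_ratio`,
#'   `up_pct_sensitive`, `up_pct_tolerant`.
#' @export
deg_set_algebra <- function(sensitive, tolerant) {
  s_ids <- unique(sensitive$gene_id); t_ids <- unique(tolerant$gene_id)
  if (length(t_ids) == 0L)
    stop_fmt("tolerant DEG set is empty: fold ratio undefined")
  common <- intersect(s_ids, t_ids)
  up_pct <- function(df) {
    if (!"direction" %in% names(df) || nrow(df) == 0L) return(NA_real_)
    round(100 * sum(df$direction == "up") / nrow(df), 1L)
  }
  list(total_sensitive = length(s_ids), total_tolerant = length(t_ids),
       common = length(common),
       specific_sensitive = length(setdiff(s_ids, t_ids)),
       specific_tolerant = length(setdiff(t_ids, s_ids)),
       fold_ratio = round(length(s_ids) / length(t_ids), 1L),
       up_pct_sensitive = up_pct(sensitive),
       up_pct_tolerant = up_pct(tolerant))
}
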