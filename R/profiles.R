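#' Weighted methylation level of a region
#'
#' The field-standard weighted level: sum of methylated reads divided by
#' sum of total reads over the region's cytosines of one context, using
#' only cytosines passing the coverage filter. Positions are interpreted
#' against 0-based half-open region coordinates (a 1-based cytosine at
#' `pos` lies in the region when `start <= pos-1 < end`).
#'
#' @param records Cytosine-record data frame.
#' @param chrom Chromosome name.
#' @param start,end Region bounds, 0-based half-open.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_coverage Minimum reads for a cytosine to contribute.
#' @return Fraction in `[0,1]`, or `NA_real_` when no covered cytosine
#'   falls in the region (a no-data marker, deliberately distinct from
#'   zero methylation).
#' @export
weighted_methylation <- function(records, chrom, start, end, context,
                                 min_coverage = 4L) {
  stopifnot(min_coverage >= 1L, end > start)
  if (!context %in% CONTEXTS) stop_fmt("unknown context '%s'", context)
  sel <- records$chrom == chrom & records$context == context &
    records$n_total >= min_coverage &
    (records$pos - 1L) >= start & (records$pos - 1L) < end
  tot <- sum(records$n_total[sel])
  if (tot == 0L) return(NA_real_)
  sum(records$n_meth[sel]) / tot
}

#' Global per-context methylation summary
#'
#' For each context, the genome-wide weighted methylation level (as a
#' percentage) and the share of all methylated-cytosine read calls
#' attributed to that context, over cytosines passing the coverage
#' filter. The shares sum to 100.
#'
#' @param records Cytosine-record data frame.
#' @param min_coverage Minimum reads per cytosine.
#' @return Data frame with `context`, `mean_level` (percent) and
#'   `pct_of_total_mC` (percent).
#' @export
global_context_summary <- function(records, min_coverage = 4L) {
  if (nrow(records) == 0L) stop_fmt("empty record set")
  r <- records[records$n_total >= min_coverage, , drop = FALSE]
  meth <- vapply(CONTEXTS, function(cx) sum(as.numeric(r$n_meth[r$context == cx])),
                 numeric(1))
  tot <- vapply(CONTEXTS, function(cx) sum(as.numeric(r$n_total[r$context == cx])),
                numeric(1))
  if (sum(meth) == 0)
    stop_fmt("no methylated calls: percentage of total mC is undefined")
  data.frame(context = CONTEXTS,
             mean_level = ifelse(tot > 0, 100 * meth / tot, NA_real_),
             pct_of_total_mC = 100 * meth / sum(meth),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign genes to six expression groups
#'
#' Genes with mean expression exactly zero form the `none` group; the
#' remaining genes are split by rank into five equal-size groups
#' (`low` ... `high`). Ties are broken by stable gene-id order, so group
#' membership is invariant under any monotone transform of expression.
#'
#' @param mean_expression Named non-negative numeric vector (names are
#'   gene ids).
#' @return Named character vector of group labels.
#' @export
expression_sextiles <- function(mean_expression) {
  if (length(mean_expression) == 0L) stop_fmt("empty expression vector")
  if (any(mean_expression < 0)) stop_fmt("negative mean expression")
  ids <- names(mean_expression)
  if (is.null(ids)) ids <- as.character(seq_along(mean_expression))
  lab <- rep("none", length(mean_expression))
  nz <- which(mean_expression > 0)
  if (length(nz) > 0L) {
    o <- nz[order(mean_expression[nz], ids[nz])]
    grp <- ceiling(seq_along(o) * 5 / length(o))
    lab[o] <- c("low", "medium-low", "medium", "medium-high", "high")[grp]
  }
  stats::setNames(lab, ids)
}

EXPRESSION_GROUPS <- c("none", "low", "medium-low", "medium",
                       "medium-high", "high")

#' Metagene methylation profile by expression group
#'
#' Computes the classic three-segment profile: the upstream flank, the
#' gene body and the downstream flank of each gene are each divided into
#' `bins_per_segment` bins (150 bins in total with the default of 50).
#' Bin 1 is always most-5' regardless of strand; minus-strand genes are
#' coordinate-reflected. Within each gene, a bin's value is the weighted
#' methylation level of the covered cytosines falling in the bin; group
#' values are means across the group's genes with data in that bin.
#' Genes shorter than `bins_per_segment` bp are binned by fractional
#' coordinates rather than rejected.
#'
#' @param genes Gene-model data frame.
#' @param records Cytosine-record data frame.
#' @param expression_groups Named character vector mapping every gene id
#'   to one of the six expression-group labels.
#' @param flank Flank width in bp.
#' @param bins_per_segment Bins per segment.
#' @param contexts Contexts to profile.
#' @param min_coverage Minimum reads per cytosine.
#' @return Long data frame with `context`, `expression_group`, `bin`
#'   (1..3*bins_per_segment), `level` (`NA` when no gene has data) and
#'   `n_genes` contributing.
#' @export
metagene_profile <- function(genes, records, expression_groups,
                             flank = 2000L, bins_per_segment = 50L,
                             contexts = CONTEXTS, min_coverage = 4L) {
  stopifnot(nrow(genes) > 0L)
  miss <- setdiff(genes$gene_id, names(expression_groups))
  if (length(miss) > 0L)
    stop_fmt("no expression group for gene(s): %s",
             paste(utils::head(miss, 3L), collapse = ", "))
  if (any(!expression_groups %in% EXPRESSION_GROUPS))
    stop_fmt("invalid expression group label")
  B <- as.integer(bins_per_segment)
  nbin <- 3L * B
  rec <- records[records$n_total >= min_coverage &
                   records$context %in% contexts, , drop = FALSE]
  out <- list()
  ext <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - flank + 1L), genes$end + flank))
  for (cx in contexts) {
    rc <- rec[rec$context == cx, , drop = FALSE]
    lev_mat <- NULL
    if (nrow(rc) > 0L) {
      pts <- GenomicRanges::GRanges(rc$chrom, IRanges::IRanges(rc$pos, rc$pos))
      hits <- GenomicRanges::findOverlaps(pts, ext)
      if (length(hits) > 0L) {
        si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
        x <- rc$pos[si] - 0.5                 # site centre, 0-based scale
        gs <- genes$start[gi]; ge <- genes$end[gi]
        plus <- genes$strand[gi] == "+"
        w <- ge - gs
        seg <- ifelse(x < gs, ifelse(plus, 1L, 3L),
                      ifelse(x < ge, 2L, ifelse(plus, 3L, 1L)))
        frac <- numeric(length(x))
        upL <- x < gs; body <- x >= gs & x < ge; dnR <- x >= ge
        frac[upL] <- ifelse(plus[upL],
                            (x[upL] - (gs[upL] - flank)) / flank,
                            (gs[upL] - x[upL]) / flank)
        frac[body] <- ifelse(plus[body],
                             (x[body] - gs[body]) / w[body],
                             (ge[body] - x[body]) / w[body])
        frac[dnR] <- ifelse(plus[dnR],
                            (x[dnR] - ge[dnR]) / flank,
                            ((ge[dnR] + flank) - x[dnR]) / flank)
        bin <- (seg - 1L) * B + pmin(B - 1L, pmax(0L, floor(frac * B))) + 1L
        key <- factor((gi - 1L) * nbin + bin)
        msum <- rowsum(rc$n_meth[si], key)[, 1L]
        tsum <- rowsum(rc$n_total[si], key)[, 1L]
        kk <- as.integer(levels(key))
        lev_mat <- data.frame(gene = (kk - 1L) %/% nbin + 1L,
                              bin = (kk - 1L) %% nbin + 1L,
                              level = msum / tsum)
      }
    }
    grp <- expression_groups[genes$gene_id]
    for (g in EXPRESSION_GROUPS) {
      gene_rows <- which(grp == g)
      if (length(gene_rows) == 0L) next
      sub <- if (is.null(lev_mat)) NULL else
        lev_mat[lev_mat$gene %in% gene_rows, , drop = FALSE]
      if (is.null(sub) || nrow(sub) == 0L) {
        level <- rep(NA_real_, nbin); ngene <- rep(0L, nbin)
      } else {
        level <- as.numeric(tapply(sub$level, factor(sub$bin, levels = 1:nbin),
                                   mean))
        ngene <- as.integer(table(factor(sub$bin, levels = 1:nbin)))
      }
      out[[length(out) + 1L]] <-
        data.frame(context = cx, expression_group = g, bin = 1:nbin,
                   level = level, n_genes = ngene, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Window-level sample correlation matrix
#'
#' Computes the weighted methylation level of each fixed-width genomic
#' window in each sample, then the pairwise Pearson correlation between
#' samples over windows; windows lacking data in either sample of a pair
#' are excluded pairwise. Pairs with fewer than two usable windows get
#' `NA`.
#'
#' @param cx_list Named list of cytosine-record data frames (>= 2).
#' @param window Window width in bp.
#' @param context Context to use.
#' @param min_coverage Minimum reads per cytosine.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
window_correlation_matrix <- function(cx_list, window = 2000L,
                                      context = "CHH", min_coverage = 4L) {
  if (length(cx_list) < 2L) stop_fmt("need at least two samples")
  if (is.null(names(cx_list)))
    names(cx_list) <- paste0("sample", seq_along(cx_list))
  lev <- lapply(cx_list, function(r) {
    r <- r[r$context == context & r$n_total >= min_coverage, , drop = FALSE]
    if (nrow(r) == 0L) return(stats::setNames(numeric(), character()))
    win <- paste(r$chrom, (r$pos - 1L) %/% window, sep = ":")
    f <- factor(win)
    m <- rowsum(r$n_meth, f)[, 1L]; t <- rowsum(r$n_total, f)[, 1L]
    stats::setNames(m / t, levels(f))
  })
  wins <- sort(unique(unlist(lapply(lev, names))))
  M <- vapply(lev, function(v) v[wins], numeric(length(wins)))
  rownames(M) <- wins
  cc <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  ## enforce the contract explicitly: <2 shared windows -> NA, diag 1
  n_shared <- crossprod(!is.na(M))
  cc[n_shared < 2L] <- NA_real_
  diag(cc) <- 1
  cc
}
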