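DMR_THRESHOLDS <- c(CG = 0.20, CHG = 0.15, CHH = 0.25)

## exact two-sided two-proportion p-value (doubled hypergeometric tail),
## vectorised. x_* methylated, n_* total reads.
two_prop_exact_p <- function(x1, n1, x2, n2) {
  K <- x1 + x2
  N <- n1 + n2
  up <- stats::phyper(x1 - 1, K, N - K, n1, lower.tail = FALSE)
  lo <- stats::phyper(x1, K, N - K, n1, lower.tail = TRUE)
  pmin(1, 2 * pmin(up, lo))
}

## interval merge: returns a group index per interval such that
## intervals whose gap (start2 - end1, half-open coordinates) is
## <= max_gap share a group. Input need not be sorted.
interval_merge_groups <- function(start, end, max_gap = 0L) {
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  n <- length(s)
  if (n == 0L) return(integer())
  run_end <- cummax(e)
  new_grp <- c(TRUE, s[-1L] > run_end[-n] + max_gap)
  grp <- cumsum(new_grp)
  res <- integer(n)
  res[o] <- grp
  res
}

#' Call candidate differentially methylated regions
#'
#' A documented window-based stand-in for smoothing-based DMR callers:
#' read counts are pooled per sliding window (per chromosome and
#' context), windows with at least `min_cytosines` covered in-context
#' cytosines in both conditions are tested with an exact two-proportion
#' test (doubled hypergeometric tail), and overlapping or book-ended
#' significant windows with the same sign of change are unioned into
#' candidate regions. Each region's methylation levels and delta are
#' those of its strongest (largest |delta|) constituent window --
#' boundary windows straddling a region edge would otherwise dilute the
#' effect size -- and its p-value is the smallest constituent window p.
#'
#' @param control,drought Cytosine-record data frames for one genotype
#'   (pool replicates first with [pool_cx()]).
#' @param window Window width in bp; must be a multiple of `step`.
#' @param step Step size in bp.
#' @param min_cytosines Minimum covered in-context cytosines per window,
#'   required in both conditions.
#' @param alpha Window-level significance threshold.
#' @param genotype_id,group Optional labels copied into the output.
#' @return Data frame of DMR records: `chrom`, `start`, `end` (0-based
#'   half-open), `context`, `meth_control`, `meth_drought`, `delta`
#'   (drought minus control, so positive = drought-hypermethylated),
#'   `p_value`, `genotype_id`, `group`.
#' @export
call_candidate_dmrs <- function(control, drought, window = 200L,
                                step = 50L, min_cytosines = 4L,
                                alpha = 0.05,
                                genotype_id = NA_character_,
                                group = NA_character_) {
  stopifnot(window >= step, window %% step == 0L)
  k <- window %/% step
  out <- list()
  if (nrow(control) > 0L && nrow(drought) > 0L) {
    ctrl_cov <- control[control$n_total > 0L,
                        c("chrom", "context", "pos", "n_meth", "n_total")]
    drt_cov <- drought[drought$n_total > 0L,
                       c("chrom", "context", "pos", "n_meth", "n_total")]
    csplit <- split(seq_len(nrow(ctrl_cov)),
                    paste(ctrl_cov$chrom, ctrl_cov$context, sep = "\r"))
    dsplit <- split(seq_len(nrow(drt_cov)),
                    paste(drt_cov$chrom, drt_cov$context, sep = "\r"))
    combos <- sort(intersect(names(csplit), names(dsplit)))
    for (key in combos) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
      ch <- parts[1L]; cx <- parts[2L]
      cc <- ctrl_cov[csplit[[key]], , drop = FALSE]
      dd <- drt_cov[dsplit[[key]], , drop = FALSE]
      maxbin <- max((c(cc$pos, dd$pos) - 1L) %/% step)
      nb <- maxbin + 1L
      binsum <- function(df) {
        b <- (df$pos - 1L) %/% step
        list(m = bin_accumulate(b, df$n_meth, nb),
             t = bin_accumulate(b, df$n_total, nb),
             s = bin_accumulate(b, rep(1L, nrow(df)), nb))
      }
      bc <- binsum(cc); bd <- binsum(dd)
      roll <- function(v) {
        cs <- cumsum(c(0, v))
        idx <- seq_len(max(1L, nb - k + 1L))
        cs[pmin(idx + k, nb + 1L)] - cs[idx]
      }
      mcw <- roll(bc$m); tcw <- roll(bc$t); scw <- roll(bc$s)
      mdw <- roll(bd$m); tdw <- roll(bd$t); sdw <- roll(bd$s)
      elig <- scw >= min_cytosines & sdw >= min_cytosines &
        tcw > 0 & tdw > 0
      if (!any(elig)) next
      p <- rep(NA_real_, length(mcw))
      p[elig] <- two_prop_exact_p(mdw[elig], tdw[elig],
                                  mcw[elig], tcw[elig])
      delta <- mdw / tdw - mcw / tcw
      sig <- which(elig & p < alpha & delta != 0)
      if (length(sig) == 0L) next
      ws <- (sig - 1L) * step
      we <- ws + window
      sgn <- sign(delta[sig])
      for (sg in unique(sgn)) {
        sel <- which(sgn == sg)
        grp_idx <- interval_merge_groups(ws[sel], we[sel], max_gap = 0L)
        widx <- sig[sel]
        ## effect size from the strongest constituent window, so that
        ## boundary windows straddling the region edge do not dilute
        ## the reported delta of the merged region
        o <- order(grp_idx, -abs(delta[widx]))
        first <- o[!duplicated(grp_idx[o])]
        peak <- widx[first]
        ug <- grp_idx[first]
        mc <- mcw[peak] / tcw[peak]
        md <- mdw[peak] / tdw[peak]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start = as.integer(tapply(ws[sel], grp_idx, min)[as.character(ug)]),
          end = as.integer(tapply(we[sel], grp_idx, max)[as.character(ug)]),
          context = cx, meth_control = mc, meth_drought = md,
          delta = md - mc,
          p_value = as.numeric(tapply(p[widx], grp_idx, min)[as.character(ug)]),
          genotype_id = genotype_id, group = group,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_dmrs())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

bin_accumulate <- function(bin0, weight, nbins) {
  v <- numeric(nbins)
  acc <- rowsum(as.numeric(weight), bin0)
  v[as.integer(rownames(acc)) + 1L] <- acc[, 1L]
  v
}

empty_dmrs <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             context = character(), meth_control = numeric(),
             meth_drought = numeric(), delta = numeric(),
             p_value = numeric(), genotype_id = character(),
             group = character(), stringsAsFactors = FALSE)
}

#' Filter DMRs by context-specific effect-size thresholds
#'
#' Keeps a DMR iff its |delta| (fraction scale) strictly exceeds the
#' context threshold: 0.20 for CG, 0.15 for CHG, 0.25 for CHH by
#' default. The comparisons are strict, matching the "greater than"
#' phrasing of the screening rule; the operator is idempotent.
#'
#' @param dmrs DMR data frame with `context` and `delta`.
#' @param thresholds Named per-context thresholds (fractions).
#' @return Filtered DMR data frame.
#' @export
filter_significant <- function(dmrs, thresholds = DMR_THRESHOLDS) {
  if (nrow(dmrs) == 0L) return(dmrs)
  unknown <- setdiff(unique(dmrs$context), names(thresholds))
  if (length(unknown) > 0L)
    stop_fmt("unknown context '%s' in DMR table", unknown[1L])
  keep <- abs(dmrs$delta) > thresholds[dmrs$context]
  out <- dmrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-genotype DMRs into group-conserved DMRs
#'
#' Within one phenotype group, DMRs of the same context and chromosome
#' separated by a gap of at most `max_gap` bp are merged (gap is
#' `start2 - end1` in half-open coordinates; a gap of exactly `max_gap`
#' merges, `max_gap + 1` does not). Each merged region records the
#' number of distinct supporting genotypes, a direction (`hyper` if all
#' contributing deltas are positive, `hypo` if all negative, otherwise
#' `mixed`) and a support-weighted mean delta (the mean over supporting
#' genotypes of each genotype's mean contributing delta, so a genotype
#' fragmented into many pieces does not dominate). Merging is
#' idempotent and its output disjoint per (context, chromosome).
#'
#' @param dmrs DMR data frame; all rows must share one `group`.
#' @param max_gap Maximum merge gap in bp.
#' @return Conserved-DMR data frame with `chrom`, `start`, `end`,
#'   `context`, `group`, `direction`, `n_support`, `mean_delta`.
#' @export
merge_conserved <- function(dmrs, max_gap = 100L) {
  if (nrow(dmrs) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      group = character(), direction = character(),
                      n_support = integer(), mean_delta = numeric(),
                      stringsAsFactors = FALSE))
  grp <- unique(dmrs$group)
  if (length(grp) > 1L)
    stop_fmt("merge_conserved expects DMRs from a single group, got: %s",
             paste(grp, collapse = ", "))
  if (!"genotype_id" %in% names(dmrs)) dmrs$genotype_id <- NA_character_
  if (!"n_support" %in% names(dmrs)) dmrs$n_support <- NA_integer_
  out <- list()
  for (key in unique(paste(dmrs$context, dmrs$chrom, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    d <- dmrs[dmrs$context == parts[1L] & dmrs$chrom == parts[2L], ,
              drop = FALSE]
    g <- interval_merge_groups(d$start, d$end, max_gap = max_gap)
    gid <- ifelse(is.na(d$genotype_id), "<na>", d$genotype_id)
    ## per-genotype mean delta first, then mean across genotypes, so a
    ## genotype fragmented into many pieces does not dominate
    gk <- paste(g, gid, sep = "\r")
    per_geno <- tapply(d$delta, gk, mean)
    pg_grp <- as.integer(sub("\r.*", "", names(per_geno)))
    ug <- sort(unique(g))
    out[[length(out) + 1L]] <- data.frame(
      chrom = parts[2L],
      start = as.integer(tapply(d$start, g, min)[as.character(ug)]),
      end = as.integer(tapply(d$end, g, max)[as.character(ug)]),
      context = parts[1L], group = grp,
      direction = as.character(tapply(d$delta, g, function(x)
        if (all(x > 0)) "hyper" else if (all(x < 0)) "hypo"
        else "mixed")[as.character(ug)]),
      n_support = as.integer(tapply(gid, g, function(x)
        length(unique(x)))[as.character(ug)]),
      mean_delta = as.numeric(tapply(per_geno, pg_grp,
                                     mean)[as.character(ug)]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$context, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter conserved DMRs by genotype support
#'
#' Keeps regions identified in at least `min_genotypes` genotypes of
#' the group.
#'
#' @param conserved Conserved-DMR data frame with `n_support`.
#' @param min_genotypes Minimum supporting genotypes.
#' @return Filtered data frame.
#' @export
support_filter <- function(conserved, min_genotypes = 3L) {
  out <- conserved[conserved$n_support >= min_genotypes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## strand-aware 2-kb flanks as GRanges (1-based closed), given internal
## half-open gene coordinates. Returns list(body, up, down).
gene_feature_ranges <- function(genes, flank) {
  body <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  plus <- genes$strand == "+"
  up_start <- ifelse(plus, genes$start - flank, genes$end)
  up_end <- ifelse(plus, genes$start, genes$end + flank)
  dn_start <- ifelse(plus, genes$end, genes$start - flank)
  dn_end <- ifelse(plus, genes$end + flank, genes$start)
  clip <- function(s, e) {
    s <- pmax(0L, as.integer(s)); e <- pmax(s, as.integer(e))
    IRanges::IRanges(s + 1L, e)   # zero-width allowed, never overlaps
  }
  list(body = body,
       up = GenomicRanges::GRanges(genes$chrom, clip(up_start, up_end)),
       down = GenomicRanges::GRanges(genes$chrom, clip(dn_start, dn_end)))
}

#' Annotate regions with their genomic feature
#'
#' Labels each region `gene_body`, `upstream2k`, `downstream2k` or
#' `intergenic`. Flanks are strand-aware; when a region overlaps
#' several features (or several genes) the highest-precedence label
#' wins, with precedence gene_body > upstream2k > downstream2k >
#' intergenic.
#'
#' @param regions Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes Gene-model data frame.
#' @param flank Flank width in bp.
#' @return Character vector of labels, one per region.
#' @export
annotate_feature <- function(regions, genes, flank = 2000L) {
  if (nrow(regions) == 0L) return(character())
  gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  fr <- gene_feature_ranges(genes, flank)
  lab <- rep("intergenic", nrow(regions))
  for (feat in c("downstream2k", "upstream2k", "gene_body")) {
    target <- switch(feat, gene_body = fr$body, upstream2k = fr$up,
                     downstream2k = fr$down)
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr, target)))
    lab[hit] <- feat
  }
  lab
}

#' Tiered DMR bookkeeping table
#'
#' From per-(group, context, tier) DMR counts, computes the per-context
#' count table, each group's CHH share of all DMRs per tier
#' (CHH / (CG+CHG+CHH) x 100, 1 decimal place), and the percentage
#' excess of the sensitive group over the tolerant group per tier
#' (100 x (S/T - 1), 2 decimal places).
#'
#' @param counts Long data frame with columns `group`, `context`,
#'   `tier`, `n`. Tiers are typically `conserved`, `significant`,
#'   `associated_genes`.
#' @return List with `counts` (input, ordered), `chh_fraction` (per
#'   group and tier) and `excess` (per tier, sensitive over tolerant).
#' @export
dmr_count_table <- function(counts) {
  need <- c("group", "context", "tier", "n")
  if (!all(need %in% names(counts)))
    stop_fmt("counts must have columns group, context, tier, n")
  tiers <- unique(counts$tier)
  groups <- unique(counts$group)
  chh <- list(); exc <- list()
  for (ti in tiers) {
    for (g in groups) {
      sub <- counts[counts$tier == ti & counts$group == g, , drop = FALSE]
      tot <- sum(sub$n)
      chh_n <- sum(sub$n[sub$context == "CHH"])
      chh[[length(chh) + 1L]] <- data.frame(
        group = g, tier = ti,
        chh_pct = if (tot > 0) round(100 * chh_n / tot, 1L) else NA_real_,
        stringsAsFactors = FALSE)
    }
    if (all(c("sensitive", "tolerant") %in% groups)) {
      s_tot <- sum(counts$n[counts$tier == ti & counts$group == "sensitive"])
      t_tot <- sum(counts$n[counts$tier == ti & counts$group == "tolerant"])
      if (t_tot == 0)
        stop_fmt("tolerant total is zero for tier '%s': excess undefined", ti)
      exc[[length(exc) + 1L]] <- data.frame(
        tier = ti, excess_pct = round(100 * (s_tot / t_tot - 1), 2L),
        stringsAsFactors = FALSE)
    }
  }
  list(counts = counts[order(counts$tier, counts$group, counts$context), ],
       chh_fraction = do.call(rbind, chh),
       excess = if (length(exc)) do.call(rbind, exc) else NULL)
}

#' Common DMRs between the two phenotype groups
#'
#' Regions differentially methylated in both groups: the intersection
#' spans of same-context conserved DMRs from the two groups that
#' overlap by at least 1 bp, reduced to disjoint regions per context.
#'
#' @param cons_a,cons_b Conserved-DMR data frames of the two groups.
#' @return Data frame with `chrom`, `start`, `end`, `context`.
#' @export
common_dmrs <- function(cons_a, cons_b) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cons_a) == 0L || nrow(cons_b) == 0L) return(empty)
  out <- list()
  for (cx in intersect(unique(cons_a$context), unique(cons_b$context))) {
    a <- cons_a[cons_a$context == cx, , drop = FALSE]
    b <- cons_b[cons_b$context == cx, , drop = FALSE]
    ga <- GenomicRanges::GRanges(a$chrom,
                                 IRanges::IRanges(a$start + 1L, a$end))
    gb <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(b$start + 1L, b$end))
    common <- GenomicRanges::reduce(GenomicRanges::intersect(ga, gb))
    if (length(common) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(common)),
      start = GenomicRanges::start(common) - 1L,
      end = GenomicRanges::end(common), context = cx,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$context, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-chromosome DMR density and subgenome totals
#'
#' @param conserved Data frame of regions with a `chrom` column.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @return List with `per_chrom` (`chrom`, `n`, `density_per_mb`,
#'   `subgenome`) and `per_subgenome` (`subgenome`, `n`,
#'   `density_per_mb` over the subgenome's total length).
#' @export
chromosome_density <- function(conserved, chrom_lengths) {
  if (any(chrom_lengths <= 0)) stop_fmt("chromosome lengths must be positive")
  missing_len <- setdiff(unique(conserved$chrom), names(chrom_lengths))
  if (length(missing_len) > 0L)
    stop_fmt("no length for chromosome '%s'", missing_len[1L])
  n <- table(factor(conserved$chrom, levels = names(chrom_lengths)))
  per_chrom <- data.frame(chrom = names(chrom_lengths),
                          n = as.integer(n),
                          density_per_mb = as.integer(n) /
                            (unname(chrom_lengths) / 1e6),
                          subgenome = subgenome_of(names(chrom_lengths)),
                          stringsAsFactors = FALSE)
  agg_n <- tapply(per_chrom$n, per_chrom$subgenome, sum)
  agg_l <- tapply(unname(chrom_lengths), per_chrom$subgenome, sum)
  per_sub <- data.frame(subgenome = names(agg_n),
                        n = as.integer(agg_n),
                        density_per_mb = as.numeric(agg_n) / (agg_l / 1e6),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(per_chrom = per_chrom, per_subgenome = per_sub)
}
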