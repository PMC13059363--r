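#' Link conserved DMRs to genes
#'
#' One link per (gene, DMR) pair with at least 1 bp of overlap between
#' the DMR and the gene body or its strand-aware 2-kb flanks. A DMR may
#' link several genes and vice versa; intergenic DMRs produce no link.
#' Placement precedence when a DMR spans several features of one gene:
#' gene_body > upstream2k > downstream2k (so a DMR spanning the TSS is
#' labelled gene_body).
#'
#' @param conserved Conserved-DMR data frame (needs `chrom`, `start`,
#'   `end`, `context`, `mean_delta`; `group` carried through if
#'   present).
#' @param genes Gene-model data frame.
#' @param flank Flank width in bp.
#' @return Data frame of links: `gene_id`, `dmr_index` (row in
#'   `conserved`), `placement`, `context`, `delta`, `width`, plus
#'   `group` when available.
#' @export
associate_dmrs_to_genes <- function(conserved, genes, flank = 2000L) {
  empty <- data.frame(gene_id = character(), dmr_index = integer(),
                      placement = character(), context = character(),
                      delta = numeric(), width = integer(),
                      group = character(), stringsAsFactors = FALSE)
  if (nrow(conserved) == 0L || nrow(genes) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(
    conserved$chrom,
    IRanges::IRanges(conserved$start + 1L, conserved$end))
  fr <- gene_feature_ranges(genes, flank)
  pair_hits <- function(target, label) {
    h <- GenomicRanges::findOverlaps(gr, target)
    if (length(h) == 0L) return(NULL)
    data.frame(dmr = S4Vectors::queryHits(h),
               gene = S4Vectors::subjectHits(h),
               placement = label, stringsAsFactors = FALSE)
  }
  hits <- rbind(pair_hits(fr$body, "gene_body"),
                pair_hits(fr$up, "upstream2k"),
                pair_hits(fr$down, "downstream2k"))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  ## precedence per (gene, DMR) pair
  prec <- c(gene_body = 1L, upstream2k = 2L, downstream2k = 3L)
  hits <- hits[order(hits$gene, hits$dmr, prec[hits$placement]), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits[, c("gene", "dmr")]), , drop = FALSE]
  delta_col <- if ("mean_delta" %in% names(conserved))
    conserved$mean_delta else conserved$delta
  out <- data.frame(gene_id = genes$gene_id[hits$gene],
                    dmr_index = hits$dmr,
                    placement = hits$placement,
                    context = conserved$context[hits$dmr],
                    delta = delta_col[hits$dmr],
                    width = conserved$end[hits$dmr] -
                      conserved$start[hits$dmr],
                    group = if ("group" %in% names(conserved))
                      conserved$group[hits$dmr] else NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Aggregate per-gene methylation change over linked DMRs
#'
#' A gene linked to several DMRs receives the length-weighted mean of
#' their deltas, computed per context and then averaged across the
#' contexts present (so a context with many small DMRs is not
#' over-weighted against one with a single large DMR). A gene with one
#' linked DMR returns that DMR's delta exactly. With
#' `method = "strongest"`, the delta with the largest absolute value is
#' used instead.
#'
#' @param links Link table from [associate_dmrs_to_genes()].
#' @param method `"length_weighted"` (default) or `"strongest"`.
#' @return Data frame with `gene_id`, `delta_meth`, `n_dmrs`,
#'   `n_contexts`.
#' @export
gene_delta_meth <- function(links, method = c("length_weighted",
                                              "strongest")) {
  method <- match.arg(method)
  if (nrow(links) == 0L)
    return(data.frame(gene_id = character(), delta_meth = numeric(),
                      n_dmrs = integer(), n_contexts = integer(),
                      stringsAsFactors = FALSE))
  split_idx <- split(seq_len(nrow(links)), links$gene_id)
  rows <- lapply(names(split_idx), function(gid) {
    l <- links[split_idx[[gid]], , drop = FALSE]
    if (method == "strongest") {
      dm <- l$delta[which.max(abs(l$delta))]
    } else {
      per_ctx <- vapply(unique(l$context), function(cx) {
        lc <- l[l$context == cx, , drop = FALSE]
        sum(lc$delta * lc$width) / sum(lc$width)
      }, numeric(1))
      dm <- mean(per_ctx)
    }
    data.frame(gene_id = gid, delta_meth = dm, n_dmrs = nrow(l),
               n_contexts = length(unique(l$context)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Methylation-expression negative-regulation screen
#'
#' Keeps genes present in both the DMR-link table and the DEG table
#' whose aggregated methylation change and expression change have
#' opposite signs, with `|delta_meth|` strictly greater than
#' `min_delta`. The output is by construction a subset of the
#' intersection of DMR-associated genes and DEGs.
#'
#' @param gene_deltas Output of [gene_delta_meth()].
#' @param degs DEG table with `gene_id`, `log2fc` (and optionally
#'   `padj`).
#' @param min_delta Methylation-difference threshold (fraction).
#' @return Candidate data frame: `gene_id`, `delta_meth`, `log2fc`,
#'   `n_dmrs`, `padj` (if available).
#' @export
negative_regulation_screen <- function(gene_deltas, degs,
                                       min_delta = 0.05) {
  m <- merge(gene_deltas, degs[, intersect(names(degs),
                                           c("gene_id", "log2fc", "padj"))],
             by = "gene_id")
  keep <- abs(m$delta_meth) > min_delta & m$log2fc != 0 &
    sign(m$delta_meth) != sign(m$log2fc)
  out <- m[keep, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between methylation and expression changes
#'
#' Per group of candidate genes, the Pearson r between `delta_meth`
#' and `log2fc` and the number of pairs. Fewer than three pairs or a
#' degenerate (constant) variable yields a no-data `NA` rather than an
#' error.
#'
#' @param candidates Candidate data frame with `delta_meth`, `log2fc`
#'   and a `group` column.
#' @return Data frame with `group`, `r`, `n`.
#' @export
correlation_summary <- function(candidates) {
  groups <- unique(candidates$group)
  rows <- lapply(groups, function(g) {
    d <- candidates[candidates$group == g, , drop = FALSE]
    r <- if (nrow(d) < 3L || stats::sd(d$delta_meth) == 0 ||
             stats::sd(d$log2fc) == 0) NA_real_
         else stats::cor(d$delta_meth, d$log2fc)
    data.frame(group = g, r = r, n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate-gene priority score
#'
#' The weighted linear combination used to rank negative-regulation
#' candidates:
#' `|log2FC| * 1 + |delta_meth| * 5 + phenotype_coverage * 10 +
#'  data_completeness * 5 + log(dmr_count) * 2`.
#' The logarithm is natural by default; the base is exposed because the
#' formula's "log" is otherwise unqualified.
#'
#' @param expr_mag Absolute log2 fold change.
#' @param meth_mag Absolute methylation difference (fraction scale).
#' @param phenotype_coverage Number of phenotype groups (1 or 2) in
#'   which the gene passes the screen.
#' @param data_completeness Fraction in `[0, 1]` of samples with usable
#'   methylation and expression data for the gene.
#' @param dmr_count Number of linked DMRs (>= 1).
#' @param base Logarithm base.
#' @return Numeric score (vectorised over its arguments).
#' @export
priority_score <- function(expr_mag, meth_mag, phenotype_coverage,
                           data_completeness, dmr_count,
                           base = exp(1)) {
  if (any(dmr_count < 1))
    stop_fmt("dmr_count must be >= 1")
  if (any(c(expr_mag, meth_mag, phenotype_coverage,
            data_completeness) < 0))
    stop_fmt("priority-score components must be non-negative")
  expr_mag * 1 + meth_mag * 5 + phenotype_coverage * 10 +
    data_completeness * 5 + log(dmr_count, base = base) * 2
}

#' Rank candidate genes by priority score
#'
#' Descending by `priority_score`, ties broken by lexicographic
#' `gene_id`; the first `top_k` rows are returned.
#'
#' @param candidates Data frame with `gene_id` and `priority_score`.
#' @param top_k Number of genes to return.
#' @return Reordered head of `candidates`.
#' @export
rank_candidates <- function(candidates, top_k = 15L) {
  o <- order(-candidates$priority_score, candidates$gene_id)
  out <- candidates[utils::head(o, top_k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-set Venn partition of candidate genes
#'
#' @param sensitive,tolerant Character vectors of gene ids (or data
#'   frames with a `gene_id` column).
#' @return List with `specific_sensitive`, `specific_tolerant`,
#'   `common`, `total` (= sum of the three partitions).
#' @export
venn_partition <- function(sensitive, tolerant) {
  s <- unique(if (is.data.frame(sensitive)) sensitive$gene_id else sensitive)
  t <- unique(if (is.data.frame(tolerant)) tolerant$gene_id else tolerant)
  common <- length(intersect(s, t))
  list(specific_sensitive = length(s) - common,
       specific_tolerant = length(t) - common,
       common = common,
       total = length(union(s, t)))
}

#' Hub genes: candidates inside core pathways
#'
#' Intersects the candidate genes with the genes belonging to the core
#' pathways (terms enriched in all four datasets). Each hub gene is
#' reported with its core pathways and group membership.
#'
#' @param candidates Candidate data frame with `gene_id` and optional
#'   `group`.
#' @param core_terms Character vector of core pathway term ids.
#' @param term_map Gene-to-term map.
#' @return Data frame with `gene_id`, `groups`, `pathways`.
#' @export
hub_genes <- function(candidates, core_terms, term_map) {
  if (length(core_terms) == 0L) {
    warning("empty core pathway set: no hub genes possible")
    return(data.frame(gene_id = character(), groups = character(),
                      pathways = character(), stringsAsFactors = FALSE))
  }
  core_map <- term_map[term_map$term_id %in% core_terms, , drop = FALSE]
  ids <- sort(intersect(unique(candidates$gene_id),
                        unique(core_map$gene_id)))
  rows <- lapply(ids, function(g) {
    grp <- if ("group" %in% names(candidates))
      paste(sort(unique(candidates$group[candidates$gene_id == g])),
            collapse = ",") else NA_character_
    data.frame(gene_id = g, groups = grp,
               pathways = paste(sort(unique(
                 core_map$term_id[core_map$gene_id == g])),
                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), groups = character(),
                      pathways = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Genome-wide methylation-expression pattern scan
#'
#' Labels every gene with both measurements as `negative` (opposite
#' signs, both passing their thresholds), `positive` (same signs, both
#' passing) or `other`, and reports the R-squared of the pooled linear
#' fit of expression change on methylation change.
#'
#' @param gene_deltas Output of [gene_delta_meth()].
#' @param de_table DE table with `gene_id`, `log2fc`, `padj`.
#' @param min_delta Methylation-difference threshold.
#' @param padj_max Expression significance threshold.
#' @return List with `labels` (data frame `gene_id`, `delta_meth`,
#'   `log2fc`, `pattern`) and `r_squared`.
#' @export
genomewide_meth_expr_scan <- function(gene_deltas, de_table,
                                      min_delta = 0.05,
                                      padj_max = 0.05) {
  m <- merge(gene_deltas, de_table[, c("gene_id", "log2fc", "padj")],
             by = "gene_id")
  pass <- abs(m$delta_meth) > min_delta & m$padj < padj_max &
    m$log2fc != 0
  opp <- sign(m$delta_meth) != sign(m$log2fc)
  pattern <- rep("other", nrow(m))
  pattern[pass & opp] <- "negative"
  pattern[pass & !opp] <- "positive"
  r2 <- if (nrow(m) >= 3L && stats::sd(m$delta_meth) > 0 &&
            stats::sd(m$log2fc) > 0)
    summary(stats::lm(log2fc ~ delta_meth, data = m))$r.squared
  else NA_real_
  list(labels = data.frame(gene_id = m$gene_id,
                           delta_meth = m$delta_meth,
                           log2fc = m$log2fc, pattern = pattern,
                           stringsAsFactors = FALSE),
       r_squared = r2)
}
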