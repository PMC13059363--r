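#' Run the full methylome-transcriptome integration pipeline
#'
#' Executes every stage of the analysis on a simulated study: per
#' genotype DMR calling (control vs drought) and context-threshold
#' filtering; per-group merging into conserved DMRs with genotype
#' support filtering; low-count filtering, the stand-in DE test and DEG
#' thresholds per group; DEG set algebra; DMR-gene association and the
#' negative-regulation screen with priority scoring; four-way pathway
#' enrichment and hub-gene calling; and an evaluation of every stage
#' against the simulation's ground-truth manifest.
#'
#' @param sim Output of [simulate_study()], or a [simulation_config()]
#'   (which is then simulated first).
#' @param window,step,min_cytosines,alpha Candidate-DMR parameters
#'   (see [call_candidate_dmrs()]).
#' @param dmr_thresholds Context thresholds for [filter_significant()].
#' @param max_gap Merge gap for [merge_conserved()].
#' @param min_genotypes Genotype-support threshold.
#' @param padj_max,lfc_min DEG thresholds.
#' @param min_total Low-count filter threshold.
#' @param screen_min_delta Negative-regulation methylation threshold.
#' @param enrich_alpha Enrichment significance threshold.
#' @param top_k Number of top-priority candidates to report.
#' @return An object of class `drought_study`.
#' @export
run_drought_study <- function(sim,
                              window = 200L, step = 50L,
                              min_cytosines = 4L, alpha = 0.05,
                              dmr_thresholds = DMR_THRESHOLDS,
                              max_gap = 100L, min_genotypes = 3L,
                              padj_max = 0.05, lfc_min = 1.0,
                              min_total = 10L,
                              screen_min_delta = 0.05,
                              enrich_alpha = 0.01, top_k = 15L) {
  if (inherits(sim, "sim_config")) sim <- simulate_study(sim)
  samples <- sim$samples
  groups <- c("tolerant", "sensitive")

  ## --- DMR stage -----------------------------------------------------
  genotypes <- unique(samples$genotype_id)
  sig_dmrs <- list()
  for (g in genotypes) {
    grp <- samples$group[match(g, samples$genotype_id)]
    ctrl_ids <- samples$sample_id[samples$genotype_id == g &
                                    samples$treatment == "control"]
    drt_ids <- samples$sample_id[samples$genotype_id == g &
                                   samples$treatment == "drought"]
    ctrl <- pool_cx(sim$cx[ctrl_ids])
    drt <- pool_cx(sim$cx[drt_ids])
    cand <- call_candidate_dmrs(ctrl, drt, window = window, step = step,
                                min_cytosines = min_cytosines,
                                alpha = alpha, genotype_id = g,
                                group = grp)
    sig_dmrs[[g]] <- filter_significant(cand, dmr_thresholds)
  }
  sig_dmrs <- do.call(rbind, sig_dmrs)
  if (is.null(sig_dmrs)) sig_dmrs <- empty_dmrs()
  rownames(sig_dmrs) <- NULL

  conserved <- list(); supported <- list()
  for (grp in groups) {
    d <- sig_dmrs[sig_dmrs$group == grp, , drop = FALSE]
    conserved[[grp]] <- merge_conserved(d, max_gap = max_gap)
    supported[[grp]] <- support_filter(conserved[[grp]],
                                       min_genotypes = min_genotypes)
  }

  ## --- expression stage ------------------------------------------------
  counts <- filter_low_counts(sim$counts, min_total = min_total)
  de <- list(); degs <- list()
  for (grp in groups) {
    de[[grp]] <- standin_de_test(counts, samples, grp)
    degs[[grp]] <- filter_degs(de[[grp]], padj_max = padj_max,
                               lfc_min = lfc_min)
  }
  set_algebra <- if (nrow(degs$tolerant) > 0L)
    deg_set_algebra(degs$sensitive, degs$tolerant) else NULL

  ## --- integration stage -----------------------------------------------
  links <- list(); gene_deltas <- list(); candidates <- list()
  for (grp in groups) {
    links[[grp]] <- associate_dmrs_to_genes(supported[[grp]], sim$genes)
    gene_deltas[[grp]] <- gene_delta_meth(links[[grp]])
    cand <- negative_regulation_screen(gene_deltas[[grp]], degs[[grp]],
                                       min_delta = screen_min_delta)
    if (nrow(cand) > 0L) cand$group <- grp
    candidates[[grp]] <- cand
  }
  all_cand <- merge_candidate_groups(candidates, sim, counts)
  if (nrow(all_cand) > 0L) {
    all_cand$priority_score <- priority_score(
      abs(all_cand$log2fc), abs(all_cand$delta_meth),
      all_cand$phenotype_coverage, all_cand$data_completeness,
      all_cand$n_dmrs)
    top <- rank_candidates(all_cand, top_k = top_k)
  } else top <- all_cand
  venn <- venn_partition(candidates$sensitive, candidates$tolerant)
  nonempty <- candidates[vapply(candidates, nrow, 1L) > 0]
  cors <- if (length(nonempty) > 0L)
    correlation_summary(do.call(rbind, nonempty))
  else data.frame(group = character(), r = numeric(), n = integer())

  ## --- enrichment stage ---------------------------------------------
  universe <- rownames(counts)
  term_map <- sim$term_map
  enr <- list()
  enriched_sets <- list()
  for (grp in groups) {
    dmr_genes <- intersect(unique(links[[grp]]$gene_id), universe)
    deg_genes <- intersect(degs[[grp]]$gene_id, universe)
    e_dmr <- hypergeom_enrich(dmr_genes, universe, term_map,
                              alpha = enrich_alpha)
    e_deg <- hypergeom_enrich(deg_genes, universe, term_map,
                              alpha = enrich_alpha)
    enr[[paste0(grp, "_dmr")]] <- e_dmr
    enr[[paste0(grp, "_deg")]] <- e_deg
    enriched_sets[[paste0(grp, "_dmr")]] <-
      e_dmr$term_id[e_dmr$significant]
    enriched_sets[[paste0(grp, "_deg")]] <-
      e_deg$term_id[e_deg$significant]
  }
  intersections <- pathway_intersections(enriched_sets)
  hubs <- if (length(intersections$core) > 0L && nrow(all_cand) > 0L)
    hub_genes(all_cand, intersections$core, term_map)
  else data.frame(gene_id = character(), groups = character(),
                  pathways = character(), stringsAsFactors = FALSE)

  res <- list(sim = sim,
              significant_dmrs = sig_dmrs,
              conserved = conserved, supported = supported,
              common_dmrs = common_dmrs(supported$tolerant,
                                        supported$sensitive),
              de = de, degs = degs, deg_set_algebra = set_algebra,
              links = links, gene_deltas = gene_deltas,
              candidates = candidates, all_candidates = all_cand,
              top_candidates = top, venn = venn, correlations = cors,
              enrichment = enr, intersections = intersections,
              hub_genes = hubs,
              params = list(window = window, step = step,
                            min_cytosines = min_cytosines, alpha = alpha,
                            dmr_thresholds = dmr_thresholds,
                            max_gap = max_gap,
                            min_genotypes = min_genotypes,
                            padj_max = padj_max, lfc_min = lfc_min,
                            min_total = min_total,
                            screen_min_delta = screen_min_delta,
                            enrich_alpha = enrich_alpha))
  res$evaluation <- evaluate_against_truth(res)
  class(res) <- "drought_study"
  res
}

## combine per-group candidates into one table with phenotype coverage
## and data completeness
merge_candidate_groups <- function(candidates, sim, counts) {
  nonempty <- candidates[vapply(candidates, nrow, 1L) > 0]
  if (length(nonempty) == 0L)
    return(data.frame(gene_id = character(), delta_meth = numeric(),
                      log2fc = numeric(), n_dmrs = integer(),
                      phenotype_coverage = integer(),
                      data_completeness = numeric(),
                      groups = character(), stringsAsFactors = FALSE))
  comb <- do.call(rbind, nonempty)
  ids <- unique(comb$gene_id)
  rows <- lapply(ids, function(gid) {
    d <- comb[comb$gene_id == gid, , drop = FALSE]
    grps <- sort(unique(d$group))
    data.frame(gene_id = gid,
               delta_meth = stats::weighted.mean(d$delta_meth, d$n_dmrs),
               log2fc = mean(d$log2fc),
               n_dmrs = max(d$n_dmrs),
               phenotype_coverage = length(grps),
               data_completeness = data_completeness_of(gid, grps, sim,
                                                        counts),
               groups = paste(grps, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## fraction of the gene's group samples with >=1 covered cytosine in
## the gene's extended region and a nonzero expression count
data_completeness_of <- function(gene_id, grps, sim, counts) {
  g <- sim$genes[sim$genes$gene_id == gene_id, ]
  if (nrow(g) == 0L) return(1)
  ids <- sim$samples$sample_id[sim$samples$group %in% grps]
  ok <- vapply(ids, function(s) {
    cxr <- sim$cx[[s]]
    has_meth <- any(cxr$chrom == g$chrom & cxr$n_total > 0L &
                      (cxr$pos - 1L) >= (g$start - 2000L) &
                      (cxr$pos - 1L) < (g$end + 2000L))
    has_expr <- gene_id %in% rownames(counts) &&
      counts[gene_id, s] > 0L
    has_meth && has_expr
  }, logical(1))
  mean(ok)
}

#' Evaluate pipeline output against the simulation truth
#'
#' Computes planted-DMR recovery (sensitivity and false discovery rate
#' of support-filtered conserved DMRs against planted regions of the
#' same group and context, >= 1 bp overlap), planted-DEG sensitivity,
#' and negative-regulation recovery (fraction of planted genes that
#' pass the screen in their group).
#'
#' @param res A `drought_study` object (or the list being built).
#' @return List of metrics.
#' @export
evaluate_against_truth <- function(res) {
  truth <- res$sim$truth
  planted <- truth$planted_dmrs
  n_called <- 0L; n_true <- 0L; n_recovered <- 0L
  for (grp in c("tolerant", "sensitive")) {
    called <- res$supported[[grp]]
    pl <- planted[planted$group == grp, , drop = FALSE]
    n_true <- n_true + nrow(pl)
    if (nrow(called) > 0L) n_called <- n_called + nrow(called)
    if (nrow(pl) == 0L || nrow(called) == 0L) next
    gr_c <- GenomicRanges::GRanges(
      paste(called$chrom, called$context),
      IRanges::IRanges(called$start + 1L, called$end))
    gr_p <- GenomicRanges::GRanges(
      paste(pl$chrom, pl$context),
      IRanges::IRanges(pl$start + 1L, pl$end))
    ov <- GenomicRanges::findOverlaps(gr_p, gr_c)
    n_recovered <- n_recovered + length(unique(S4Vectors::queryHits(ov)))
  }
  ## false calls: called regions not overlapping any planted region of
  ## their group (any context? matched context, consistent with above)
  n_false <- 0L
  for (grp in c("tolerant", "sensitive")) {
    called <- res$supported[[grp]]
    if (nrow(called) == 0L) next
    pl <- planted[planted$group == grp, , drop = FALSE]
    if (nrow(pl) == 0L) { n_false <- n_false + nrow(called); next }
    gr_c <- GenomicRanges::GRanges(
      paste(called$chrom, called$context),
      IRanges::IRanges(called$start + 1L, called$end))
    gr_p <- GenomicRanges::GRanges(
      paste(pl$chrom, pl$context),
      IRanges::IRanges(pl$start + 1L, pl$end))
    ov <- GenomicRanges::findOverlaps(gr_c, gr_p)
    n_false <- n_false + sum(!seq_len(nrow(called)) %in%
                               S4Vectors::queryHits(ov))
  }
  dmr_sensitivity <- if (n_true > 0L) n_recovered / n_true else NA_real_
  dmr_fdr <- if (n_called > 0L) n_false / n_called else NA_real_

  pd <- truth$planted_degs
  deg_hits <- 0L
  if (nrow(pd) > 0L) {
    for (grp in unique(pd$group)) {
      want <- pd$gene_id[pd$group == grp]
      got <- res$degs[[grp]]$gene_id
      deg_hits <- deg_hits + sum(want %in% got)
    }
  }
  deg_sensitivity <- if (nrow(pd) > 0L) deg_hits / nrow(pd) else NA_real_

  nr <- truth$negreg
  nr_hits <- 0L
  if (!is.null(nr) && nrow(nr) > 0L) {
    for (grp in unique(nr$group)) {
      want <- nr$gene_id[nr$group == grp]
      got <- res$candidates[[grp]]$gene_id
      nr_hits <- nr_hits + sum(want %in% got)
    }
  }
  negreg_recovery <- if (!is.null(nr) && nrow(nr) > 0L)
    nr_hits / nrow(nr) else NA_real_

  list(dmr_sensitivity = dmr_sensitivity, dmr_fdr = dmr_fdr,
       dmr_called = n_called, dmr_planted = n_true,
       deg_sensitivity = deg_sensitivity,
       negreg_recovery = negreg_recovery)
}

#' @export
print.drought_study <- function(x, ...) {
  cat("Methylome-transcriptome integration study\n")
  cat(sprintf("  genotypes: %d per group; samples: %d\n",
              x$sim$config$n_genotypes_per_group, nrow(x$sim$samples)))
  cat(sprintf("  significant DMRs: %d (tolerant %d / sensitive %d)\n",
              nrow(x$significant_dmrs),
              sum(x$significant_dmrs$group == "tolerant"),
              sum(x$significant_dmrs$group == "sensitive")))
  cat(sprintf("  conserved DMRs (support >= %d): tolerant %d, sensitive %d\n",
              x$params$min_genotypes, nrow(x$supported$tolerant),
              nrow(x$supported$sensitive)))
  cat(sprintf("  DEGs: tolerant %d, sensitive %d\n",
              nrow(x$degs$tolerant), nrow(x$degs$sensitive)))
  cat(sprintf("  negative-regulation candidates: %d (S %d / T %d / common %d)\n",
              x$venn$total, x$venn$specific_sensitive,
              x$venn$specific_tolerant, x$venn$common))
  cat(sprintf("  core pathways: %d; hub genes: %d\n",
              length(x$intersections$core), nrow(x$hub_genes)))
  ev <- x$evaluation
  if (!is.na(ev$dmr_sensitivity))
    cat(sprintf("  planted-DMR recovery: sensitivity %.2f, FDR %.2f\n",
                ev$dmr_sensitivity, ev$dmr_fdr))
  if (!is.na(ev$negreg_recovery))
    cat(sprintf("  negative-regulation recovery: %.2f\n",
                ev$negreg_recovery))
  invisible(x)
}

#' @export
summary.drought_study <- function(object, ...) {
  print(object, ...)
  cat("\nTop priority candidates:\n")
  print(utils::head(object$top_candidates[, c("gene_id", "groups",
                                              "delta_meth", "log2fc",
                                              "priority_score")], 15L))
  invisible(object)
}
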