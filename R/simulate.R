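#' Build and validate a simulation configuration
#'
#' Defines a desk-scale study emulating a two-group drought-contrast
#' design: `n_genotypes_per_group` genotypes per phenotype group
#' (tolerant / sensitive), each profiled under control and drought.
#' Per-cytosine methylation is drawn binomially around context-specific
#' baselines (defaults from a *B. napus* control methylome: CG 92.31%,
#' CHG 46.76%, CHH 32.16%), with a per-site Beta-distributed latent
#' level shared across treatments within a genotype so that
#' control-vs-drought comparisons are null wherever no effect is
#' planted. Planted DMRs shift the latent level of drought samples of
#' one group; planted DEGs multiply negative-binomial count means; and
#' negative-regulation genes receive an upstream-flank methylation shift
#' paired with an opposite-sign expression shift.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_chrom_A,n_chrom_C Number of A- and C-subgenome chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of gene models.
#' @param n_genotypes_per_group Genotypes per phenotype group.
#' @param n_replicates Replicates per genotype and treatment.
#' @param baseline_meth Named per-context baseline methylation fractions.
#' @param context_weights Named per-context cytosine-site proportions.
#' @param site_density Cytosine sites per bp.
#' @param coverage_mean Mean sequencing reads per cytosine (Poisson).
#' @param site_concentration Beta concentration of per-site latent
#'   levels around the context baseline (smaller = more site
#'   heterogeneity).
#' @param genotype_concentration Beta concentration of per-genotype
#'   jitter around the site level; large values keep
#'   control-vs-control differences well below DMR thresholds.
#' @param planted_dmr_spec Data frame with columns `context`, `delta`
#'   (signed fraction), `width` (bp), `count`, `group`.
#' @param planted_deg_spec Data frame with columns `log2fc`, `count`,
#'   `group`.
#' @param n_negreg_genes Negative-regulation genes planted per group.
#' @param negreg_hyper_delta,negreg_hypo_delta Methylation shifts used
#'   for the hyper-CHH (paired with down-regulation) and hypo-CHG
#'   (paired with up-regulation) halves of the negative-regulation
#'   planting.
#' @param negreg_lfc_range Range of |log2FC| for negative-regulation
#'   genes.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param library_size_range Range of relative library size factors.
#' @param mean_log_expression,sd_log_expression Log-normal parameters of
#'   gene base means.
#' @param frac_silent Fraction of genes with zero expression.
#' @param c_subgenome_weight Probability that a planted DMR is placed on
#'   a C-subgenome chromosome (epigenetic remodelling in *B. napus* is
#'   C-biased).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom_A = 2L, n_chrom_C = 2L,
                              chrom_length = 250000L,
                              n_genes = 200L,
                              n_genotypes_per_group = 6L,
                              n_replicates = 1L,
                              baseline_meth = c(CG = 0.9231, CHG = 0.4676,
                                                CHH = 0.3216),
                              context_weights = c(CG = 0.15, CHG = 0.20,
                                                  CHH = 0.65),
                              site_density = 0.25,
                              coverage_mean = 30,
                              site_concentration = 60,
                              genotype_concentration = 200,
                              planted_dmr_spec = default_dmr_spec(),
                              planted_deg_spec = default_deg_spec(),
                              n_negreg_genes = 10L,
                              negreg_hyper_delta = 0.35,
                              negreg_hypo_delta = -0.30,
                              negreg_lfc_range = c(1.5, 3),
                              nb_dispersion = 0.05,
                              library_size_range = c(0.8, 1.2),
                              mean_log_expression = log(100),
                              sd_log_expression = 1,
                              frac_silent = 0.10,
                              c_subgenome_weight = 0.67) {
  cfg <- list(seed = as.integer(seed), n_chrom_A = as.integer(n_chrom_A),
              n_chrom_C = as.integer(n_chrom_C),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_genotypes_per_group = as.integer(n_genotypes_per_group),
              n_replicates = as.integer(n_replicates),
              baseline_meth = baseline_meth,
              context_weights = context_weights,
              site_density = site_density, coverage_mean = coverage_mean,
              site_concentration = site_concentration,
              genotype_concentration = genotype_concentration,
              planted_dmr_spec = planted_dmr_spec,
              planted_deg_spec = planted_deg_spec,
              n_negreg_genes = as.integer(n_negreg_genes),
              negreg_hyper_delta = negreg_hyper_delta,
              negreg_hypo_delta = negreg_hypo_delta,
              negreg_lfc_range = negreg_lfc_range,
              nb_dispersion = nb_dispersion,
              library_size_range = library_size_range,
              mean_log_expression = mean_log_expression,
              sd_log_expression = sd_log_expression,
              frac_silent = frac_silent,
              c_subgenome_weight = c_subgenome_weight,
              gene_pitch = 3500L)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

default_dmr_spec <- function() {
  rbind(
    data.frame(context = c("CHH", "CHH", "CHG", "CG"),
               delta = c(0.40, -0.28, 0.30, -0.30),
               width = 400L, count = c(6L, 2L, 2L, 2L),
               group = "sensitive", stringsAsFactors = FALSE),
    data.frame(context = c("CHH", "CHH", "CHG", "CHG", "CG"),
               delta = c(0.40, -0.28, 0.30, -0.30, -0.30),
               width = 400L, count = c(3L, 3L, 1L, 1L, 2L),
               group = "tolerant", stringsAsFactors = FALSE))
}

default_deg_spec <- function() {
  data.frame(log2fc = c(2, -2, 2, -2), count = c(8L, 8L, 5L, 3L),
             group = c("sensitive", "sensitive", "tolerant", "tolerant"),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  if (!setequal(names(cfg$baseline_meth), CONTEXTS))
    stop_fmt("baseline_meth must be named CG, CHG, CHH")
  if (any(cfg$baseline_meth < 0 | cfg$baseline_meth > 1))
    stop_fmt("baseline_meth fractions must be in [0,1]")
  if (any(cfg$context_weights < 0) ||
      abs(sum(cfg$context_weights) - 1) > 1e-8)
    stop_fmt("context_weights must be non-negative and sum to 1")
  spec <- cfg$planted_dmr_spec
  if (nrow(spec) > 0) {
    if (any(!spec$context %in% CONTEXTS))
      stop_fmt("planted_dmr_spec: unknown context")
    if (any(!spec$group %in% c("tolerant", "sensitive")))
      stop_fmt("planted_dmr_spec: unknown group")
    shifted <- cfg$baseline_meth[spec$context] + spec$delta
    if (any(shifted < 0 | shifted > 1))
      stop_fmt("planted_dmr_spec: baseline + delta outside [0,1] for context %s",
               spec$context[which(shifted < 0 | shifted > 1)[1L]])
    if (any(spec$width >= cfg$chrom_length))
      stop_fmt("planted_dmr_spec: region wider than chromosome")
  }
  if (cfg$n_negreg_genes > 0) {
    if (cfg$baseline_meth[["CHH"]] + cfg$negreg_hyper_delta > 1 ||
        cfg$baseline_meth[["CHG"]] + cfg$negreg_hypo_delta < 0)
      stop_fmt("negative-regulation deltas push levels outside [0,1]")
  }
  n_chrom <- cfg$n_chrom_A + cfg$n_chrom_C
  if (n_chrom < 1L) stop_fmt("need at least one chromosome")
  slots <- floor(0.7 * cfg$chrom_length / cfg$gene_pitch)
  if (n_chrom * slots < cfg$n_genes)
    stop_fmt("gene capacity %d < n_genes %d; lengthen or add chromosomes",
             n_chrom * slots, cfg$n_genes)
  n_special <- 2L * cfg$n_negreg_genes + sum(cfg$planted_deg_spec$count)
  if (n_special > floor(cfg$n_genes * (1 - cfg$frac_silent)))
    stop_fmt("not enough expressed genes for planted DEG/negative-regulation spec")
  invisible(cfg)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a complete drought-contrast study
#'
#' Generates gene annotation, per-sample CX reports, a count matrix,
#' a sample sheet, a gene-to-term map and a ground-truth manifest, all
#' consistent with the design in `config`. Outputs are deterministic
#' functions of `config$seed`. If `dir` is given, every table is also
#' written through the package's own writers (so the files round-trip
#' through the package's readers); all validation happens before any
#' file is written.
#'
#' @param config A [simulation_config()] object.
#' @param dir Optional output directory.
#' @return List with `genes`, `cx` (named list of cytosine-record data
#'   frames, one per sample), `counts`, `samples`, `term_map`,
#'   `chrom_lengths` and `truth` (the manifest of planted effects).
#' @export
simulate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  chroms <- c(if (config$n_chrom_A > 0) sprintf("A%02d", seq_len(config$n_chrom_A)),
              if (config$n_chrom_C > 0) sprintf("C%02d", seq_len(config$n_chrom_C)))
  L <- config$chrom_length
  chrom_lengths <- stats::setNames(rep(L, length(chroms)), chroms)

  ## --- sample sheet -------------------------------------------------
  ng <- config$n_genotypes_per_group
  genotypes <- c(sprintf("T%02d", seq_len(ng)), sprintf("S%02d", seq_len(ng)))
  groups <- rep(c("tolerant", "sensitive"), each = ng)
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         treatment = c("control", "drought"),
                         genotype_id = genotypes,
                         stringsAsFactors = FALSE)
  samples$group <- groups[match(samples$genotype_id, genotypes)]
  samples$sample_id <- paste(samples$genotype_id, samples$treatment,
                             sprintf("R%d", samples$replicate), sep = "_")
  samples <- samples[, c("sample_id", "genotype_id", "group", "treatment",
                         "replicate")]

  ## --- gene models ---------------------------------------------------
  pitch <- config$gene_pitch
  slots_per_chrom <- floor(0.7 * L / pitch)
  slot_chrom <- rep(chroms, each = slots_per_chrom)
  slot_start <- rep((seq_len(slots_per_chrom) - 1L) * pitch, length(chroms))
  take <- seq_len(config$n_genes)
  ## round-robin over chromosomes so both subgenomes carry genes
  ord <- order(rep(seq_len(slots_per_chrom), length(chroms)))
  slot_chrom <- slot_chrom[ord][take]
  slot_start <- slot_start[ord][take]
  width <- floor(stats::runif(config$n_genes, 800, 1400))
  gstart <- slot_start + 2100L
  genes <- data.frame(gene_id = sprintf("gene%04d", take),
                      chrom = slot_chrom, start = gstart,
                      end = gstart + width,
                      strand = sample(c("+", "-"), config$n_genes,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  genes$subgenome <- subgenome_of(genes$chrom)

  ## --- cytosine sites ------------------------------------------------
  n_sites_chr <- round(L * config$site_density)
  site_list <- lapply(chroms, function(ch) {
    data.frame(chrom = ch, pos = sort(sample.int(L, n_sites_chr)),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  sites$context <- sample(CONTEXTS, nrow(sites), replace = TRUE,
                          prob = config$context_weights[CONTEXTS])
  sites$strand <- sample(c("+", "-"), nrow(sites), replace = TRUE)
  base <- config$baseline_meth[sites$context]
  cs <- config$site_concentration
  p_site <- stats::rbeta(nrow(sites), base * cs, (1 - base) * cs)
  ## degenerate Beta draws at the boundary are possible for extreme
  ## baselines; keep levels in the open interval for the genotype layer
  p_site <- pmin(1 - 1e-6, pmax(1e-6, p_site))
  cg <- config$genotype_concentration
  p_geno <- vapply(genotypes, function(g)
    stats::rbeta(nrow(sites), p_site * cg, (1 - p_site) * cg),
    numeric(nrow(sites)))

  ## --- expression baselines -------------------------------------------
  base_mean <- stats::rlnorm(config$n_genes, config$mean_log_expression,
                             config$sd_log_expression)
  silent <- sample.int(config$n_genes, round(config$frac_silent * config$n_genes))
  base_mean[silent] <- 0
  expressed <- setdiff(seq_len(config$n_genes), silent)

  ## --- choose negative-regulation and DEG genes -----------------------
  pool <- sample(expressed)   # randomised, seed-deterministic
  nn <- config$n_negreg_genes
  negreg_idx <- list(sensitive = pool[seq_len(nn)],
                     tolerant = pool[nn + seq_len(nn)])
  if (nn > 0L) pool <- pool[-seq_len(2L * nn)]
  deg_spec <- config$planted_deg_spec
  deg_rows <- list()
  for (i in seq_len(nrow(deg_spec))) {
    if (deg_spec$count[i] == 0L) next
    idx <- pool[seq_len(deg_spec$count[i])]
    pool <- pool[-seq_len(deg_spec$count[i])]
    deg_rows[[i]] <- data.frame(gene_id = genes$gene_id[idx],
                                log2fc = deg_spec$log2fc[i],
                                group = deg_spec$group[i],
                                kind = "deg", stringsAsFactors = FALSE)
  }
  planted_degs <- if (length(deg_rows)) do.call(rbind, deg_rows) else
    data.frame(gene_id = character(), log2fc = numeric(),
               group = character(), kind = character())

  ## --- negative-regulation planting ----------------------------------
  negreg <- list()
  for (grp in c("sensitive", "tolerant")) {
    idx <- negreg_idx[[grp]]
    if (length(idx) == 0L) next
    hyper <- seq_along(idx) <= ceiling(length(idx) / 2)
    d <- ifelse(hyper, config$negreg_hyper_delta, config$negreg_hypo_delta)
    ctx <- ifelse(hyper, "CHH", "CHG")
    mag <- stats::runif(length(idx), config$negreg_lfc_range[1L],
                        config$negreg_lfc_range[2L])
    lfc <- ifelse(hyper, -mag, mag)
    g <- genes[idx, ]
    ustart <- ifelse(g$strand == "+", g$start - 1800L, g$end + 1200L)
    negreg[[grp]] <- data.frame(gene_id = g$gene_id, group = grp,
                                chrom = g$chrom, start = ustart,
                                end = ustart + 600L, context = ctx,
                                delta = d, log2fc = lfc,
                                stringsAsFactors = FALSE)
  }
  negreg <- if (length(negreg)) do.call(rbind, negreg) else NULL

  ## --- place planted DMR regions -------------------------------------
  zone0 <- slots_per_chrom * pitch + 1000L
  cursor <- stats::setNames(rep(zone0, length(chroms)), chroms)
  a_chroms <- chroms[subgenome_of(chroms) == "A"]
  c_chroms <- chroms[subgenome_of(chroms) == "C"]
  dmr_rows <- list()
  spec <- config$planted_dmr_spec
  for (i in seq_len(nrow(spec))) {
    for (j in seq_len(spec$count[i])) {
      use_c <- length(c_chroms) > 0 &&
        (length(a_chroms) == 0 || stats::runif(1) < config$c_subgenome_weight)
      ch <- if (use_c) c_chroms[sample.int(length(c_chroms), 1L)]
            else a_chroms[sample.int(length(a_chroms), 1L)]
      s <- cursor[[ch]]
      e <- s + spec$width[i]
      if (e + 600L > L)
        stop_fmt("planted DMRs do not fit on chromosome %s; lengthen chrom_length", ch)
      cursor[[ch]] <- e + 600L
      dmr_rows[[length(dmr_rows) + 1L]] <-
        data.frame(chrom = ch, start = s, end = e,
                   context = spec$context[i], delta = spec$delta[i],
                   group = spec$group[i], kind = "dmr",
                   gene_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  planted_dmrs <- if (length(dmr_rows)) do.call(rbind, dmr_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               context = character(), delta = numeric(), group = character(),
               kind = character(), gene_id = character())
  if (!is.null(negreg)) {
    planted_dmrs <- rbind(planted_dmrs,
                          data.frame(chrom = negreg$chrom,
                                     start = negreg$start, end = negreg$end,
                                     context = negreg$context,
                                     delta = negreg$delta,
                                     group = negreg$group, kind = "negreg",
                                     gene_id = negreg$gene_id,
                                     stringsAsFactors = FALSE))
  }

  ## --- methylation counts per sample ----------------------------------
  geno_group <- stats::setNames(groups, genotypes)
  shift_idx <- lapply(c(tolerant = "tolerant", sensitive = "sensitive"),
                      function(grp) {
    pd <- planted_dmrs[planted_dmrs$group == grp, , drop = FALSE]
    if (nrow(pd) == 0L) return(list(idx = integer(), delta = numeric()))
    idx <- integer(); dd <- numeric()
    for (r in seq_len(nrow(pd))) {
      hit <- which(sites$chrom == pd$chrom[r] &
                   sites$context == pd$context[r] &
                   (sites$pos - 1L) >= pd$start[r] &
                   (sites$pos - 1L) < pd$end[r])
      idx <- c(idx, hit); dd <- c(dd, rep(pd$delta[r], length(hit)))
    }
    list(idx = idx, delta = dd)
  })

  cx <- vector("list", nrow(samples))
  names(cx) <- samples$sample_id
  for (k in seq_len(nrow(samples))) {
    geno <- samples$genotype_id[k]
    lev <- p_geno[, geno]
    if (samples$treatment[k] == "drought") {
      sh <- shift_idx[[geno_group[[geno]]]]
      if (length(sh$idx)) lev[sh$idx] <- clamp01(lev[sh$idx] + sh$delta)
    }
    n_total <- stats::rpois(nrow(sites), config$coverage_mean)
    n_meth <- stats::rbinom(nrow(sites), n_total, lev)
    cx[[k]] <- data.frame(chrom = sites$chrom, pos = sites$pos,
                          strand = sites$strand, context = sites$context,
                          n_meth = n_meth, n_total = n_total,
                          coverage_zero = n_total == 0L,
                          stringsAsFactors = FALSE)
  }

  ## --- expression counts ----------------------------------------------
  sf <- stats::runif(nrow(samples), config$library_size_range[1L],
                     config$library_size_range[2L])
  fc <- matrix(1, nrow = config$n_genes, ncol = nrow(samples),
               dimnames = list(genes$gene_id, samples$sample_id))
  plant_fc <- function(gene_ids, lfc, grp) {
    cols <- samples$treatment == "drought" & samples$group == grp
    fc[gene_ids, cols] <<- fc[gene_ids, cols] * 2^lfc
  }
  for (r in seq_len(nrow(planted_degs)))
    plant_fc(planted_degs$gene_id[r], planted_degs$log2fc[r],
             planted_degs$group[r])
  if (!is.null(negreg))
    for (r in seq_len(nrow(negreg)))
      plant_fc(negreg$gene_id[r], negreg$log2fc[r], negreg$group[r])
  mu <- outer(base_mean, sf) * fc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = config$n_genes,
                   dimnames = dimnames(fc))
  storage.mode(counts) <- "integer"

  ## --- term map --------------------------------------------------------
  ## background terms at random, plus a few shared stress pathways that
  ## collect the planted genes of both groups: the same pathways then
  ## respond at the methylation and the expression layer, giving the
  ## four-way intersection a genuine core
  n_terms <- 30L
  term_ids <- sprintf("T%03d", seq_len(n_terms))
  stress_terms <- term_ids[1:3]
  bg_terms <- term_ids[-(1:3)]
  k_terms <- sample(1:3, config$n_genes, replace = TRUE)
  term_map <- data.frame(
    gene_id = rep(genes$gene_id, k_terms),
    term_id = unlist(lapply(k_terms, function(k) sample(bg_terms, k))),
    stringsAsFactors = FALSE)
  planted_gene_ids <- unique(if (!is.null(negreg)) negreg$gene_id)
  if (length(planted_gene_ids) > 0L) {
    term_map <- rbind(term_map, data.frame(
      gene_id = rep(planted_gene_ids, each = length(stress_terms)),
      term_id = rep(stress_terms, length(planted_gene_ids)),
      stringsAsFactors = FALSE))
  }
  term_map <- term_map[!duplicated(term_map[, c("gene_id", "term_id")]), ]
  term_map <- term_map[order(term_map$gene_id, term_map$term_id), ]
  rownames(term_map) <- NULL
  term_map$term_name <- paste0("pathway_", sub("^T", "", term_map$term_id))

  truth <- list(planted_dmrs = planted_dmrs, planted_degs = planted_degs,
                negreg = if (is.null(negreg)) data.frame() else negreg,
                site_counts = table(sites$context),
                column_sums = colSums(counts),
                baseline_meth = config$baseline_meth)

  out <- list(config = config, genes = genes, cx = cx, counts = counts,
              samples = samples, term_map = term_map,
              chrom_lengths = chrom_lengths, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_gene_annotation(genes, file.path(dir, "annotation.gff3"), "gff3")
    cxd <- file.path(dir, "cx")
    if (!dir.exists(cxd)) dir.create(cxd)
    for (s in names(cx))
      write_cx_report(cx[[s]], file.path(cxd, paste0(s, ".cx.tsv")))
    write_count_matrix(counts, file.path(dir, "counts.tsv"))
    write_sample_sheet(samples, file.path(dir, "samples.tsv"))
    write_term_map(term_map, file.path(dir, "term_map.tsv"))
    write.table(planted_dmrs, file.path(dir, "truth_dmrs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(planted_degs, file.path(dir, "truth_degs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth$negreg, file.path(dir, "truth_negreg.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(deparse(unclass(config)), file.path(dir, "config.txt"))
  }
  out
}

#' Aboveground water content
#'
#' The drought-tolerance index used for phenotyping:
#' `WC1 = (fresh - dry) / fresh`.
#'
#' @param fresh_weight Fresh weight in g, must be positive.
#' @param dry_weight Dry weight in g, in `[0, fresh_weight]`.
#' @return Water-content fraction in `[0, 1]`.
#' @export
water_content <- function(fresh_weight, dry_weight) {
  if (any(fresh_weight <= 0))
    stop_fmt("fresh_weight must be positive")
  if (any(dry_weight < 0) || any(dry_weight > fresh_weight))
    stop_fmt("dry_weight must lie in [0, fresh_weight]")
  (fresh_weight - dry_weight) / fresh_weight
}

#' Pool cytosine records across samples
#'
#' Sums methylated and total read counts position-wise across a list of
#' cytosine-record data frames (for example technical replicates, or
#' all samples of a condition), keeping chromosome, strand and context
#' from the first occurrence of each site.
#'
#' @param cx_list List of cytosine-record data frames.
#' @return A single pooled cytosine-record data frame.
#' @export
pool_cx <- function(cx_list) {
  stopifnot(length(cx_list) >= 1L)
  if (length(cx_list) == 1L) return(cx_list[[1L]])
  all <- do.call(rbind, cx_list)
  key <- paste(all$chrom, all$pos, all$context, all$strand, sep = "\r")
  first <- !duplicated(key)
  base <- all[first, c("chrom", "pos", "strand", "context")]
  f <- factor(key, levels = key[first])
  base$n_meth <- as.integer(rowsum(all$n_meth, f)[, 1L])
  base$n_total <- as.integer(rowsum(all$n_total, f)[, 1L])
  base$coverage_zero <- base$n_total == 0L
  rownames(base) <- NULL
  base
}
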