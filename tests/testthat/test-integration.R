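test_that("DMR-gene links respect the 2-kb flank and TSS precedence", {
  genes <- toy_genes(c("gp", "gm"), "A01", c(10000, 30000),
                     c(12000, 31000), c("+", "-"))
  cons <- data.frame(chrom = "A01",
                     start = c(10500L,   # inside gp body
                               9900L,    # spans gp's TSS
                               8000L,    # just inside the 2-kb flank
                               7800L,    # >= 2001 bp upstream: out of range
                               31500L),  # within gm's upstream flank
                     end = c(10700L, 10100L, 8200L, 8000L, 31700L),
                     context = "CHH", mean_delta = 0.3, group = "sensitive",
                     stringsAsFactors = FALSE)
  links <- associate_dmrs_to_genes(cons, genes)
  expect_equal(links$placement[links$dmr_index == 1], "gene_body")
  expect_equal(links$placement[links$dmr_index == 2], "gene_body")
  expect_equal(links$placement[links$dmr_index == 3], "upstream2k")
  expect_false(4L %in% links$dmr_index)
  expect_equal(links$gene_id[links$dmr_index == 5], "gm")
  expect_equal(links$placement[links$dmr_index == 5], "upstream2k")
})

test_that("per-gene delta aggregation is a length-weighted per-context mean", {
  links <- data.frame(gene_id = "g1", dmr_index = 1:2,
                      placement = "gene_body", context = "CHH",
                      delta = c(0.2, 0.4), width = c(100L, 100L),
                      group = "sensitive", stringsAsFactors = FALSE)
  expect_equal(gene_delta_meth(links)$delta_meth, 0.3)
  # single DMR returns its delta exactly
  expect_equal(gene_delta_meth(links[1, ])$delta_meth, 0.2)
  # length weighting
  links$width <- c(300L, 100L)
  expect_equal(gene_delta_meth(links)$delta_meth,
               (0.2 * 300 + 0.4 * 100) / 400)
  # order invariance
  expect_equal(gene_delta_meth(links[2:1, ]), gene_delta_meth(links))
  # strongest-DMR mode
  expect_equal(gene_delta_meth(links, method = "strongest")$delta_meth,
               0.4)
})

test_that("contexts are averaged after within-context weighting", {
  links <- data.frame(gene_id = "g1", dmr_index = 1:3,
                      placement = "gene_body",
                      context = c("CHH", "CHH", "CG"),
                      delta = c(0.2, 0.4, -0.1), width = c(100L, 100L, 50L),
                      group = "sensitive", stringsAsFactors = FALSE)
  expect_equal(gene_delta_meth(links)$delta_meth, mean(c(0.3, -0.1)))
  expect_equal(gene_delta_meth(links)$n_dmrs, 3L)
  expect_equal(gene_delta_meth(links)$n_contexts, 2L)
})

test_that("the negative-regulation screen applies both the threshold and the sign rule", {
  gd <- data.frame(gene_id = c("a", "b", "c", "d"),
                   delta_meth = c(0.10, 0.04, 0.10, -0.10),
                   n_dmrs = 1L, n_contexts = 1L, stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = c("a", "b", "c", "d"),
                     log2fc = c(-1.5, -1.5, 1.5, 1.5),
                     padj = 0.01, stringsAsFactors = FALSE)
  out <- negative_regulation_screen(gd, degs)
  expect_equal(out$gene_id, c("a", "d"))   # b fails |delta|, c same sign
  # screen output is a subset of the intersection by construction
  expect_true(all(out$gene_id %in% intersect(gd$gene_id, degs$gene_id)))
})

test_that("correlation summary matches the direct formula and handles degeneracy", {
  cand <- data.frame(delta_meth = seq(0.1, 0.5, length.out = 5),
                     log2fc = -2 * seq(0.1, 0.5, length.out = 5),
                     group = "sensitive")
  cs <- correlation_summary(cand)
  expect_equal(cs$r, -1)
  expect_equal(cs$n, 5L)

  set.seed(10)
  cand2 <- data.frame(delta_meth = runif(25, -0.5, 0.5),
                      log2fc = rnorm(25), group = "tolerant")
  cs2 <- correlation_summary(cand2)
  expect_equal(cs2$r, cor(cand2$delta_meth, cand2$log2fc),
               tolerance = 1e-12)

  degen <- data.frame(delta_meth = rep(0.2, 4), log2fc = rnorm(4),
                      group = "x")
  expect_true(is.na(correlation_summary(degen)$r))
  expect_true(is.na(correlation_summary(cand[1:2, ])$r))
})

test_that("the priority score evaluates its weighted formula exactly", {
  expect_equal(priority_score(2.0, 0.30, 1, 1.0, 1), 18.5)
  expect_equal(priority_score(0, 0, 1, 0, 1), 10.0)
  # doubling the DMR count adds exactly 2*ln(2)
  base <- priority_score(1, 0.2, 1, 0.5, 3)
  expect_equal(priority_score(1, 0.2, 1, 0.5, 6) - base, 2 * log(2),
               tolerance = 1e-12)
  # base-10 logarithm option
  expect_equal(priority_score(0, 0, 1, 0, 10, base = 10), 12.0)
  expect_error(priority_score(1, 0.1, 1, 1, 0), "dmr_count")
})

test_that("the priority score is strictly increasing in every component", {
  set.seed(20)
  for (i in 1:20) {
    comp <- list(e = runif(1, 0, 3), m = runif(1, 0, 1),
                 pc = sample(1:2, 1), dc = runif(1), k = sample(1:5, 1))
    s0 <- priority_score(comp$e, comp$m, comp$pc, comp$dc, comp$k)
    expect_gt(priority_score(comp$e + 0.1, comp$m, comp$pc, comp$dc,
                             comp$k), s0)
    expect_gt(priority_score(comp$e, comp$m + 0.01, comp$pc, comp$dc,
                             comp$k), s0)
    expect_gt(priority_score(comp$e, comp$m, comp$pc + 1, comp$dc,
                             comp$k), s0)
    expect_gt(priority_score(comp$e, comp$m, comp$pc, comp$dc + 0.1,
                             comp$k), s0)
    expect_gt(priority_score(comp$e, comp$m, comp$pc, comp$dc,
                             comp$k + 1), s0)
  }
})

test_that("candidate ranking is score-descending with gene-id tie-break", {
  cand <- data.frame(gene_id = c("z", "a", "m", "b"),
                     priority_score = c(5, 7, 5, 9),
                     stringsAsFactors = FALSE)
  r <- rank_candidates(cand, top_k = 4)
  expect_equal(r$gene_id, c("b", "a", "m", "z"))
  expect_equal(rank_candidates(cand, top_k = 2)$gene_id, c("b", "a"))
  # brute-force comparison on random scores
  set.seed(40)
  cand2 <- data.frame(gene_id = sample(paste0("g", 1:50)),
                      priority_score = sample(rnorm(25), 50, TRUE))
  r2 <- rank_candidates(cand2, top_k = 50)
  o <- order(-cand2$priority_score, cand2$gene_id)
  expect_equal(r2$gene_id, cand2$gene_id[o])
})

test_that("the candidate Venn partition reproduces the published split", {
  s <- c(paste0("s", 1:89), "shared")
  t <- c(paste0("t", 1:16), "shared")
  v <- venn_partition(s, t)
  expect_equal(v$specific_sensitive, 89L)
  expect_equal(v$specific_tolerant, 16L)
  expect_equal(v$common, 1L)
  expect_equal(v$total, 106L)
  ident <- venn_partition(c("a", "b"), c("a", "b"))
  expect_equal(ident$specific_sensitive + ident$specific_tolerant, 0L)
  # partitions always sum to the union size
  set.seed(50)
  for (i in 1:20) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    v2 <- venn_partition(a, b)
    expect_equal(v2$total, length(union(a, b)))
    expect_equal(v2$common, length(intersect(a, b)))
  }
})

test_that("hub genes are the candidates inside core pathways", {
  cand <- data.frame(gene_id = c("g1", "g2"), group = "sensitive",
                     stringsAsFactors = FALSE)
  tm <- data.frame(gene_id = c("g1", "g3"), term_id = c("T1", "T1"),
                   term_name = "t")
  h <- hub_genes(cand, "T1", tm)
  expect_equal(h$gene_id, "g1")
  expect_equal(h$pathways, "T1")
  h2 <- hub_genes(cand, "T9", tm)
  expect_equal(nrow(h2), 0L)
  expect_warning(hub_genes(cand, character(), tm), "empty core")
})

test_that("the genome-wide scan labels patterns and reports the pooled fit", {
  gd <- data.frame(gene_id = paste0("g", 1:4),
                   delta_meth = c(0.2, -0.3, 0.1, 0.02),
                   n_dmrs = 1L, n_contexts = 1L)
  de <- data.frame(gene_id = paste0("g", 1:4),
                   log2fc = c(-1, 2, 3, -4),
                   padj = c(0.01, 0.01, 0.01, 0.01))
  out <- genomewide_meth_expr_scan(gd, de)
  expect_equal(out$labels$pattern, c("negative", "negative", "positive",
                                     "other"))
  expect_equal(nrow(out$labels), 4L)
  fit <- lm(log2fc ~ delta_meth,
            data = merge(gd, de, by = "gene_id"))
  expect_equal(out$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
  # thresholds at 0/1 classify every measured gene
  all_lab <- genomewide_meth_expr_scan(gd, de, min_delta = 0,
                                       padj_max = 1)$labels$pattern
  expect_true(all(all_lab %in% c("negative", "positive")))
})
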