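test_that("identical control and drought counts produce no candidate DMRs", {
  r <- cx_records("A01", seq(10, 2000, by = 10), "CHH", 3, 10)
  out <- call_candidate_dmrs(r, r)
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(call_candidate_dmrs(r[0, ], r[0, ])), 0L)
})

test_that("an extreme window is called with delta +1", {
  pos <- seq(5, 195, by = 10)
  ctrl <- cx_records("A01", pos, "CHH", 0, 5)
  drt <- cx_records("A01", pos, "CHH", 5, 5)
  out <- call_candidate_dmrs(ctrl, drt)
  expect_equal(nrow(out), 1L)
  expect_equal(out$delta, 1.0)
  expect_equal(out$meth_control, 0)
  expect_equal(out$meth_drought, 1)
  expect_lt(out$p_value, 1e-10)
})

test_that("windows below the cytosine minimum are skipped", {
  pos <- c(50, 100, 150)  # only 3 in-context sites
  ctrl <- cx_records("A01", pos, "CG", 0, 20)
  drt <- cx_records("A01", pos, "CG", 20, 20)
  expect_equal(nrow(call_candidate_dmrs(ctrl, drt, min_cytosines = 4)), 0L)
  expect_equal(nrow(call_candidate_dmrs(ctrl, drt, min_cytosines = 3)), 1L)
})

test_that("context thresholds are strict and sign-symmetric", {
  d <- data.frame(chrom = "A01", start = 0L, end = 100L,
                  context = c("CG", "CG", "CHH", "CHG", "CHH"),
                  delta = c(0.21, 0.20, -0.26, 0.1501, 0.25),
                  stringsAsFactors = FALSE)
  kept <- filter_significant(d)
  expect_equal(kept$delta, c(0.21, -0.26, 0.1501))
  expect_error(filter_significant(transform(d, context = "CNN")),
               "unknown context")
})

test_that("significance filtering matches a brute-force filter and is idempotent", {
  set.seed(12)
  n <- 200
  d <- data.frame(chrom = "A01", start = 0L, end = 100L,
                  context = sample(c("CG", "CHG", "CHH"), n, TRUE),
                  delta = runif(n, -0.5, 0.5), stringsAsFactors = FALSE)
  thr <- c(CG = 0.20, CHG = 0.15, CHH = 0.25)
  keep <- logical(n)
  for (i in seq_len(n)) keep[i] <- abs(d$delta[i]) > thr[[d$context[i]]]
  got <- filter_significant(d)
  expect_equal(got$delta, d$delta[keep])
  expect_equal(filter_significant(got), got)
})

test_that("conserved merging honours the 100-bp gap boundary", {
  mk <- function(s2) data.frame(chrom = "A01",
                                start = c(100L, s2), end = c(200L, s2 + 50L),
                                context = "CHH", delta = c(0.3, 0.3),
                                genotype_id = c("g1", "g2"),
                                group = "sensitive", stringsAsFactors = FALSE)
  m50 <- merge_conserved(mk(250L))
  expect_equal(nrow(m50), 1L)
  expect_equal(c(m50$start, m50$end), c(100L, 300L))
  expect_equal(m50$n_support, 2L)
  m100 <- merge_conserved(mk(300L))   # gap exactly 100 -> merged
  expect_equal(nrow(m100), 1L)
  m101 <- merge_conserved(mk(301L))   # gap 101 -> kept apart
  expect_equal(nrow(m101), 2L)
})

test_that("merged direction and support-weighted mean delta are computed per genotype", {
  d <- data.frame(chrom = "A01", start = c(0L, 50L, 120L),
                  end = c(40L, 100L, 200L), context = "CHG",
                  delta = c(0.2, 0.4, 0.4),
                  genotype_id = c("g1", "g1", "g2"), group = "tolerant",
                  stringsAsFactors = FALSE)
  m <- merge_conserved(d)
  expect_equal(nrow(m), 1L)
  expect_equal(m$direction, "hyper")
  expect_equal(m$n_support, 2L)
  # g1 contributes mean(0.2, 0.4) = 0.3; g2 contributes 0.4
  expect_equal(m$mean_delta, mean(c(0.3, 0.4)))
  d$delta[3] <- -0.4
  expect_equal(merge_conserved(d)$direction, "mixed")
})

test_that("merging is idempotent and its output disjoint on random interval sets", {
  set.seed(4)
  for (rep in 1:100) {
    n <- sample(3:20, 1)
    s <- sample(0:5000, n)
    d <- data.frame(chrom = sample(c("A01", "C01"), n, TRUE),
                    start = s, end = s + sample(20:400, n, TRUE),
                    context = sample(c("CG", "CHH"), n, TRUE),
                    delta = runif(n, -1, 1),
                    genotype_id = sample(paste0("g", 1:4), n, TRUE),
                    group = "sensitive", stringsAsFactors = FALSE)
    m <- merge_conserved(d)
    # disjoint (indeed separated by > 100) within each context/chrom
    for (k in unique(paste(m$context, m$chrom))) {
      sub <- m[paste(m$context, m$chrom) == k, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1L)
        expect_true(all(sub$start[-1] - sub$end[-nrow(sub)] > 100))
    }
    # idempotence on the merged regions
    again <- merge_conserved(transform(m, delta = mean_delta,
                                       genotype_id = NA_character_))
    expect_equal(again[, c("chrom", "start", "end", "context")],
                 m[order(m$context, m$chrom, m$start),
                   c("chrom", "start", "end", "context")])
  }
})

test_that("genotype-support filtering is a strict >= threshold", {
  d <- data.frame(chrom = "A01", start = 1:4 * 1000L,
                  end = 1:4 * 1000L + 100L, context = "CHH",
                  group = "sensitive", n_support = c(1L, 2L, 3L, 6L),
                  stringsAsFactors = FALSE)
  expect_equal(support_filter(d, 3L)$n_support, c(3L, 6L))
  expect_equal(support_filter(d, 1L), d)
  # brute force on random support counts
  set.seed(6)
  d$n_support <- sample(1:6, 4, TRUE)
  expect_equal(support_filter(d, 4L)$n_support,
               d$n_support[d$n_support >= 4L])
})

test_that("feature annotation is strand-aware with documented precedence", {
  genes <- toy_genes(c("gp", "gm"), "A01", c(10000, 30000),
                     c(12000, 31000), c("+", "-"))
  regions <- data.frame(
    chrom = "A01",
    start = c(10500L,  # inside gp body
              31400L,  # 400 bp beyond gm's end coord = upstream for minus
              20000L,  # 3 kb or more from any gene
              9900L),  # spans gp's TSS: body wins over upstream
    end = c(10700L, 31600L, 20500L, 10100L))
  lab <- annotate_feature(regions, genes)
  expect_equal(lab, c("gene_body", "upstream2k", "intergenic",
                      "gene_body"))
  # 500 bp 5' of the minus-strand gene's start coord is downstream
  lab2 <- annotate_feature(data.frame(chrom = "A01", start = 29400L,
                                      end = 29600L), genes)
  expect_equal(lab2, "downstream2k")
})

test_that("the tiered count table reproduces CHH fractions and group excesses", {
  counts <- rbind(
    data.frame(group = "tolerant", context = c("CG", "CHG", "CHH"),
               tier = "significant", n = c(1362L, 918L, 4894L)),
    data.frame(group = "sensitive", context = c("CG", "CHG", "CHH"),
               tier = "significant", n = c(1515L, 911L, 5552L)))
  out <- dmr_count_table(counts)
  chh <- out$chh_fraction
  expect_equal(chh$chh_pct[chh$group == "sensitive"], 69.6)
  expect_equal(chh$chh_pct[chh$group == "tolerant"], 68.2)
  # equal groups give zero excess
  eq <- counts; eq$n[eq$group == "sensitive"] <- eq$n[eq$group == "tolerant"]
  expect_equal(dmr_count_table(eq)$excess$excess_pct, 0)
  # zero tolerant total is an error, not an Inf
  z <- counts; z$n[z$group == "tolerant"] <- 0L
  expect_error(dmr_count_table(z), "undefined")
})

test_that("chromosome density is count per Mb with subgenome totals", {
  cons <- data.frame(chrom = c(rep("A01", 10), rep("C01", 4)))
  cd <- chromosome_density(cons, c(A01 = 1e6, C01 = 2e6))
  expect_equal(cd$per_chrom$density_per_mb, c(10, 2))
  expect_equal(cd$per_subgenome$n[cd$per_subgenome$subgenome == "A"], 10L)
  # input order does not matter
  cd2 <- chromosome_density(cons[sample(nrow(cons)), , drop = FALSE],
                            c(A01 = 1e6, C01 = 2e6))
  expect_equal(cd2, cd)
  expect_error(chromosome_density(data.frame(chrom = "X99"),
                                  c(A01 = 1e6)), "X99")
})

test_that("common DMRs are the same-context overlaps between groups", {
  a <- data.frame(chrom = "A01", start = c(100L, 1000L), end = c(300L, 1200L),
                  context = c("CHH", "CG"), stringsAsFactors = FALSE)
  b <- data.frame(chrom = "A01", start = c(200L, 1000L), end = c(400L, 1200L),
                  context = c("CHH", "CHH"), stringsAsFactors = FALSE)
  cm <- common_dmrs(a, b)
  expect_equal(nrow(cm), 1L)   # the CG/CHH pair at 1000 does not count
  expect_equal(c(cm$start, cm$end), c(200L, 300L))
  expect_equal(cm$context, "CHH")
  expect_equal(nrow(common_dmrs(a, a[0, ])), 0L)
})

test_that("C-biased planting yields higher C-subgenome DMR density", {
  cfg <- small_config(seed = 2, chrom_length = 120000L,
                      c_subgenome_weight = 0.8,
                      planted_dmr_spec = data.frame(
                        context = "CHH", delta = 0.3, width = 300L,
                        count = 30L, group = "sensitive",
                        stringsAsFactors = FALSE),
                      n_negreg_genes = 0L)
  sim <- simulate_study(cfg)
  pl <- sim$truth$planted_dmrs
  cd <- chromosome_density(pl, sim$chrom_lengths)
  ps <- cd$per_subgenome
  expect_gt(ps$density_per_mb[ps$subgenome == "C"],
            ps$density_per_mb[ps$subgenome == "A"])
})
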