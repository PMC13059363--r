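# in-code fixture builders shared across test files

cx_records <- function(chrom, pos, context, n_meth, n_total,
                       strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_total = as.integer(n_total),
             coverage_zero = n_total == 0L, stringsAsFactors = FALSE)
}

toy_genes <- function(gene_id, chrom, start, end, strand) {
  data.frame(gene_id = gene_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             subgenome = ifelse(grepl("^A[0-9]", chrom), "A",
                                ifelse(grepl("^C[0-9]", chrom), "C",
                                       "other")),
             stringsAsFactors = FALSE)
}

empty_dmr_plant <- function() {
  data.frame(context = character(), delta = numeric(), width = integer(),
             count = integer(), group = character(),
             stringsAsFactors = FALSE)
}

empty_deg_plant <- function() {
  data.frame(log2fc = numeric(), count = integer(), group = character(),
             stringsAsFactors = FALSE)
}

# a fast desk-scale configuration for unit tests (2 genotypes/group);
# any simulation_config() argument can be overridden through ...
small_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed, n_chrom_A = 1L, n_chrom_C = 1L, chrom_length = 80000L,
    n_genes = 16L, n_genotypes_per_group = 2L, coverage_mean = 10,
    site_density = 0.15,
    planted_dmr_spec = data.frame(context = "CHH", delta = 0.40,
                                  width = 400L, count = 2L,
                                  group = c("sensitive", "tolerant"),
                                  stringsAsFactors = FALSE),
    planted_deg_spec = data.frame(log2fc = c(2, -2), count = 2L,
                                  group = c("sensitive", "tolerant"),
                                  stringsAsFactors = FALSE),
    n_negreg_genes = 2L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(simulation_config, args)
}

# memoised small simulation shared by several test files
.sim_cache <- new.env(parent = emptyenv())
cached_small_sim <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_study(small_config(seed = seed))
  .sim_cache[[key]]
}
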