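#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1.
#' Input values outside `[0, 1]` are rejected.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop_fmt("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric term enrichment
#'
#' For each term with at least one gene in the universe, tests the
#' over-representation of the term among the study genes with the
#' hypergeometric upper tail `P[X >= k]`, then adjusts across all
#' tested terms with Benjamini-Hochberg. A term is called significant
#' when `p_adj < alpha` (strict; default 0.01).
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of universe gene ids.
#' @param term_map Data frame with `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @param alpha Significance threshold on adjusted p.
#' @return Data frame with `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adj`, `significant`, ordered by `p_adj`.
#' @export
hypergeom_enrich <- function(study, universe, term_map, alpha = 0.01) {
  study <- unique(study); universe <- unique(universe)
  rogue <- setdiff(study, universe)
  if (length(rogue) > 0L)
    stop_fmt("study genes not in universe: %s",
             paste(utils::head(rogue, 5L), collapse = ", "))
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  tm <- tm[!duplicated(tm[, c("gene_id", "term_id")]), , drop = FALSE]
  if (nrow(tm) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      p_adj = numeric(), significant = logical()))
  K <- table(tm$term_id)
  in_study <- tm[tm$gene_id %in% study, , drop = FALSE]
  k <- table(factor(in_study$term_id, levels = names(K)))
  N <- length(universe); n <- length(study)
  p <- stats::phyper(as.integer(k) - 1L, as.integer(K),
                     N - as.integer(K), n, lower.tail = FALSE)
  name_of <- if ("term_name" %in% names(tm))
    tm$term_name[match(names(K), tm$term_id)] else names(K)
  res <- data.frame(term_id = names(K), term_name = name_of,
                    k = as.integer(k), K = as.integer(K), n = n, N = N,
                    p_value = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE)
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p_adj, res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Four-way intersection of enriched-term sets
#'
#' Computes all 15 exclusive partitions of the union of four term sets
#' (two phenotype groups x two omics layers), the core (terms present
#' in all four sets) and per-set unique counts. The partition counts
#' always sum to the size of the union.
#'
#' @param sets Named list of exactly four character vectors of term
#'   ids.
#' @return List with `partitions` (data frame: one row per non-empty
#'   membership combination, logical columns per set plus `count`),
#'   `core` (character vector), `unique_counts` (named integer vector)
#'   and `union_size`.
#' @export
pathway_intersections <- function(sets) {
  if (length(sets) != 4L || is.null(names(sets)))
    stop_fmt("sets must be a named list of four term-id vectors")
  sets <- lapply(sets, unique)
  un <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 1L) memb <- matrix(memb, nrow = 1L,
                                       dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4L))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  key <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
  ckey <- apply(combos, 1L, function(r) paste(as.integer(r), collapse = ""))
  count <- as.integer(table(factor(key, levels = ckey)))
  partitions <- cbind(combos, count = count)
  rownames(partitions) <- NULL
  core <- un[rowSums(memb) == 4L]
  unique_counts <- vapply(seq_len(4L), function(i)
    sum(memb[, i] & rowSums(memb) == 1L), integer(1))
  names(unique_counts) <- names(sets)
  list(partitions = partitions, core = core,
       unique_counts = unique_counts, union_size = length(un))
}

#' Categorise core pathways
#'
#' Counts core terms per functional category; every core term must map
#' to exactly one category.
#'
#' @param core_terms Character vector of core term ids.
#' @param category_map Data frame with `term_id`, `category`, or a
#'   named character vector (names = term ids).
#' @return Data frame with `category`, `n`; attribute `total` equals
#'   `length(core_terms)`.
#' @export
categorize_core_pathways <- function(core_terms, category_map) {
  if (is.data.frame(category_map)) {
    map <- stats::setNames(category_map$category, category_map$term_id)
  } else map <- category_map
  core_terms <- unique(core_terms)
  unmapped <- core_terms[!core_terms %in% names(map)]
  if (length(unmapped) > 0L)
    stop_fmt("core term(s) without category: %s",
             paste(utils::head(unmapped, 5L), collapse = ", "))
  tab <- table(map[core_terms])
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- length(core_terms)
  out
}
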