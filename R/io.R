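#' @importFrom utils read.table write.table count.fields
NULL

CONTEXTS <- c("CG", "CHG", "CHH")

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a Bismark-style CX report
#'
#' Parses a 7-column tab-separated per-cytosine methylation report
#' (chromosome, 1-based position, strand, methylated count, unmethylated
#' count, context, trinucleotide) into a cytosine-record data frame.
#' Records with zero total coverage are retained and flagged, so that
#' positional completeness is preserved for binning; downstream level
#' computations exclude them through their coverage filter.
#'
#' @param path Path to a CX report (plain or gzip text).
#' @return A data frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `n_meth`, `n_total` and logical `coverage_zero`.
#' @export
read_cx_report <- function(path) {
  if (!file.exists(path)) stop_fmt("file does not exist: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) return(empty_cx())
  bad <- which(nf != 7L)
  if (length(bad) > 0L)
    stop_fmt("malformed CX report %s: expected 7 tab-separated columns, got %d at line %d",
             path, nf[bad[1L]], bad[1L])
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "pos", "strand", "n_meth",
                                 "n_unmeth", "context", "tri"),
                   colClasses = c("character", "integer", "character",
                                  "integer", "integer", "character",
                                  "character"))
  if (any(df$n_meth < 0L) || any(df$n_unmeth < 0L))
    stop_fmt("negative read count in CX report %s", path)
  if (any(df$pos < 1L))
    stop_fmt("non-positive position in CX report %s", path)
  ok_ctx <- df$context %in% CONTEXTS
  if (!all(ok_ctx))
    stop_fmt("unknown methylation context '%s' in CX report %s (line %d)",
             df$context[which(!ok_ctx)[1L]], path, which(!ok_ctx)[1L])
  if (!all(df$strand %in% c("+", "-")))
    stop_fmt("invalid strand in CX report %s", path)
  out <- data.frame(chrom = df$chrom, pos = df$pos, strand = df$strand,
                    context = df$context, n_meth = df$n_meth,
                    n_total = df$n_meth + df$n_unmeth,
                    stringsAsFactors = FALSE)
  out$coverage_zero <- out$n_total == 0L
  out
}

empty_cx <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             context = character(), n_meth = integer(), n_total = integer(),
             coverage_zero = logical(), stringsAsFactors = FALSE)
}

#' Write a CX report
#'
#' Inverse of [read_cx_report()]: writes cytosine records as a 7-column
#' Bismark-style CX report. The trinucleotide column is filled with the
#' context string (the parser ignores it).
#'
#' @param records Cytosine-record data frame.
#' @param path Output path.
#' @export
write_cx_report <- function(records, path) {
  df <- data.frame(records$chrom, records$pos, records$strand,
                   records$n_meth, records$n_total - records$n_meth,
                   records$context, records$context)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

subgenome_of <- function(chrom) {
  ifelse(grepl("^A[0-9]", chrom, ignore.case = TRUE), "A",
         ifelse(grepl("^C[0-9]", chrom, ignore.case = TRUE), "C", "other"))
}

#' Read gene annotation from GFF3 or BED6
#'
#' Gene models are stored internally with 0-based half-open coordinates;
#' GFF3's 1-based closed intervals are converted on input (start-1, end)
#' and back on output, BED coordinates pass through. The subgenome of
#' each gene is derived from its chromosome name: `A` for chromosomes
#' matching `A<digit>`, `C` for `C<digit>` (case-insensitive), otherwise
#' `other` -- the conventional naming of the two ancestral subgenomes of
#' allopolyploid *Brassica napus*.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` (rows of type `gene`) or `"bed"` (6 columns).
#' @return Data frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `subgenome`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("file does not exist: %s", path)
  if (format == "gff3") {
    ln <- readLines(path)
    ln <- ln[!grepl("^#", ln) & nzchar(ln)]
    if (length(ln) == 0L) return(empty_genes())
    f <- strsplit(ln, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf != 9L))
      stop_fmt("malformed GFF3 %s: expected 9 columns at line %d", path,
               which(nf != 9L)[1L])
    m <- do.call(rbind, f)
    keep <- m[, 3L] == "gene"
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L) return(empty_genes())
    id <- sub(".*ID=([^;]+).*", "\\1", m[, 9L])
    start1 <- as.integer(m[, 4L]); end1 <- as.integer(m[, 5L])
    strand <- m[, 7L]
    if (any(!strand %in% c("+", "-")))
      stop_fmt("gene without strand in %s", path)
    start0 <- start1 - 1L; end0 <- end1
    if (any(end0 <= start0)) stop_fmt("gene with end <= start in %s", path)
    g <- data.frame(gene_id = id, chrom = m[, 1L], start = start0,
                    end = end0, strand = strand, stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                     stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(empty_genes())
    if (ncol(df) < 6L) stop_fmt("BED6 required (6 columns) in %s", path)
    if (any(!df[[6L]] %in% c("+", "-")))
      stop_fmt("gene without strand in %s", path)
    if (any(df[[3L]] <= df[[2L]]))
      stop_fmt("gene with end <= start in %s", path)
    g <- data.frame(gene_id = as.character(df[[4L]]), chrom = df[[1L]],
                    start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                    strand = df[[6L]], stringsAsFactors = FALSE)
  }
  g$subgenome <- subgenome_of(g$chrom)
  g
}

empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), subgenome = character(),
             stringsAsFactors = FALSE)
}

#' Write gene annotation
#'
#' @param genes Gene-model data frame (0-based half-open internal
#'   coordinates).
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @export
write_gene_annotation <- function(genes, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    ln <- sprintf("%s\tdmrlink\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  genes$chrom, genes$start + 1L, genes$end, genes$strand,
                  genes$gene_id)
    writeLines(c("##gff-version 3", ln), path)
  } else {
    df <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                     ".", genes$strand)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a gene-by-sample count matrix
#'
#' @param path TSV with a header of sample ids and gene ids in the first
#'   column. Cells must be non-negative integers; duplicate gene ids and
#'   ragged rows are rejected.
#' @return Integer matrix, genes in rows, samples in columns (input
#'   order preserved).
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop_fmt("file does not exist: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L)
    stop_fmt("ragged rows in count matrix %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop_fmt("duplicate gene_id '%s' in count matrix %s",
             ids[duplicated(ids)][1L], path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop_fmt("count matrix %s must contain non-negative integers", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix
#' @param mat Integer matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects columns `sample_id`, `genotype_id`, `group`, `treatment`,
#' `replicate`. Validates that groups are `tolerant`/`sensitive`,
#' treatments `control`/`drought`, that (genotype, treatment, replicate)
#' is unique and that each genotype belongs to exactly one group.
#'
#' @param path TSV path.
#' @return Data frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "genotype_id", "group", "treatment", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_fmt("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(df$group %in% c("tolerant", "sensitive")))
    stop_fmt("sample sheet group must be 'tolerant' or 'sensitive'")
  if (!all(df$treatment %in% c("control", "drought")))
    stop_fmt("sample sheet treatment must be 'control' or 'drought'")
  key <- paste(df$genotype_id, df$treatment, df$replicate)
  if (anyDuplicated(key))
    stop_fmt("duplicate (genotype, treatment, replicate) in sample sheet")
  gg <- unique(df[, c("genotype_id", "group")])
  if (anyDuplicated(gg$genotype_id))
    stop_fmt("a genotype is assigned to more than one group")
  df
}

#' Write a sample sheet
#' @param samples Sample metadata data frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term map
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`.
#' @return Data frame with those three columns.
#' @export
read_term_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "term_name")
  if (!all(need %in% names(df)))
    stop_fmt("term map must have columns gene_id, term_id, term_name")
  df[, need]
}

#' Write a gene-to-term map
#' @param term_map Data frame with `gene_id`, `term_id`, `term_name`.
#' @param path Output path.
#' @export
write_term_map <- function(term_map, path) {
  write.table(term_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate gene ids through a homolog mapping table
#'
#' Used to bridge annotation systems (for example expression quantified
#' against one reference genome and methylation against another, linked
#' by a homolog table). One-to-many mappings expand to all targets;
#' unmapped ids are reported, never silently dropped.
#'
#' @param map Data frame whose first column is the source id and second
#'   the target id, or a path to such a two-column TSV (with header).
#' @param ids Character vector of source ids.
#' @return List with `mapped` (data frame `source`, `target`) and
#'   `unmapped` (character vector).
#' @export
translate_gene_ids <- function(map, ids) {
  if (is.character(map) && length(map) == 1L) {
    map <- read.table(map, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(map) || nrow(map) == 0L || ncol(map) < 2L)
    stop_fmt("empty or invalid id mapping table")
  src <- as.character(map[[1L]]); tgt <- as.character(map[[2L]])
  hit <- ids %in% src
  keep <- src %in% ids
  mapped <- data.frame(source = src[keep], target = tgt[keep],
                       stringsAsFactors = FALSE)
  mapped <- mapped[order(match(mapped$source, ids)), , drop = FALSE]
  rownames(mapped) <- NULL
  list(mapped = mapped, unmapped = ids[!hit])
}
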