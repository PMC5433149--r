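# TSV dialect used throughout: features x samples matrices with the feature
# id in the first column and sample ids in the header; tab-separated, no
# quoting.

#' Read / write an expression (or methylation) matrix as TSV
#'
#' First column = feature id, header = sample ids.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_expression_matrix(m)
  m
}

#' @rdname read_expression_tsv
#' @param x matrix to write.
#' @param id_column name for the feature-id column (default `"feature"`).
#' @export
write_expression_tsv <- function(x, path, id_column = "feature") {
  check_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a survival table (sample, time_months, event)
#' @param path file path.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_survival_table(df)
  df
}

#' @rdname read_survival_tsv
#' @param surv survival table to write.
#' @export
write_survival_tsv <- function(surv, path) {
  check_survival_table(surv)
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' BED coordinates are 0-based half-open, which is also this package's
#' internal convention, so values pass through unchanged.
#'
#' @param path BED file (3+ columns).
#' @return data.frame: `chrom`, `start`, `end`, and `name` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  check_intervals(out, "bed")
  out
}

#' Read a probe annotation table
#'
#' Expects columns `probe`, `chrom`, and a position column; 1-based
#' positions (the common array-annotation convention) are converted to the
#' internal 0-based convention unless `one_based = FALSE`.
#'
#' @param path TSV path with columns probe, chrom, pos (or pos_1based).
#' @param one_based whether the file's positions are 1-based (default TRUE).
#' @return data.frame: `probe`, `chrom`, `pos` (0-based), plus any extra
#'   columns (e.g. `tss_distance`, `ctcf_class`) passed through.
#' @export
read_probe_table <- function(path, one_based = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pos_col <- intersect(c("pos", "pos_1based", "position"), names(df))[1]
  if (!all(c("probe", "chrom") %in% names(df)) || is.na(pos_col))
    stop("probe table needs columns probe, chrom and pos/pos_1based")
  df$pos <- df[[pos_col]] - as.integer(one_based)
  if (pos_col != "pos") df[[pos_col]] <- NULL
  df
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(stats::setNames(names(sets), names(sets)),
         function(nm) gene_set(nm, unique(sets[[nm]])))
}

#' Read network priors from TSV edge lists
#'
#' @param motif_path TSV with columns regulator, gene, weight.
#' @param ppi_path TSV with columns regulator_a, regulator_b, weight
#'   (undirected; the diagonal is set to 1).
#' @param expression genes x samples matrix for the coexpression prior.
#' @param mirna_path optional one-column file of miRNA regulator ids.
#' @return a [regulatory_priors()].
#' @export
read_regulatory_priors <- function(motif_path, ppi_path, expression,
                                   mirna_path = NULL) {
  motif <- utils::read.delim(motif_path, stringsAsFactors = FALSE)
  if (!all(c("regulator", "gene", "weight") %in% names(motif)))
    stop("motif prior needs columns regulator, gene, weight")
  regs <- sort(unique(motif$regulator))
  genes <- rownames(expression)
  w0 <- matrix(0, length(regs), length(genes), dimnames = list(regs, genes))
  keep <- motif$gene %in% genes
  w0[cbind(motif$regulator[keep], motif$gene[keep])] <- motif$weight[keep]
  p0 <- diag(length(regs))
  dimnames(p0) <- list(regs, regs)
  if (!is.null(ppi_path)) {
    ppi <- utils::read.delim(ppi_path, stringsAsFactors = FALSE)
    if (!all(c("regulator_a", "regulator_b", "weight") %in% names(ppi)))
      stop("PPI prior needs columns regulator_a, regulator_b, weight")
    ok <- ppi$regulator_a %in% regs & ppi$regulator_b %in% regs
    ppi <- ppi[ok, , drop = FALSE]
    p0[cbind(ppi$regulator_a, ppi$regulator_b)] <- ppi$weight
    p0[cbind(ppi$regulator_b, ppi$regulator_a)] <- ppi$weight
    diag(p0) <- 1
  }
  mirnas <- if (!is.null(mirna_path))
    utils::read.delim(mirna_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  else character()
  regulatory_priors(w0, p0, expression, intersect(mirnas, regs))
}

#' Write an edge table as TSV
#' @param edges `edge_table` data.frame.
#' @param path output path.
#' @export
write_edge_table_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
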