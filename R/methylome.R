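# Coordinates are 0-based, half-open [start, end) throughout this module;
# single-base probe positions are 0-based. BED files carry this convention
# natively; 1-based tables must be converted on ingest (see read_probe_table).

#' The 14q32 imprinted region (hg19)
#'
#' Chromosome 14, 89,800,000-109,000,000 (19.2 Mb), the region harbouring the
#' DLK1-DIO3 imprinted locus and the genome's largest miRNA cluster.
#'
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
region_14q32 <- function() {
  data.frame(chrom = "chr14", start = 89800000L, end = 109000000L,
             name = "14q32", stringsAsFactors = FALSE)
}

check_intervals <- function(iv, arg = "intervals") {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(iv) || !all(req %in% names(iv)))
    stop(sprintf("`%s` must be a data.frame with chrom, start, end", arg))
  if (any(!is.finite(iv$start)) || any(!is.finite(iv$end)) ||
      any(iv$start < 0) || any(iv$start >= iv$end))
    stop(sprintf("malformed intervals in `%s`: need 0 <= start < end", arg))
  invisible(iv)
}

iv_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(start = iv$start + 1L, end = iv$end))
}

#' Classify probes by CTCF binding-site context
#'
#' A probe is `in_site` when its position lies within a CTCF site,
#' `near_site` when it lies within `near_window_bp` of a site boundary
#' (boundary inclusive) without being inside, and `not_in_site` otherwise.
#' The three classes partition the probes. The near window defaults to
#' 1000 bp and is a tunable convention, not a measured quantity.
#'
#' @param probes data.frame with `probe`, `chrom`, `pos` (0-based base).
#' @param ctcf_sites interval data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open), e.g. from [read_bed()].
#' @param near_window_bp distance defining "near", in bp.
#' @return the `probes` data.frame with a `ctcf_class` column added.
#' @export
annotate_ctcf_overlap <- function(probes, ctcf_sites, near_window_bp = 1000L) {
  if (!is.data.frame(probes) || !all(c("probe", "chrom", "pos") %in% names(probes)))
    stop("probes must have columns probe, chrom, pos")
  check_intervals(ctcf_sites, "ctcf_sites")
  if (near_window_bp < 0) stop("near_window_bp must be non-negative")
  pr <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(start = probes$pos + 1L,
                                                width = 1L))
  sites <- iv_granges(ctcf_sites)
  # near-range in 0-based terms: [start - w, end + w], both boundaries inclusive
  near_rng <- GenomicRanges::GRanges(
    ctcf_sites$chrom,
    IRanges::IRanges(start = pmax(ctcf_sites$start - near_window_bp, 0L) + 1L,
                     end = ctcf_sites$end + near_window_bp + 1L))
  inside <- IRanges::overlapsAny(pr, sites)
  near <- IRanges::overlapsAny(pr, near_rng) & !inside
  probes$ctcf_class <- ifelse(inside, "in_site",
                              ifelse(near, "near_site", "not_in_site"))
  probes
}

#' Count CpG islands within an upstream window
#'
#' Counts islands intersecting `[position - window, position)` (upstream =
#' decreasing coordinates, the + strand convention; strand handling for -
#' strand genes is the caller's responsibility via its annotation).
#'
#' @param position 0-based position(s); vectorized.
#' @param islands CpG-island interval data.frame (0-based half-open).
#' @param window upstream window in bp (default 100,000).
#' @param chrom optional chromosome name(s) to match against the islands;
#'   when omitted all islands are assumed on the query chromosome.
#' @return integer vector of counts, one per position.
#' @export
cpg_upstream_count <- function(position, islands, window = 100000L,
                               chrom = NULL) {
  check_intervals(islands, "islands")
  if (window < 0) stop("window must be non-negative")
  if (!is.null(chrom)) islands <- islands[islands$chrom %in% chrom, ,
                                          drop = FALSE]
  if (window == 0 || nrow(islands) == 0)
    return(integer(length(position)))
  # query [pos - window, pos) 0-based -> 1-based [pos - window + 1, pos]
  q <- IRanges::IRanges(start = pmax(position - window, 0L) + 1L,
                        end = position)
  subj <- IRanges::IRanges(start = islands$start + 1L, end = islands$end)
  IRanges::countOverlaps(q, subj)
}

#' Spearman correlation table between matched rows of two matrices
#'
#' For each requested (row of `a`, row of `b`) pair computes the Spearman
#' rank correlation (average-tie ranks) with a two-sided p-value, and
#' attaches the conventional strength bin. Constant vectors are flagged
#' (`degenerate = TRUE`, rho/p = NA) rather than propagating NaN.
#'
#' @param a,b numeric matrices with matching sample columns and row names.
#' @param pairs data.frame with columns `a_id`, `b_id` naming rows of `a`
#'   and `b`; defaults to the full cross of rows.
#' @return data.frame: `a_id`, `b_id`, `rho`, `p`, `strength`, `degenerate`.
#' @export
spearman_correlation_table <- function(a, b, pairs = NULL) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (ncol(a) != ncol(b)) stop("a and b must have matching sample columns")
  if (is.null(pairs))
    pairs <- expand.grid(a_id = rownames(a), b_id = rownames(b),
                         stringsAsFactors = FALSE)
  if (!all(c("a_id", "b_id") %in% names(pairs)))
    stop("pairs must have columns a_id and b_id")
  if (!all(pairs$a_id %in% rownames(a)) || !all(pairs$b_id %in% rownames(b)))
    stop("pairs reference unknown row ids")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xv <- a[pairs$a_id[i], ]; yv <- b[pairs$b_id[i], ]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
      return(c(NA_real_, NA_real_, TRUE))
    ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value, FALSE)
  })
  res <- do.call(rbind, res)
  out <- data.frame(a_id = pairs$a_id, b_id = pairs$b_id,
                    rho = res[, 1], p = res[, 2],
                    strength = ifelse(is.na(res[, 1]), NA_character_,
                                      classify_correlation_strength(
                                        ifelse(is.na(res[, 1]), 0, res[, 1]))),
                    degenerate = as.logical(res[, 3]),
                    stringsAsFactors = FALSE)
  out
}

#' Bin a correlation coefficient by conventional strength cut-points
#'
#' Bins on the magnitude: `|rho| >= 0.5` strong, `[0.3, 0.5)` moderately
#' strong, `[0.15, 0.3)` moderate, below 0.15 weak. The sign is reported
#' separately by the correlation itself.
#'
#' @param rho numeric vector of correlations, `|rho| <= 1`.
#' @return character vector of bins.
#' @export
classify_correlation_strength <- function(rho) {
  if (any(is.na(rho)) || any(abs(rho) > 1))
    stop("correlations must be non-missing with |rho| <= 1")
  a <- abs(rho)
  ifelse(a >= 0.5, "strong",
         ifelse(a >= 0.3, "moderately_strong",
                ifelse(a >= 0.15, "moderate", "weak")))
}

#' Three-way methylation / expression / phenotype corner assignment
#'
#' Median-splits each of the three axes and assigns every sample to one of
#' the eight (high/low)^3 corners. The concordance score is the fraction of
#' samples in the two CTCF-consistent corners: for an in-site probe
#' (positive methylation-expression coupling) these are high/high/high and
#' low/low/low; for an out-of-site probe the methylation axis is inverted
#' (high/low/low and low/high/high). Under independence the expectation is
#' 2 of 8 corners = 0.25.
#'
#' @param methyl numeric methylation vector (one probe across samples).
#' @param expr numeric expression summary (e.g. signed-average miRNA score).
#' @param phenotype numeric phenotype (e.g. proliferative capacity).
#' @param mode `"in_site"` or `"out_of_site"`.
#' @return list: `corners` (character, e.g. "HLH" in methyl/expr/phenotype
#'   order), `score`, `mode`.
#' @export
threeway_pattern_assignment <- function(methyl, expr, phenotype,
                                        mode = c("in_site", "out_of_site")) {
  mode <- match.arg(mode)
  n <- length(methyl)
  if (length(expr) != n || length(phenotype) != n)
    stop("all three axes must have equal length")
  if (n < 4) stop("at least 4 samples are required")
  hl <- function(v) ifelse(v > stats::median(v), "H", "L")
  corners <- paste0(hl(methyl), hl(expr), hl(phenotype))
  consistent <- if (mode == "in_site") c("HHH", "LLL") else c("HLL", "LHH")
  list(corners = corners, score = mean(corners %in% consistent), mode = mode)
}
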