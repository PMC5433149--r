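# Internal helpers shared across modules.

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so generators never leak global state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Validate a features x samples expression matrix.
check_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix (features x samples)", arg))
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", arg))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("`%s` must carry feature row names and sample column names", arg))
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate feature ids in `%s`", arg))
  if (anyDuplicated(colnames(x)))
    stop(sprintf("duplicate sample ids in `%s`", arg))
  invisible(x)
}

# Validate a survival table (data.frame: sample, time_months, event, ...).
check_survival_table <- function(surv, x = NULL) {
  req <- c("sample", "time_months", "event")
  if (!is.data.frame(surv) || !all(req %in% names(surv)))
    stop("survival table needs columns: sample, time_months, event")
  if (any(!is.finite(surv$time_months)) || any(surv$time_months <= 0))
    stop("survival times must be positive and finite")
  if (!all(surv$event %in% c(0, 1)))
    stop("event indicator must be 0/1")
  if (!is.null(x)) {
    if (!identical(as.character(surv$sample), colnames(x)))
      stop("survival table samples must match expression matrix columns (same order)")
  }
  invisible(surv)
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

col_sds <- function(x) sqrt(row_vars(t(x)))
row_sds <- function(x) sqrt(row_vars(x))
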