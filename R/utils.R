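# Internal helpers shared across modules.

# Classed error so callers can distinguish schema/parse/unit/domain/config
# failures programmatically.
pd_stop <- function(msg, class = "error", call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("phagedyn_", class), "phagedyn_error")))
}

pd_warn <- function(msg) {
  warning(warningCondition(msg, class = c("phagedyn_warning")))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-table seed stream: a single study seed fans out to one
# sub-seed per named table so adding a table never perturbs earlier ones.
stream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((as.numeric(seed) %% 65011 + 1) * 32749 + h) %% 2147483629L
}

# Two-sided Wilcoxon rank-sum p-value. Exact distribution when both sides
# have n <= 25 and no ties; otherwise normal approximation with continuity
# correction (wilcox.test falls back itself when ties are present).
rank_sum_p <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 1L || length(y) < 1L) return(NA_real_)
  exact <- length(x) <= 25L && length(y) <= 25L
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

# All permutations of 1..n as an n! x n integer matrix (used only for the
# exact Spearman null at small n).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[((i - 1L) * m + 1L):(i * m), ] <- cbind(i, matrix(rest[sub], m))
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, required_cols = NULL, what = "table") {
  if (!file.exists(path)) pd_stop(sprintf("file not found: %s", path), "io_error")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing))
      pd_stop(sprintf("%s at %s is missing column(s): %s",
                      what, path, paste(missing, collapse = ", ")), "schema_error")
  }
  df
}
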