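# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop with a consistent error class so callers/tests can distinguish
# format errors (bad file shape) from value errors (bad content)
mq_stop <- function(msg, class) {
  stop(structure(class = c(class, "mqtlkit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

mq_value_error  <- function(msg) mq_stop(msg, "mqtlkit_value_error")
mq_format_error <- function(msg) mq_stop(msg, "mqtlkit_format_error")

# log-sum-exp over matrix rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# least-squares slope of y over x
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

# longest increasing subsequence (indices), O(n^2); ties broken toward
# earlier elements so the first of a conflicting pair is retained
lis_indices <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (v[j] <= v[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  out <- integer(0)
  while (!is.na(i)) {
    out <- c(i, out)
    i <- prev[i]
  }
  out
}

# Theil-Sen line: median pairwise slope, median residual intercept;
# falls back to unit slope when all x coincide
theil_sen <- function(x, y) {
  slopes <- numeric(0)
  n <- length(x)
  for (i in seq_len(n - 1L)) {
    dx <- x[(i + 1L):n] - x[i]
    dy <- y[(i + 1L):n] - y[i]
    ok <- dx != 0
    slopes <- c(slopes, dy[ok] / dx[ok])
  }
  slope <- if (length(slopes) > 0) stats::median(slopes) else 1
  if (!is.finite(slope) || slope <= 0) slope <- 1
  list(slope = slope, icept = stats::median(y - slope * x))
}

# uniform integer draw on [a, b]; safe when a == b (unlike sample(seq(a,b)))
sample_range <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

read_tsv_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) mq_format_error(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    mq_format_error(sprintf("missing required column(s): %s",
                            paste(miss, collapse = ", ")))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
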