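# Internal helpers shared across modules.

# Derive a per-stage RNG seed from the run seed so that adding a stage never
# perturbs the streams of earlier stages. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) * 1009 + stage * 9973) %% 2147483629)
}

# Natural (alphanumeric) sort: "Z2" before "Z10", matching the figure
# convention of listing equivalent markers in alphabetical and numerical
# order.
natural_order <- function(x) {
  x <- as.character(x)
  # split into alternating alpha / numeric chunks, pad numbers
  key <- vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    parts <- vapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) sprintf("%020d", as.numeric(p)) else p
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  order(key, x)
}

natural_sort <- function(x) x[natural_order(x)]

# round half away from zero, the convention used for reported percentages
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# write a data.frame as a TSV ending in a newline, tab the only delimiter
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
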