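# Fixture builders shared across tests. Everything is generated in code;
# no data files ship with the package.

# Minimal two-block plate export written to a temp file.
write_plate_fixture <- function(mfi, counts, samples,
                                path = tempfile(fileext = ".csv"),
                                format = plate_format()) {
  d <- format$delimiter
  hdr <- paste(c("Location", "Sample", colnames(mfi)), collapse = d)
  block <- function(title, m) {
    c(title, hdr,
      vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], samples[i], m[i, ]), collapse = d)
      }, ""))
  }
  writeLines(c(block(format$median_header, mfi),
               block(format$count_header, counts)), path)
  path
}

# A hand-rolled bbea_binding for unit tests that bypass plate IO.
make_binding <- function(b, plate, sample, replicate = NULL, extra = NULL) {
  n <- nrow(b)
  meta <- data.frame(
    plate = plate,
    well = well_labels()[seq_len(n)],
    reading_index = seq_len(n) - 1L,
    sample = sample,
    replicate = replicate %||% rep(1L, n),
    is_nsb = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(extra)) meta <- cbind(meta, extra)
  rownames(meta) <- paste(meta$plate, meta$well, sep = ":")
  rownames(b) <- rownames(meta)
  structure(list(b = b, y = b, floored = b < 0, counts = b * 0 + 50,
                 meta = meta, baseline = NULL, qc = NULL,
                 level = "well", isotype = NULL),
            class = "bbea_binding")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force two-way ANOVA ICC oracle (sums of squares written
# out longhand, no shared code with icc()).
icc_oracle <- function(x, type) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (sum(x[i, ]) / k - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(x[, j]) / n - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  if (type == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
}

# Brute-force BH step-up oracle: find, for each i, the smallest adjusted
# value by the textbook definition min_{j >= i} (m/j) p_(j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- numeric(0)
    for (j in i:m) cand <- c(cand, m / j * ps[j])
    adj[i] <- min(1, cand)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
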