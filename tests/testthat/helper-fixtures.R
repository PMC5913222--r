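# Checksum pinning the packaged evidence transcription; tallies asserted in
# the suite are only meaningful against this exact file.
evidence_md5 <- "970d36e2f77a5e0658adb5f2501c2cef"

# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# A minimal balanced two-group, multi-gene wide Cq table.
make_cq_df <- function(genes = c("Tgt", "Ref"), n_per_group = 3,
                       base_cq = 25, jitter = 0) {
  n <- 2 * n_per_group
  sample_id <- sprintf("S%02d", seq_len(n))
  group <- rep(c("RF", "Li"), each = n_per_group)
  rows <- lapply(genes, function(g) {
    cq <- base_cq + seq_len(n) / 10 + jitter
    data.frame(sample_id = sample_id, group = group, gene = g, plate = "P1",
               cq_rep1 = cq, cq_rep2 = cq + 0.01,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

make_cq_dataset <- function(...) {
  suppressMessages(cq_dataset(make_cq_df(...), control = "RF"))
}

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent brute-force oracles ------------------------------------------

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# values to the two groups (utils::combn), using the same U orientation
# (pairs with y > x) as the implementation under test.
brute_force_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  n <- length(y)
  u_of <- function(xi, yi) sum(outer(yi, xi, ">")) + 0.5 * sum(outer(yi, xi, "=="))
  u_obs <- u_of(x, y)
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

brute_force_hl <- function(x, y) {
  median(as.vector(outer(y, x, "-")))
}

# Literal Benjamini-Hochberg by its defining minimisation: the adjusted
# value of p_i is the smallest threshold-scaled value t * m / #{p <= t}
# over candidate thresholds t >= p_i, capped at 1.
brute_force_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    ts <- p[p >= p[i]]
    min(1, vapply(ts, function(t) t * m / sum(p <= t), numeric(1)))
  }, numeric(1))
}
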