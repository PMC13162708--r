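# Independent brute-force oracles. These deliberately avoid the package's
# IRanges-based machinery: every statistic is recomputed by per-base marking
# or all-pairs loops, so agreement is evidence, not tautology.

# per-base membership: a source base is aligned iff it falls in any ungapped
# block of any chain (walks chain blocks by cumulative offsets, like the
# format definition, not like the index)
bf_aligned_bases <- function(seq_id, start, end, chains) {
  pos <- seq(start, end - 1)
  aligned <- rep(FALSE, length(pos))
  for (ch in chains) {
    if (ch$t_name != seq_id) next
    t <- ch$t_start
    b <- ch$blocks
    for (i in seq_len(nrow(b))) {
      aligned <- aligned | (pos >= t & pos < t + b$size[i])
      t <- t + b$size[i] + b$dt[i]
    }
  }
  sum(aligned)
}

# per-base union coverage of one interval by a set of intervals
bf_covered <- function(start, end, cov_starts, cov_ends) {
  pos <- seq(start, end - 1)
  hit <- rep(FALSE, length(pos))
  for (i in seq_along(cov_starts))
    hit <- hit | (pos >= cov_starts[i] & pos < cov_ends[i])
  sum(hit)
}

overlaps_1bp <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# random but always-valid chain over a source sequence
random_chain <- function(seq_id, t_size, chain_id, minus_ok = TRUE) {
  nb <- sample(1:8, 1)
  size <- sample(1:30, nb, replace = TRUE)
  dt <- c(sample(0:15, max(nb - 1, 0), replace = TRUE), 0)
  dq <- c(sample(0:15, max(nb - 1, 0), replace = TRUE), 0)
  t_span <- sum(size + dt)
  q_span <- sum(size + dq)
  t_start <- sample(0:max(0, t_size - t_span), 1)
  q_start <- sample(0:50, 1)
  q_size <- q_start + q_span + sample(0:50, 1)
  q_strand <- if (minus_ok && runif(1) < 0.4) "-" else "+"
  relic:::new_chain(score = sample(100:5000, 1),
                    t_name = seq_id, t_size = t_size, t_strand = "+",
                    t_start = t_start, t_end = t_start + t_span,
                    q_name = paste0("q_", chain_id), q_size = q_size,
                    q_strand = q_strand, q_start = q_start,
                    q_end = q_start + q_span, chain_id = chain_id,
                    blocks = data.frame(size = size, dt = dt, dq = dq))
}

identity_chain <- function(seq_id = "chr1", len = 1000, q_name = "chrA",
                           chain_id = 1) {
  relic:::new_chain(score = 1000, t_name = seq_id, t_size = len,
                    t_strand = "+", t_start = 0, t_end = len,
                    q_name = q_name, q_size = len, q_strand = "+",
                    q_start = 0, q_end = len, chain_id = chain_id,
                    blocks = data.frame(size = len, dt = 0, dq = 0))
}

# closed-form simple OLS (textbook sums), independent of lm()
bf_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  se <- sqrt(ss_res / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
}

random_intervals <- function(n, seqs, L, len_range = c(5, 80),
                             prefix = "iv") {
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  s <- sapply(len, function(l) sample(0:(L - l), 1))
  genomic_intervals(sample(seqs, n, replace = TRUE), s, s + len,
                    name = sprintf("%s_%03d", prefix, seq_len(n)))
}

make_gene <- function(id, seq_id, start, end, strand = "+",
                      exons = NULL, biotype = "protein_coding") {
  list(gene_id = id,
       interval = genomic_intervals(seq_id, start, end, strand = strand,
                                    name = id),
       tss = if (strand == "+") start else end - 1,
       biotype = biotype,
       exons = if (is.null(exons))
         genomic_intervals(character(0), numeric(0), numeric(0))
       else exons)
}
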