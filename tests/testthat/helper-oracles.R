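# Independent oracles used across the suite. Each transliterates the relevant
# definition step by step, without sharing code with the implementation.

# Unbiased F_ST components from the printed formulas, scalar arithmetic only.
oracle_fst <- function(p, n, denom = c("printed", "classical")) {
  denom <- match.arg(denom)
  p <- unname(p); n <- unname(n)
  s <- length(p)
  ntot <- 0
  for (ni in n) ntot <- ntot + ni
  msg_num <- 0
  for (i in seq_len(s)) msg_num <- msg_num + n[i] * p[i] * (1 - p[i])
  msg <- msg_num / (if (denom == "printed") ntot - 1 else ntot - s)
  pbar_num <- 0
  for (i in seq_len(s)) pbar_num <- pbar_num + n[i] * p[i]
  pbar <- pbar_num / ntot
  msp_num <- 0
  for (i in seq_len(s)) msp_num <- msp_num + n[i] * (p[i] - pbar)^2
  msp <- msp_num / (s - 1)
  sq <- 0
  for (ni in n) sq <- sq + ni^2
  nc <- (ntot - sq / ntot) / (s - 1)
  den <- msp + (nc - 1) * msg
  list(msg = msg, msp = msp, nc = nc, pbar = pbar,
       fst = if (den == 0) NA_real_ else (msp - msg) / den)
}

# Dispersion score from its definition.
oracle_ds <- function(p, n) {
  p <- unname(p)
  pu <- sum(p) / length(p)
  sqrt(sum((p - pu)^2) / sum(n))
}

# AUC by exhaustive pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels > 0]; neg <- scores[labels < 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exact two-sample rank-sum p-value by enumeration of all group assignments.
oracle_ranksum_exact <- function(a, b, alternative = "two.sided") {
  x <- c(a, b); na <- length(a)
  idx <- utils::combn(length(x), na)
  r <- rank(x)
  wobs <- sum(r[seq_len(na)])
  ws <- apply(idx, 2L, function(i) sum(r[i]))
  switch(alternative,
    greater = mean(ws >= wobs),
    less = mean(ws <= wobs),
    two.sided = min(1, 2 * min(mean(ws >= wobs), mean(ws <= wobs))))
}

# One-sided Fisher p as the closed-form hypergeometric upper tail.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; kk <- a + b
  tot <- 0
  for (x in a:min(kk, m))
    tot <- tot + choose(m, x) * choose(nn, kk - x) / choose(m + nn, kk)
  tot
}

# Brute-force interval overlap scan (1-based closed intervals).
oracle_overlaps <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- list()
  for (i in seq_along(q_start)) for (j in seq_along(s_start)) {
    if (q_chrom[i] != s_chrom[j]) next
    lo <- max(q_start[i], s_start[j]); hi <- min(q_end[i], s_end[j])
    if (lo <= hi)
      out[[length(out) + 1L]] <- data.frame(variant = i, interval = j,
                                            overlap_length = hi - lo + 1L)
  }
  if (!length(out)) return(data.frame(variant = integer(), interval = integer(),
                                      overlap_length = integer()))
  do.call(rbind, out)
}
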