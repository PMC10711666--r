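# Independent oracles and small fixture builders used across test files.
# These deliberately take different code paths from the package internals.

# Exhaustive-enumeration Mann-Whitney oracle: U computed by pairwise
# comparison counting, p by enumerating every assignment of the pooled
# values to the first sample.
mwu_enum_oracle <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  u_obs <- u_of(x, y)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Hypergeometric upper tail by explicit combinatorial summation.
hyper_sum_oracle <- function(overlap, set_size, query_size, background) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(background - set_size, query_size - ks)) /
    choose(background, query_size)
}

# Benjamini-Hochberg by the literal step-up definition.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Count 4-connected components of a logical matrix (simple BFS labeling).
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (lab[cur] != 0L || !mask[cur]) next
      lab[cur] <- comp
      r <- (cur - 1L) %% nrow(mask) + 1L
      c <- (cur - 1L) %/% nrow(mask) + 1L
      nb <- c(if (r > 1) cur - 1L, if (r < nrow(mask)) cur + 1L,
              if (c > 1) cur - nrow(mask), if (c < ncol(mask)) cur + nrow(mask))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      queue <- c(queue, nb)
    }
  }
  comp
}

# Brute-force isodata oracle: scan all candidate thresholds for the value
# minimizing |t - intermeans(t)| (extreme bins ignored as in the method).
isodata_scan_oracle <- function(h) {
  h <- as.numeric(h)
  h[c(1, 256)] <- 0
  vals <- 0:255
  occ <- which(h > 0) - 1L
  lo <- min(occ); hi <- max(occ)
  if (lo == hi) return(lo)
  cand <- lo:(hi - 1L)
  score <- vapply(cand, function(t) {
    wb <- h[(lo:t) + 1L]; wa <- h[((t + 1L):hi) + 1L]
    mb <- sum((lo:t) * wb) / sum(wb)
    ma <- sum(((t + 1L):hi) * wa) / sum(wa)
    abs(t - (mb + ma) / 2)
  }, numeric(1))
  cand[which.min(score)]
}

# A small, quick simulation spec shared by several tests.
small_spec <- function(seed = 1L, ...) {
  sc_sim_spec(cells_per_sample = 150, n_genes = 800, seed = seed, ...)
}
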