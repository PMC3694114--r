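# Shared randomization null.
#
# One null stream is drawn per (query length m, seed) and reused across
# every reference set of a query: each draw is an ordered tuple of m
# distinct probes, uniform over the universe. Because the columns of such
# a tuple are exchangeable, scoring every draw with the query's fixed sign
# vector is distributionally identical to assigning the query's multiset
# of signs in random order, so no per-draw sign permutation is needed.

# Deterministic sub-seed per query length so that queries of different
# lengths (e.g. leave-one-out perturbations) never share a stream.
stream_seed <- function(seed, m) {
  as.integer((as.double(seed) + 100003 * as.double(m)) %% .Machine$integer.max)
}

# n draws of m distinct probe indices from 1..npop, as an n x m integer
# matrix. Sampling iid with replacement and redrawing rows that contain a
# duplicate is exact (uniform conditional on distinctness) and fast for
# m << npop.
null_probe_draws <- function(n, m, npop, seed) {
  withr::with_seed(seed, {
    idx <- matrix(sample.int(npop, n * m, replace = TRUE), nrow = n)
    if (m > 1L) {
      repeat {
        bad <- which(apply_has_dup(idx))
        if (!length(bad)) break
        idx[bad, ] <- sample.int(npop, length(bad) * m, replace = TRUE)
      }
    }
    idx
  })
}

# Row-wise duplicate flag, vectorised over all column pairs (m is small).
apply_has_dup <- function(idx) {
  m <- ncol(idx)
  dup <- logical(nrow(idx))
  for (a in seq_len(m - 1L)) {
    for (b in seq.int(a + 1L, m)) {
      dup <- dup | (idx[, a] == idx[, b])
    }
  }
  dup
}

# Count null draws whose |setscore strength| reaches the observed one.
# rbar is the set's mean signed-rank vector in universe order; strengths
# are compared on the unnormalised c scale (sums of exact dyadic rationals,
# so >= is exact). Chunked to bound memory at large n_random.
null_tail_count <- function(idx, signs, rbar, c_abs_obs, chunk = 200000L) {
  n <- nrow(idx)
  m <- ncol(idx)
  total <- 0L
  start <- 1L
  while (start <= n) {
    end <- min(start + chunk - 1L, n)
    g <- rbar[idx[start:end, , drop = FALSE]]
    dim(g) <- c(end - start + 1L, m)
    cs <- abs(drop(g %*% signs))
    total <- total + sum(cs >= c_abs_obs)
    start <- end + 1L
  }
  total
}
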