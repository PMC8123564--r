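# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# Deterministic child seed from a master seed and one or more indices.
# Kept below 2^31 - 1; a small multiplicative hash, not a crypto stream.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483629
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 16807 + 1) %% 2147483629
  }
  as.integer(h)
}

# NaN/NA-aware mean and sd (both treat NaN as missing).
nan_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

nan_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end) indices.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Merge runs (index intervals, inclusive) whose gap is < gap samples.
merge_runs <- function(runs, gap) {
  if (nrow(runs) < 2) return(runs)
  runs <- runs[order(runs$start), , drop = FALSE]
  out_start <- runs$start[1]
  out_end <- runs$end[1]
  starts <- ends <- integer(0)
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out_end - 1 < gap) {
      out_end <- max(out_end, runs$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- runs$start[i]; out_end <- runs$end[i]
    }
  }
  starts <- c(starts, out_start); ends <- c(ends, out_end)
  data.frame(start = starts, end = ends)
}

# 32-bit modular multiply, exact in doubles (splits a into 16-bit halves).
mul32 <- function(a, b) {
  a_lo <- a %% 65536
  a_hi <- (a - a_lo) / 65536
  (a_lo * b + ((a_hi * b) %% 65536) * 65536) %% 4294967296
}

# 32-bit FNV-1a hash of a character vector, returned as 8 hex digits.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256 # xor touches only the low byte; h itself exceeds int range
    h <- mul32(h - lo + bitwXor(as.integer(lo), as.integer(b)), 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
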