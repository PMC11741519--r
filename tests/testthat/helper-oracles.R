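# Independent brute-force recomputations used as oracles. These deliberately
# avoid the package's own numeric helpers (and, where feasible, base R's
# specialized routines) so that agreement is informative.

# Trapezoid quadrature from first principles.
oracleTrapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Rate at time t = 1/ISI of the interval containing t, by direct scan.
oracleIsiRate <- function(spikes, t) {
  if (length(spikes) < 2) return(0)
  for (k in seq_len(length(spikes) - 1)) {
    if (t >= spikes[k] && t < spikes[k + 1])
      return(1 / (spikes[k + 1] - spikes[k]))
  }
  0
}

# Running median with window clipped at the edges. Interior samples (at least
# half a window away from either end) match any endpoint convention.
oracleRunningMedian <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Two-key population sort by explicit pairwise comparison.
oracleSortPopulation <- function(tab, thr = 8) {
  excit <- !is.na(tab$peak_change) & tab$peak_change > thr
  key <- ifelse(excit, tab$half_width, tab$pause_duration)
  key[is.na(key)] <- Inf
  grp <- ifelse(excit, 0, 1)
  n <- nrow(tab)
  idx <- seq_len(n)
  # selection sort with the documented comparison (group, key, cell_id)
  lessThan <- function(i, j) {
    if (grp[i] != grp[j]) return(grp[i] < grp[j])
    if (key[i] != key[j]) return(key[i] < key[j])
    tab$cell_id[i] < tab$cell_id[j]
  }
  for (a in seq_len(n - 1)) {
    m <- a
    for (b in (a + 1):n) if (lessThan(idx[b], idx[m])) m <- b
    tmp <- idx[a]; idx[a] <- idx[m]; idx[m] <- tmp
  }
  idx
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all sign assignments
# (valid for untied |differences|; zeros must be dropped by the caller).
oracleWilcoxonExact <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  vAll <- vapply(seq_len(2^n) - 1, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  # two-sided: probability of a statistic at least as extreme as observed
  mean(abs(vAll - mu) >= abs(vObs - mu) - 1e-12)
}

# Spearman rho as Pearson correlation of average ranks, from first
# principles.
oracleSpearmanRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# A deterministic noiseless model cell plus the standard categorization burst,
# shared by several tests.
referenceBurst <- function(n = 20, rate = 100, t0 = 1) {
  makeBurstPattern(n, rate, t0 = t0)
}
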