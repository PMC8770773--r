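# Independent brute-force oracles, written with naive loops and kept free of
# the package's internal code paths.

# --- SCR pipeline oracle -----------------------------------------------------

# least-squares line fit by the closed-form normal equations
oracle_detrend_keep_mean <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  tbar <- mean(t)
  beta <- sum((t - tbar) * (x - mean(x))) / sum((t - tbar)^2)
  alpha <- mean(x) - beta * tbar
  resid <- numeric(n)
  for (i in seq_len(n)) resid[i] <- x[i] - (alpha + beta * i)
  resid + mean(x)
}

# median over the even window [i-25, i+24] with half-sample reflection
oracle_median_filter_50 <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- numeric(50)
    k <- 0
    for (off in -25:24) {
      j <- i + off
      if (j < 1) j <- 1 - j          # reflect: 0 -> 1, -1 -> 2, ...
      if (j > n) j <- 2 * n + 1 - j  # reflect: n+1 -> n, n+2 -> n-1, ...
      if (j < 1) j <- 1
      if (j > n) j <- n
      k <- k + 1
      win[k] <- x[j]
    }
    s <- sort(win)
    out[i] <- (s[25] + s[26]) / 2
  }
  out
}

# full per-run recomputation from the raw 1 kHz samples: detrend, filter,
# decimate, epoch, baseline, trough-to-peak score. Returns one peak per onset.
oracle_scr_peaks <- function(samples_1k, onsets_1k) {
  x <- oracle_median_filter_50(oracle_detrend_keep_mean(samples_1k))
  x100 <- x[seq(1, length(x), by = 10)]
  peaks <- numeric(length(onsets_1k))
  for (k in seq_along(onsets_1k)) {
    o <- (onsets_1k[k] - 1) %/% 10 + 1
    if (o - 100 < 1 || o + 800 > length(x100)) {
      peaks[k] <- NA_real_
      next
    }
    epoch <- x100[(o - 100):(o + 800)]
    epoch <- epoch - mean(epoch[1:100])
    p <- max(epoch[201:901]) - min(epoch[101:200])
    peaks[k] <- if (p < 0.02) 0 else p
  }
  peaks
}

# --- feature ranking oracle --------------------------------------------------

# voxelwise class-mean difference and top-K ranking with naive loops
oracle_rank_features <- function(X, y, K) {
  p <- ncol(X)
  score <- numeric(p)
  for (v in seq_len(p)) {
    score[v] <- mean(X[y == "CSplus", v]) - mean(X[y == "CSminus", v])
  }
  remaining <- seq_len(p)
  picked <- integer(0)
  while (length(picked) < K) {
    best <- remaining[1]
    for (v in remaining) {
      if (score[v] > score[best] || (score[v] == score[best] && v < best)) best <- v
    }
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
  }
  picked
}

# --- repeated-measures ANOVA oracle ------------------------------------------

# spreadsheet-style sums-of-squares decomposition for a 2x2 within design;
# `tab` has columns pid, A, B, y with one row per cell
oracle_rm_anova_2x2 <- function(tab) {
  pids <- sort(unique(tab$pid))
  As <- sort(unique(tab$A))
  Bs <- sort(unique(tab$B))
  n <- length(pids)
  cell <- function(p, a, b) tab$y[tab$pid == p & tab$A == a & tab$B == b]
  grand <- mean(tab$y)
  m_p <- sapply(pids, function(p) mean(tab$y[tab$pid == p]))
  m_a <- sapply(As, function(a) mean(tab$y[tab$A == a]))
  m_b <- sapply(Bs, function(b) mean(tab$y[tab$B == b]))
  m_ab <- outer(As, Bs, Vectorize(function(a, b) mean(tab$y[tab$A == a & tab$B == b])))
  m_pa <- outer(pids, As, Vectorize(function(p, a) mean(tab$y[tab$pid == p & tab$A == a])))
  m_pb <- outer(pids, Bs, Vectorize(function(p, b) mean(tab$y[tab$pid == p & tab$B == b])))

  ss_s <- 4 * sum((m_p - grand)^2)      # each participant mean covers 4 cells
  ss_a <- 2 * n * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
  ss_as <- 2 * sum((m_pa - outer(m_p, m_a, "+") + grand)^2)
  ss_bs <- 2 * sum((m_pb - outer(m_p, m_b, "+") + grand)^2)
  ss_tot <- sum((tab$y - grand)^2)
  ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs

  dfe <- n - 1
  f_a <- (ss_a / 1) / (ss_as / dfe)
  f_b <- (ss_b / 1) / (ss_bs / dfe)
  f_ab <- (ss_ab / 1) / (ss_abs / dfe)
  denom_err <- ss_s + ss_as + ss_bs + ss_abs
  list(
    F = c(A = f_a, B = f_b, AB = f_ab),
    p = c(A = pf(f_a, 1, dfe, lower.tail = FALSE),
          B = pf(f_b, 1, dfe, lower.tail = FALSE),
          AB = pf(f_ab, 1, dfe, lower.tail = FALSE)),
    eta_G = c(A = ss_a / (ss_a + denom_err),
              B = ss_b / (ss_b + denom_err),
              AB = ss_ab / (ss_ab + denom_err))
  )
}
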