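# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package's own algorithms.

# flood-fill connected-component labelling (stack-based, O(n * k))
oracle_label <- function(mask, connectivity = 8) {
  mk <- mask != 0
  n <- nrow(mk); p <- ncol(mk)
  lab <- matrix(0L, n, p)
  offs <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  cur <- 0L
  for (j in seq_len(p)) for (i in seq_len(n)) {
    if (mk[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j)); lab[i, j] <- cur
      while (length(stack)) {
        q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(offs))) {
          ii <- q[1] + offs[k, 1]; jj <- q[2] + offs[k, 2]
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= p &&
              mk[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# do two labelings define the same partition of the foreground?
same_partition <- function(a, b) {
  fa <- a > 0; fb <- b > 0
  if (!identical(fa, fb)) return(FALSE)
  key <- paste(a[fa], b[fb])
  length(unique(key)) == length(unique(a[fa])) &&
    length(unique(key)) == length(unique(b[fb]))
}

# exhaustive-threshold Otsu: maximize between-class variance over all cut
# points between sorted distinct values (single threshold)
oracle_otsu1 <- function(v) {
  u <- sort(unique(v))
  best <- -Inf; best_t <- NA
  for (t in u[-length(u)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    w1 <- length(lo) / length(v); w2 <- 1 - w1
    bc <- w1 * w2 * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; best_t <- t }
  }
  best_t
}

# exhaustive two-threshold Otsu (maximize sum w_k mu_k^2)
oracle_otsu2 <- function(v) {
  u <- sort(unique(v))
  best <- -Inf; best_t <- c(NA, NA)
  cuts <- u[-length(u)]
  for (a in seq_along(cuts)) for (b in seq_along(cuts)) {
    if (b <= a) next
    t1 <- cuts[a]; t2 <- cuts[b]
    g <- list(v[v <= t1], v[v > t1 & v <= t2], v[v > t2])
    sc <- sum(vapply(g, function(x)
      if (length(x)) length(x) / length(v) * mean(x)^2 else 0, numeric(1)))
    if (sc > best) { best <- sc; best_t <- c(t1, t2) }
  }
  best_t
}

# direct O(n^2 k^2) 2D convolution (true convolution: the kernel is flipped
# relative to correlation) with symmetric padding
oracle_convolve <- function(m, k) {
  kr <- (nrow(k) - 1) / 2; kc <- (ncol(k) - 1) / 2
  n <- nrow(m); p <- ncol(m)
  ridx <- function(i) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n + 1 - i, i) }
  cidx <- function(j) { j <- ifelse(j < 1, 1 - j, j); ifelse(j > p, 2 * p + 1 - j, j) }
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    acc <- 0
    for (di in -kr:kr) for (dj in -kc:kc)
      acc <- acc + m[ridx(i - di), cidx(j - dj)] * k[di + kr + 1, dj + kc + 1]
    out[i, j] <- acc
  }
  out
}

# per-pixel sorted-neighbourhood median with symmetric padding
oracle_median <- function(m, size = 5) {
  r <- (size - 1) / 2
  n <- nrow(m); p <- ncol(m)
  ridx <- function(i) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n + 1 - i, i) }
  cidx <- function(j) { j <- ifelse(j < 1, 1 - j, j); ifelse(j > p, 2 * p + 1 - j, j) }
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, m[ridx(i + di), cidx(j + dj)])
    out[i, j] <- median(vals)
  }
  out
}

# hand-expanded sums-of-squares for one-way within-subject ANOVA
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_t <- 0
  for (j in seq_len(k)) ss_t <- ss_t + n * (mean(m[, j]) - grand)^2
  ss_s <- 0
  for (i in seq_len(n)) ss_s <- ss_s + k * (mean(m[i, ]) - grand)^2
  ss_tot <- sum((m - grand)^2)
  ss_e <- ss_tot - ss_t - ss_s
  Fv <- (ss_t / (k - 1)) / (ss_e / ((k - 1) * (n - 1)))
  list(F = Fv, p = pf(Fv, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# brute-force sup |ECDF - CDF| over both sides of every jump point
oracle_ks_D <- function(x) {
  x <- sort(x)
  n <- length(x)
  cdf <- pnorm(x, mean(x), sd(x))
  sup <- 0
  for (i in seq_len(n)) {
    sup <- max(sup, abs(i / n - cdf[i]), abs((i - 1) / n - cdf[i]))
  }
  sup
}
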