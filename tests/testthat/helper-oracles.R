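# Independent oracles used to validate the package's implementations.
# These deliberately use naive algorithms (linear-scan Dijkstra, exhaustive
# threshold search, per-pixel sorting) and share no code with the package.

# Dijkstra with axial cost 1, diagonal cost sqrt(2), restricted to `region`.
# Linear-scan extraction; fine for the <= 32x32 grids used in tests.
oracle_dijkstra <- function(region, sources) {
  H <- nrow(region); W <- ncol(region)
  dist <- matrix(Inf, H, W)
  done <- matrix(FALSE, H, W)
  dist[sources & region] <- 0
  nb <- expand.grid(dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dy == 0 & nb$dx == 0), ]
  repeat {
    d <- dist
    d[done | !region] <- Inf
    if (all(is.infinite(d))) break
    k <- which.min(d)
    i <- (k - 1) %% H + 1
    j <- (k - 1) %/% H + 1
    done[i, j] <- TRUE
    for (m in seq_len(nrow(nb))) {
      ni <- i + nb$dy[m]; nj <- j + nb$dx[m]
      if (ni < 1 || ni > H || nj < 1 || nj > W) next
      if (!region[ni, nj]) next
      step <- if (nb$dy[m] != 0 && nb$dx[m] != 0) sqrt(2) else 1
      if (dist[i, j] + step < dist[ni, nj]) dist[ni, nj] <- dist[i, j] + step
    }
  }
  dist[!region] <- NA_real_
  dist[is.infinite(dist)] <- NA_real_
  dist
}

# Exhaustive Otsu: try every unique value as the cut `x < t` vs `x >= t`,
# recomputing class weights and means directly from the raw pixels.
oracle_otsu <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  u <- sort(unique(v))
  best_t <- NA_real_; best_bcv <- -Inf
  for (t in u[-1]) {
    lo <- v[v < t]; hi <- v[v >= t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv + 1e-15) {  # strict improvement => lowest tie wins
      best_bcv <- bcv; best_t <- t
    }
  }
  best_t
}

# Per-pixel median by explicit sort-and-middle.
oracle_stack_median <- function(frames) {
  arr <- simplify2array(frames)
  apply(arr, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) return(NA_real_)
    s <- sort(v)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  })
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
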