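## Independent oracles used across tests. Each is a brute-force or
## closed-form reimplementation, deliberately kept separate from the package
## code paths it checks.

## closed-form OLS line fit (slope, intercept)
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = b, intercept = mean(y) - b * mean(x))
}

## broken-stick intersection from two independent OLS fits
oracle_tg <- function(T, V, low, high) {
  li <- T >= low[1] & T <= low[2]
  hi <- T >= high[1] & T <= high[2]
  fl <- oracle_ols(T[li], V[li])
  fh <- oracle_ols(T[hi], V[hi])
  unname((fl["intercept"] - fh["intercept"]) / (fh["slope"] - fl["slope"]))
}

## naive O(n^2) multi-origin MSD of one scalar coordinate
oracle_msd_1d <- function(x) {
  N <- length(x)
  vapply(0:(N - 1L), function(m) {
    if (m == 0L) return(0)
    mean((x[(1 + m):N] - x[1:(N - m)])^2)
  }, numeric(1))
}

## Monte-Carlo probe-insertion free volume (minimum image), chunked
oracle_fv_mc <- function(frame, probe, radii, n_samples = 1e5, seed = 99) {
  set.seed(seed)
  pos <- frame_positions(frame)
  R <- radii[frame$atoms$element] + probe
  box <- frame$box
  free <- 0L
  done <- 0L
  while (done < n_samples) {
    nb <- min(20000L, n_samples - done)
    pts <- cbind(runif(nb) * box[1], runif(nb) * box[2], runif(nb) * box[3])
    ok <- rep(TRUE, nb)
    for (i in seq_len(nrow(pos))) {
      d <- sweep(pts, 2L, pos[i, ])
      for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
      ok <- ok & (rowSums(d^2) > R[i]^2)
    }
    free <- free + sum(ok)
    done <- done + nb
  }
  free / n_samples
}

## brute-force reflect-and-average smoother (direct transcription of the
## definition, no shared code with smooth_reflect)
oracle_smooth <- function(eps, sig, h) {
  xs <- c(-rev(eps[eps > 0]), eps)
  ys <- c(-rev(sig[eps > 0]), ifelse(eps == 0, 0, sig))
  vapply(eps, function(e) {
    he <- min(h, max(eps) - e)
    mean(ys[xs >= e - he - 1e-12 & xs <= e + he + 1e-12])
  }, numeric(1))
}

## bisection root of f on [lo, hi]
oracle_bisect <- function(f, lo, hi, tol = 1e-10) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

## minimal valid GRO text for fixtures (fixed-width fields)
gro_lines <- function() {
  at <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                c(1L, 1L, 2L), c("SOL", "SOL", "POL"),
                c("OW", "HW1", "O6"), 1:3,
                c(0.5, 0.57, 0.8), c(0.5, 0.57, 0.5), c(0.5, 0.5, 0.5))
  c("three waters-ish atoms", "    3", at,
    "   2.00000   2.00000   2.00000")
}
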