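# Independent reference implementations used as oracles. These deliberately
# share no code with the package: dense 2-D convolution with its own
# reflection indexing, and a label-permutation enumeration for the exact
# Kruskal-Wallis p-value.

# Dense difference-of-Gaussians by explicit kernel summation.
oracle_dog <- function(m, sigma_low = 0.5, sigma_high = 8) {
  kern1d <- function(s) {
    r <- ceiling(4 * s)
    w <- exp(-(-r:r)^2 / (2 * s^2))
    w / sum(w)
  }
  k1 <- kern1d(sigma_low)
  k2 <- kern1d(sigma_high)
  z <- (length(k2) - length(k1)) / 2
  k1p <- c(rep(0, z), k1, rep(0, z))
  kd <- k1p %o% k1p - k2 %o% k2
  p <- (length(k2) - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    rows <- refl(r + (-p:p), nr)
    for (cc in seq_len(nc)) {
      cols <- refl(cc + (-p:p), nc)
      out[r, cc] <- sum(kd * m[rows, cols])
    }
  }
  out
}

# Exact Kruskal-Wallis p by enumerating every assignment of the pooled values
# to two groups (first `n1` indices of each combination form group 1).
oracle_kw_exact_2g <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  h_of <- function(ix) {
    g1 <- pooled[ix]; g2 <- pooled[-ix]
    r <- rank(c(g1, g2))
    nn <- length(r)
    rb1 <- mean(r[seq_along(g1)]); rb2 <- mean(r[-seq_along(g1)])
    h <- 12 / (nn * (nn + 1)) *
      (length(g1) * (rb1 - (nn + 1) / 2)^2 + length(g2) * (rb2 - (nn + 1) / 2)^2)
    tt <- table(c(g1, g2))
    h / (1 - sum(tt^3 - tt) / (nn^3 - nn))
  }
  h_obs <- h_of(seq_len(n1))
  combos <- utils::combn(n, n1, simplify = FALSE)
  mean(vapply(combos, h_of, numeric(1)) >= h_obs - 1e-12)
}

# Dark disk of the given radius centred in a bright square frame.
make_disk_image <- function(radius, bg = 200, n = 201, disk = 0) {
  cr <- (n - 1) / 2
  rr <- row(matrix(0, n, n)) - 1
  cc <- col(matrix(0, n, n)) - 1
  m <- matrix(bg, n, n)
  m[sqrt((rr - cr)^2 + (cc - cr)^2) <= radius] <- disk
  calibrated_image(m, pitch_um = 1)
}

# Ring-calibrated papilla phantom for vessel-size checks: the bright ring
# puts the 20% relative threshold at the half-height of the lumen edge.
ring_calibrated_phantom <- function(radius, ...) {
  make_papilla_phantom(lumen_radius_px = radius,
                       papilla_outer_radius_px = max(45, radius + 15),
                       ring_outer_radius_px = max(60, radius + 30),
                       intensities = c(0, 0.4, 1, 0.5), ...)
}
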