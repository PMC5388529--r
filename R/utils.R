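# Internal numeric helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards so seeded generators do not disturb user RNG flow.
.withSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("a finite integer seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trapezoidal integral of y over x.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Trapezoidal integral of the piecewise-linear interpolant of (x, y)
# restricted to [a, b]; interval endpoints falling between samples are
# resolved by linear interpolation so compartment boundaries need not sit
# on the grid.
.trapzInterval <- function(x, y, a, b) {
  a <- max(a, x[1]); b <- min(b, x[length(x)])
  if (b <= a) return(0)
  inside <- x > a & x < b
  xs <- c(a, x[inside], b)
  ys <- c(stats::approx(x, y, xout = a)$y, y[inside],
          stats::approx(x, y, xout = b)$y)
  .trapz(xs, ys)
}

# Gaussian smoothing of a uniformly sampled signal; sigma in the same units
# as the sample spacing `dx`. Kernel truncated at 4 sigma, edge-renormalized.
.gaussSmooth <- function(v, sigma, dx) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(4 * sigma / dx))
  k <- stats::dnorm(seq(-r, r) * dx, sd = sigma)
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- k[j - i + r + 1L]
    out[i] <- sum(v[j] * w) / sum(w)
  }
  out
}

# Shoelace signed area (pixel^2) of a closed polygon given as an n x 2 matrix.
.shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Proper segment-pair intersection test for polygon simplicity checking.
# Adjacent edges (sharing a vertex) are allowed to touch at the shared vertex.
.selfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1 else i + 1, ])
  orient <- function(p, q, r) {
    d <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    if (abs(d) < 1e-12) 0 else sign(d)
  }
  onSeg <- function(p, q, r) {
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
      min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  crosses <- function(a, b) {
    o1 <- orient(a[1, ], a[2, ], b[1, ]); o2 <- orient(a[1, ], a[2, ], b[2, ])
    o3 <- orient(b[1, ], b[2, ], a[1, ]); o4 <- orient(b[1, ], b[2, ], a[2, ])
    if (o1 != o2 && o3 != o4) return(TRUE)
    (o1 == 0 && onSeg(a[1, ], a[2, ], b[1, ])) ||
      (o2 == 0 && onSeg(a[1, ], a[2, ], b[2, ])) ||
      (o3 == 0 && onSeg(b[1, ], b[2, ], a[1, ])) ||
      (o4 == 0 && onSeg(b[1, ], b[2, ], a[2, ]))
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) next
      if (crosses(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# md5 of an arbitrary R object via its serialization (used for config hashes
# in run provenance logs).
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# Vectorized two-sided Welch t-test summaries from group summaries.
# Inputs are vectors (one entry per position/variable).
.welchFromSummaries <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zeroVar <- is.finite(m1) & is.finite(m2) & se2 == 0
  p[zeroVar & m1 != m2] <- .Machine$double.xmin
  t[zeroVar & m1 != m2] <- sign(m1 - m2)[zeroVar & m1 != m2] * Inf
  p[zeroVar & m1 == m2] <- 1
  t[zeroVar & m1 == m2] <- 0
  df[zeroVar] <- n1[zeroVar] + n2[zeroVar] - 2
  list(t = t, df = df, p = p, zeroVariance = zeroVar)
}
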