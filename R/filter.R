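# Digital Chebyshev Type II low-pass design and zero-phase application.
# No IIR-design package ships in this stack, so the standard zpk route is
# implemented here: analog inverse-Chebyshev prototype -> low-pass frequency
# transform -> bilinear transform -> polynomial transfer function, applied
# forward-backward with odd-extension padding (Gustafsson-style initial
# conditions) for zero phase.

# Analog inverse-Chebyshev (Type II) low-pass prototype with unit stopband
# edge. Returns zeros z, poles p (complex) and gain k with |H(0)| = 1.
cheb2_prototype <- function(order, stop_atten_db) {
  de <- 1 / sqrt(10^(0.1 * stop_atten_db) - 1)
  mu <- asinh(1 / de) / order
  if (order %% 2) {
    m <- c(seq(-order + 1, -1, by = 2), seq(2, order - 1, by = 2))
  } else {
    m <- seq(-order + 1, order - 1, by = 2)
  }
  z <- -Conj(1i / sin(m * pi / (2 * order)))
  ang <- pi * seq(-order + 1, order - 1, by = 2) / (2 * order)
  p <- -exp(1i * ang)
  p <- complex(real = sinh(mu) * Re(p), imaginary = cosh(mu) * Im(p))
  p <- 1 / p
  k <- Re(prod(-p) / prod(-z))
  list(z = z, p = p, k = k)
}

# zpk low-pass frequency scaling and bilinear transform (fs = 2 convention,
# cutoff as a fraction of Nyquist), then conversion to b, a polynomials.
cheby2_lowpass <- function(order, stop_atten_db, w_frac) {
  check_scalar(order, "order", lower = 1)
  check_scalar(stop_atten_db, "stop_atten_db", lower = 0, allow_equal_lower = FALSE)
  check_scalar(w_frac, "cutoff", lower = 0, upper = 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  proto <- cheb2_prototype(order, stop_atten_db)
  fs <- 2
  warped <- 2 * fs * tan(pi * w_frac / fs)
  z <- proto$z * warped
  p <- proto$p * warped
  k <- proto$k * warped^(length(p) - length(z))
  # bilinear transform
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  poly_from_roots <- function(r) {
    coef <- 1 + 0i
    for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
    coef
  }
  b <- Re(kd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Direct-form II transposed IIR filter with initial conditions.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      for (j in 1:(n - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  list(y = y, z = z)
}

# Steady-state initial conditions for a unit-step input (Gustafsson).
iir_filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1) return(numeric(0))
  comp <- cbind(rbind(diag(1, n - 2), rep(0, n - 2)))
  if (n == 2) comp <- matrix(0, 1, 0)
  zin <- diag(1, n - 1) - cbind(-a[2:n], comp)
  zid <- b[2:n] - a[2:n] * b[1]
  as.numeric(solve(zin, zid))
}

# Zero-phase forward-backward filtering with odd-extension padding.
filtfilt_fb <- function(b, a, x) {
  padlen <- 3 * max(length(a), length(b))
  if (length(x) <= padlen)
    stop_invalid("x", sprintf("series too short to filter (need > %d points)", padlen))
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  zi <- iir_filter_zi(b, a)
  fwd <- iir_filter(b, a, ext, zi * ext[1])$y
  rev1 <- rev(fwd)
  bwd <- iir_filter(b, a, rev1, zi * rev1[1])$y
  y <- rev(bwd)
  y[(padlen + 1):(padlen + length(x))]
}
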