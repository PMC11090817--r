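## Vectorised bivariate standard normal CDF and Gaussian-copula calibration.
##
## The synthetic community generator plants a target co-occurrence for every
## OTU pair by solving, per pair, for the latent Gaussian correlation that
## yields a prescribed joint presence probability.  That requires ~1e6
## evaluations of the bivariate normal CDF inside a vectorised bisection, so
## a vectorised implementation of the Drezner-Wesolowsky/Genz quadrature
## algorithm is used (accuracy ~1e-14; unit-tested against mvtnorm).

.gl20 <- local({
  ## 20-point Gauss-Legendre nodes/weights on [-1, 1]
  x <- c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
         0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
         0.5108670019508271, 0.3737060887154195, 0.2277858511416451,
         0.0765265211334973)
  w <- c(0.0176140071391521, 0.0406014298003869, 0.0626720483341091,
         0.0832767415767048, 0.1019301198172404, 0.1181945319615184,
         0.1316886384491766, 0.1420961093183820, 0.1491729864726037,
         0.1527533871307258)
  list(x = c(-x, x), w = c(w, w))
})

## P(X > h, Y > k) for standard bivariate normal with correlation r.
## Vectorised over h, k, r (recycled to common length).
bvn_upper <- function(h, k, r) {
  n <- max(length(h), length(k), length(r))
  h <- rep_len(h, n); k <- rep_len(k, n); r <- rep_len(r, n)
  out <- numeric(n)

  ## exact degenerate correlations
  m <- r >= 1
  if (any(m)) out[m] <- stats::pnorm(-pmax(h[m], k[m]))
  m <- r <= -1
  if (any(m)) out[m] <- pmax(0, stats::pnorm(-h[m]) - stats::pnorm(k[m]))

  gl <- .gl20

  ## moderate correlation: quadrature on sin-transformed Drezner integral
  m1 <- abs(r) < 0.925
  if (any(m1)) {
    hh <- h[m1]; kk <- k[m1]; rr <- r[m1]
    hk <- hh * kk
    hs <- (hh * hh + kk * kk) / 2
    asr <- asin(rr)
    bvn <- 0
    for (i in seq_along(gl$x)) {
      sn <- sin(asr * (1 + gl$x[i]) / 2)
      bvn <- bvn + gl$w[i] * exp((sn * hk - hs) / (1 - sn * sn))
    }
    out[m1] <- bvn * asr / (4 * pi) + stats::pnorm(-hh) * stats::pnorm(-kk)
  }

  ## high |correlation|: Genz's asymptotic-corrected quadrature
  m2 <- abs(r) >= 0.925 & abs(r) < 1
  if (any(m2)) {
    hh <- h[m2]; kk <- k[m2]; rr <- r[m2]
    neg <- rr < 0
    kk[neg] <- -kk[neg]
    hk <- hh * kk
    as_ <- (1 - rr) * (1 + rr)
    a <- sqrt(as_)
    bs <- (hh - kk)^2
    cc <- (4 - hk) / 8
    dd <- (12 - hk) / 16
    asr0 <- -(bs / as_ + hk) / 2
    bvn <- ifelse(asr0 > -100,
                  a * exp(asr0) *
                    (1 - cc * (bs - as_) * (1 - dd * bs / 5) / 3 +
                       cc * dd * as_ * as_ / 5),
                  0)
    ok <- -hk < 100
    if (any(ok)) {
      b <- sqrt(bs[ok])
      sp <- sqrt(2 * pi) * stats::pnorm(-b / a[ok])
      bvn[ok] <- bvn[ok] - exp(-hk[ok] / 2) * sp * b *
        (1 - cc[ok] * bs[ok] * (1 - dd[ok] * bs[ok] / 5) / 3)
    }
    ah <- a / 2
    acc <- numeric(length(hh))
    for (i in seq_along(gl$x)) {
      xs <- (ah * (1 + gl$x[i]))^2
      rs <- sqrt(1 - xs)
      asr1 <- -(bs / xs + hk) / 2
      keep <- asr1 > -100
      if (any(keep)) {
        term <- ah[keep] * gl$w[i] * exp(asr1[keep]) *
          (exp(-hk[keep] * (1 - rs[keep]) / (2 * (1 + rs[keep]))) / rs[keep] -
             (1 + cc[keep] * xs[keep] * (1 + dd[keep] * xs[keep])))
        acc[keep] <- acc[keep] + term
      }
    }
    bvn <- -(bvn + acc) / (2 * pi)
    pos <- !neg
    bvn[pos] <- bvn[pos] + stats::pnorm(-pmax(hh[pos], kk[pos]))
    if (any(neg)) {
      bvn[neg] <- -bvn[neg]
      adj <- neg & (kk > hh)
      bvn[adj] <- bvn[adj] + stats::pnorm(kk[adj]) - stats::pnorm(hh[adj])
    }
    out[m2] <- bvn
  }
  pmin(pmax(out, 0), 1)
}

## P(X <= h, Y <= k), vectorised
pbvnorm <- function(h, k, r) bvn_upper(-h, -k, r)

## Solve pbvnorm(za, zb, rho) = joint for rho by vectorised bisection.
## joint is clamped inside the Frechet bounds implied by the marginals.
calibrate_latent_rho <- function(joint, pa, pb, iterations = 60) {
  lower_b <- pmax(0, pa + pb - 1)
  upper_b <- pmin(pa, pb)
  eps <- 1e-6
  joint <- pmin(pmax(joint, lower_b + eps * (upper_b - lower_b)),
                upper_b - eps * (upper_b - lower_b))
  za <- stats::qnorm(pa)
  zb <- stats::qnorm(pb)
  lo <- rep_len(-0.9999, length(joint))
  hi <- rep_len(0.9999, length(joint))
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    f <- pbvnorm(za, zb, mid)
    too_low <- f < joint   # CDF increasing in rho
    lo[too_low] <- mid[too_low]
    hi[!too_low] <- mid[!too_low]
  }
  (lo + hi) / 2
}

## Project a symmetric matrix onto the PSD cone and renormalise to unit
## diagonal (eigenvalue clipping; adequate for simulation covariances).
nearest_correlation <- function(R, min_eig = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, min_eig)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out
}

## Fit rho(d): nonnegative mixture of exponential kernels exp(-theta * d)
## (the covariance family of Ornstein-Uhlenbeck processes on the tree, PSD
## on tree metrics), approximating per-pair target correlations as a
## function of patristic distance.  Returns the fitted per-pair values; the
## implied full matrix is PSD by construction, so no eigenvalue clipping is
## needed and the planted co-occurrence curve is not distorted.
fit_monotone_psd_rho <- function(d, rho_target,
                                 thetas = c(0, 2^seq(-3, 5, by = 0.5))) {
  A <- exp(-outer(d, thetas))
  w <- pracma::lsqnonneg(A, rho_target)$x
  f0 <- sum(w)                       # fitted value at distance 0
  if (f0 > 0.999) w <- w * (0.999 / f0)
  list(weights = w, thetas = thetas,
       fitted = as.vector(A %*% w),
       predict = function(dd) as.vector(exp(-outer(dd, thetas)) %*% w))
}
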