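# Bessel J0 for complex argument, needed for the oscillatory pipe-flow
# profile (argument i^{3/2} * Wo * xi). Base R's besselJ is real-only, so the
# two standard representations are combined: the ascending power series for
# moderate |z| and the Hankel asymptotic expansion beyond.

#' @keywords internal
.besselJ0_complex <- function(z) {
  z <- as.complex(z)
  out <- complex(length(z))
  small <- Mod(z) <= 12
  if (any(small)) {
    zs <- z[small]
    q <- -zs * zs / 4
    term <- rep(1 + 0i, length(zs))
    s <- term
    for (k in 1:45) {
      term <- term * q / (k * k)
      s <- s + term
    }
    out[small] <- s
  }
  if (any(!small)) {
    zl <- z[!small]
    # Hankel coefficients a_k = prod(-(2j-1)^2)/(k! 8^k) for nu = 0
    a1 <- -1 / 8
    a2 <- 9 / 128
    a3 <- -75 / 1024
    a4 <- 11025 / 98304
    a5 <- -893025 / 3932160
    iz2 <- 1 / (zl * zl)
    P <- 1 - a2 * iz2 + a4 * iz2 * iz2
    Q <- a1 / zl - a3 / zl^3 + a5 / zl^5
    w <- zl - pi / 4
    out[!small] <- sqrt(2 / (pi * zl)) * (P * cos(w) - Q * sin(w))
  }
  out
}
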