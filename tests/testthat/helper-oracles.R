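# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# bound-complex concentration by bisection on B^2 - (P+L+Kd)B + PL = 0,
# iterated to the machine-precision bracket (relative stopping rule)
bisect_bound <- function(kd, p, l) {
  if (p == 0 || l == 0) return(0)
  f <- function(b) b^2 - (p + l + kd) * b + p * l
  lo <- 0; hi <- min(p, l)
  if (f(hi) == 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break   # bracket exhausted in doubles
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exhaustive Costes scan: same acceptance rule, no early exit, all candidates
costes_bruteforce <- function(red, green, equal = FALSE) {
  r <- as.vector(red); g <- as.vector(green)
  sxx <- var(r); syy <- var(g); sxy <- cov(r, g)
  b <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  a <- mean(g) - b * mean(r)
  pear <- function(x, y) {
    mx <- mean(x); my <- mean(y); n <- length(x)
    sx <- sqrt(sum((x - mx)^2) / n); sy <- sqrt(sum((y - my)^2) / n)
    if (sx == 0 || sy == 0) return(NA_real_)
    sum((x - mx) * (y - my)) / (n * sx * sy)
  }
  best <- NA_real_
  for (t in sort(unique(r))) {
    tg <- if (equal) t else a + b * t
    below <- r < t & g < tg
    if (sum(below) < 2) next
    rho <- pear(r[below], g[below])
    if (!is.na(rho) && rho <= 0 && (is.na(best) || t > best)) best <- t
  }
  if (is.na(best)) best <- min(r)
  best
}

# closed-form area of a Gaussian band over [lo, hi]
gauss_area <- function(amp, center, width, lo, hi) {
  amp * width * sqrt(2 * pi) *
    (pnorm((hi - center) / width) - pnorm((lo - center) / width))
}
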