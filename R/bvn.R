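# Bivariate standard normal orthant probabilities.
#
# The tetrachoric and liability-threshold machinery needs upper-orthant
# masses P(X > h, Y > k) at thresholds around 2-3, where the mass is of
# order 1e-4 and naive Monte Carlo is useless.  We use the Gauss-Legendre
# quadrature scheme of Genz (1994, "Numerical computation of rectangular
# bivariate and trivariate normal and t probabilities"), which is accurate
# to ~1e-15 and is the algorithm behind the standard Fortran BVND routine.

# Gauss-Legendre nodes/weights on (0,1), selected by |rho|.
.gl_rules <- list(
  n6 = list(
    w = c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904),
    x = c(0.9324695142031522, 0.6612093864662647, 0.2386191860831970)),
  n12 = list(
    w = c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
          0.2031674267230659, 0.2334925365383547, 0.2491470458134029),
    x = c(0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
          0.5873179542866171, 0.3678314989981802, 0.1252334085114692)),
  n20 = list(
    w = c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
          0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
          0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
          0.1527533871307259),
    x = c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
          0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
          0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
          0.07652652113349733))
)

# Scalar Genz BVND: P(X > dh, Y > dk) for standard bivariate normal.
.bvnu_scalar <- function(dh, dk, r) {
  if (is.infinite(dh) && dh > 0) return(0)
  if (is.infinite(dk) && dk > 0) return(0)
  if (is.infinite(dh)) { # dh = -Inf
    if (is.infinite(dk)) return(1)
    return(stats::pnorm(-dk))
  }
  if (is.infinite(dk)) return(stats::pnorm(-dh))

  ar <- abs(r)
  rule <- if (ar < 0.3) .gl_rules$n6 else if (ar < 0.75) .gl_rules$n12 else .gl_rules$n20
  w <- c(rule$w, rule$w)
  x <- c(1 - rule$x, 1 + rule$x)

  h <- dh; k <- dk; hk <- h * k
  if (ar < 0.925) {
    hs <- (h * h + k * k) / 2
    asr <- asin(r) / 2
    sn <- sin(asr * x)
    bvn <- sum(exp((sn * hk - hs) / (1 - sn^2)) * w)
    bvn <- bvn * asr / (2 * pi) + stats::pnorm(-h) * stats::pnorm(-k)
  } else {
    if (r < 0) { k <- -k; hk <- -hk }
    bvn <- 0
    if (ar < 1) {
      as_ <- 1 - r^2
      a <- sqrt(as_)
      bs <- (h - k)^2
      asr <- -(bs / as_ + hk) / 2
      cc <- (4 - hk) / 8
      dd <- (12 - hk) / 80
      if (asr > -100)
        bvn <- a * exp(asr) * (1 - cc * (bs - as_) * (1 - dd * bs) / 3 + cc * dd * as_^2)
      if (hk > -100) {
        b <- sqrt(bs)
        sp <- sqrt(2 * pi) * stats::pnorm(-b / a)
        bvn <- bvn - exp(-hk / 2) * sp * b * (1 - cc * bs * (1 - dd * bs) / 3)
      }
      a <- a / 2
      xs <- (a * x)^2
      asr <- -(bs / xs + hk) / 2
      ix <- asr > -100
      if (any(ix)) {
        xs_i <- xs[ix]
        sp <- 1 + cc * xs_i * (1 + 5 * dd * xs_i)
        rs <- sqrt(1 - xs_i)
        ep <- exp(-(hk / 2) * xs_i / (1 + rs)^2) / rs
        bvn <- (a * sum(exp(asr[ix]) * (sp - ep) * w[ix]) - bvn) / (2 * pi)
      } else {
        bvn <- -bvn / (2 * pi)
      }
    }
    if (r > 0) {
      bvn <- bvn + stats::pnorm(-max(h, k))
    } else if (h >= k) {
      bvn <- -bvn
    } else {
      L <- if (h < 0) stats::pnorm(k) - stats::pnorm(h)
           else stats::pnorm(-h) - stats::pnorm(-k)
      bvn <- L - bvn
    }
  }
  max(0, min(1, bvn))
}

#' Upper-orthant probability of the standard bivariate normal
#'
#' Computes \eqn{P(X > h, Y > k)} for a standard bivariate normal vector
#' with correlation `rho`, the quantity underlying the liability-threshold
#' model: with thresholds set by disease prevalence, this orthant mass is
#' the probability that both members of a twin pair are affected.
#'
#' Uses Genz's Gauss-Legendre quadrature scheme (absolute accuracy well
#' below 1e-10).  The degenerate cases `rho = 1` and `rho = -1` use the
#' closed forms `min(P(X>h), P(Y>k))` and `max(0, P(X>h) - P(Y<=-k))`.
#'
#' All three arguments are recycled to a common length.
#'
#' @param h,k Thresholds (finite or infinite).
#' @param rho Correlation(s) in `[-1, 1]`.
#' @return Numeric vector of probabilities.
#' @examples
#' bvn_orthant(0, 0, 0)      # 0.25
#' bvn_orthant(1.5, 1.5, 1)  # pnorm(-1.5)
#' @export
bvn_orthant <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  if (any(abs(rho) > 1, na.rm = TRUE))
    stop("`rho` must lie in [-1, 1]")
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- rho[i]
    if (r == 1) {
      out[i] <- min(stats::pnorm(-h[i]), stats::pnorm(-k[i]))
    } else if (r == -1) {
      # Y = -X: need X > h and -X > k, i.e. h < X < -k
      out[i] <- max(0, stats::pnorm(-k[i]) - stats::pnorm(h[i]))
    } else {
      out[i] <- .bvnu_scalar(h[i], k[i], r)
    }
  }
  out
}

#' Cell probabilities of a dichotomized bivariate normal
#'
#' Returns the four rectangle probabilities of the 2x2 table obtained by
#' thresholding a standard bivariate normal at `(h1, h2)`: `p11` (both
#' above threshold, i.e. both affected), `p10`, `p01`, `p00`.  The four
#' cells sum to 1 by construction.
#'
#' @param h1,h2 Thresholds for the two margins.
#' @param rho Latent correlation.
#' @return Named numeric vector `c(p11, p10, p01, p00)`.
#' @export
bvn_cell_probs <- function(h1, h2, rho) {
  p11 <- bvn_orthant(h1, h2, rho)
  m1 <- stats::pnorm(-h1)   # P(X > h1)
  m2 <- stats::pnorm(-h2)
  p10 <- pmax(m1 - p11, 0)
  p01 <- pmax(m2 - p11, 0)
  p00 <- pmax(1 - p11 - p10 - p01, 0)
  c(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
}
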