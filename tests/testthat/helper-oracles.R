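# Independent oracles used to cross-check the package's closed forms and
# fitters. These deliberately avoid the implementation paths they verify.

# SLS creep indentation with the ramp factor evaluated by adaptive quadrature
# of the ramp-convolution integral a * int_0^1 u^(a-1) e^(zu) du, instead of
# the package's Kummer series.
oracle_sls_delta <- function(t, k_l, k_a, eta, alpha, F_c = 30e-9,
                             ramp_time = 1, r = 44.65e-6) {
  C0 <- 1 / (k_l + k_a)
  C1 <- 1 / k_l
  C2 <- k_l * k_a / (eta * (k_l + k_a))
  z <- ramp_time * C2
  if (z >= 700) stop("oracle: ramp argument too large")
  M <- alpha * stats::integrate(function(u) u^(alpha - 1) * exp(z * u),
                                0, 1, rel.tol = 1e-12)$value
  pref <- 0.75 * (F_c / sqrt(r)) * alpha^(1 - alpha) * ramp_time^(alpha - 1)
  inner <- pref * (C0 + (C0 - C1) * exp(-t * C2) * M)
  if (any(inner <= 0)) stop("oracle: bracket non-positive")
  inner^(2 / 3)
}

# Brute-force Hertz modulus: grid search over K minimizing the SSE of
# F = (4/3) K sqrt(R) delta^(3/2) at a known contact height.
oracle_hertz_grid <- function(curve, z_c, K_grid) {
  meta <- curve_meta(curve)
  ext <- curve[curve$segment == "extend", ]
  delta <- (ext$height_m - z_c) - ext$force_n / meta$spring_constant
  ok <- delta > 0
  sse <- vapply(K_grid, function(K) {
    sum((ext$force_n[ok] -
           (4 / 3) * K * sqrt(meta$bead_radius) * delta[ok]^1.5)^2)
  }, numeric(1))
  K_grid[which.min(sse)]
}

# Exhaustive-enumeration null distribution of the Mann-Whitney U statistic
# for two groups of sizes n1, n2 with the observed pooled values; returns the
# two-sided p for the observed split.
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  mu <- length(x) * length(y) / 2
  p <- mean(abs(all_u - mu) >= abs(obs - mu) - 1e-12)
  list(statistic = obs, p.value = min(1, p))
}

# Discrete perimeter of a binary mask by the same intercept-count definition
# the package documents, recomputed independently (loop form).
oracle_perimeter <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  n_h <- 0
  for (i in seq_len(nr)) {
    row <- c(FALSE, bw[i, ], FALSE)
    n_h <- n_h + sum(row[-1] != row[-length(row)])
  }
  n_v <- 0
  for (j in seq_len(nc)) {
    col <- c(FALSE, bw[, j], FALSE)
    n_v <- n_v + sum(col[-1] != col[-length(col)])
  }
  (pi / 4) * (n_h + n_v)
}

# quick constructor for a single-frame node table
make_frame <- function(u, pos = NULL, f = NULL) {
  n <- nrow(u)
  if (is.null(pos)) {
    pos <- cbind(seq_len(n) * 1e-5, 0, 0)
  }
  out <- tibble::tibble(frame = 0L, x_m = pos[, 1], y_m = pos[, 2],
                        z_m = pos[, 3], ux_m = u[, 1], uy_m = u[, 2],
                        uz_m = u[, 3])
  if (!is.null(f)) {
    out$fx_n <- f[, 1]; out$fy_n <- f[, 2]; out$fz_n <- f[, 3]
  }
  out
}
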