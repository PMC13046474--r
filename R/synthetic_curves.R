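# Synthetic AFM inputs with known ground truth.
#
# The Hertz generator mirrors real acquisition: piezo height, not indentation,
# is stepped; at each height the consistent (indentation, force) pair is found
# from the implicit contact relation  s = delta + F(delta)/k_c  by vectorized
# bisection (force tolerance 1e-15 N).

.hertz_force <- function(K, R, delta) (4 / 3) * K * sqrt(R) * delta^1.5

# Solve delta from s = delta + hertz(delta)/k_c for each element of s (> 0).
.solve_indentation <- function(s, K, R, k_c, iters = 80) {
  lo <- rep(0, length(s))
  hi <- s
  g <- function(d) d + .hertz_force(K, R, d) / k_c - s
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Generate a synthetic Hertzian indentation curve
#'
#' Produces the extend segment of an indentation experiment on an elastic
#' half-space with reduced apparent modulus `K_true`: a linear pre-contact
#' baseline, then the Hertz spherical-contact force
#' \eqn{F = (4/3) K \sqrt{R}\, \delta^{3/2}} with the indentation depth
#' \eqn{\delta} computed self-consistently with cantilever deflection
#' (piezo travel = indentation + deflection \eqn{F/k_c}). The curve ends at
#' the first sample where the noiseless contact force reaches `max_force`.
#'
#' @param K_true Ground-truth reduced apparent elastic modulus (Pa).
#' @param bead_radius Probe radius R (m). Default: 18.64 um bead.
#' @param spring_constant Cantilever spring constant k_c (N/m).
#' @param max_force Target maximum indentation force (N). Default 10 nN.
#' @param approach_speed Piezo speed (m/s). Default 5 um/s.
#' @param data_rate Sampling rate (Hz). Default 1000 Hz.
#' @param baseline_slope,baseline_offset Linear baseline drift (N/m, N).
#' @param pre_contact_length Piezo travel before contact (m).
#' @param noise_sd Additive i.i.d. Gaussian force noise (N).
#' @param seed Integer seed; identical seeds give identical curves.
#'
#' @return A [force_curve()] (extend segment only) with attribute
#'   `truth = list(K, contact_height)`.
#' @export
#' @examples
#' fc <- gen_hertz_curve(K_true = 432, seed = 1)
#' attr(fc, "truth")$K
gen_hertz_curve <- function(K_true, bead_radius = 18.64e-6,
                            spring_constant = 0.03, max_force = 10e-9,
                            approach_speed = 5e-6, data_rate = 1000,
                            baseline_slope = 0, baseline_offset = 0,
                            pre_contact_length = 2e-6, noise_sd = 0,
                            seed = NULL) {
  if (K_true <= 0) stop_tm("K_true must be > 0", "tm_parameter_error")
  if (max_force <= 0) stop_tm("max_force must be > 0", "tm_parameter_error")
  if (noise_sd < 0) stop_tm("noise_sd must be >= 0", "tm_parameter_error")
  if (bead_radius <= 0 || spring_constant <= 0 || approach_speed <= 0 ||
      data_rate <= 0 || pre_contact_length < 0) {
    stop_tm("invalid acquisition parameter", "tm_parameter_error")
  }
  step <- approach_speed / data_rate
  delta_max <- (3 * max_force / (4 * K_true * sqrt(bead_radius)))^(2 / 3)
  travel <- pre_contact_length + delta_max + max_force / spring_constant
  n <- ceiling(travel / step) + 2L
  z <- (seq_len(n) - 1) * step
  s <- pmax(z - pre_contact_length, 0)
  fh <- numeric(n)
  post <- s > 0
  if (any(post)) {
    d <- .solve_indentation(s[post], K_true, bead_radius, spring_constant)
    fh[post] <- .hertz_force(K_true, bead_radius, d)
  }
  last <- which(fh >= max_force)[1]
  if (is.na(last)) last <- n
  z <- z[1:last]; fh <- fh[1:last]
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(sub_seed(seed, 1))
    rnorm(last, 0, noise_sd)
  } else 0
  force <- baseline_offset + baseline_slope * z + fh + noise
  fc <- force_curve(
    tibble(time_s = z / approach_speed, height_m = z, force_n = force,
           segment = "extend"),
    spring_constant = spring_constant, bead_radius = bead_radius,
    setpoint = max_force, approach_speed = approach_speed,
    data_rate = data_rate
  )
  attr(fc, "truth") <- list(K = K_true, contact_height = pre_contact_length)
  fc
}

#' Generate a synthetic force-clamp creep record
#'
#' Builds an extend segment (short pre-contact approach plus a force ramp of
#' duration `ramp_time`) followed by a constant-force hold whose indentation
#' follows the ramp-corrected standard-linear-solid closed form
#' ([sls_indentation()]) evaluated at the ground-truth parameters, with
#' optional Gaussian noise on the indentation (expressed through the height
#' channel). Force during the hold is exactly `clamp_force`.
#'
#' @param k_l,k_a,eta Ground-truth standard-linear-solid parameters (model
#'   units, all > 0).
#' @param alpha Ramp-shape parameter, in (1, 2).
#' @param clamp_force Clamp force F_c (N). Default 30 nN.
#' @param ramp_time Force ramp duration \eqn{\Delta t_a} (s).
#' @param indenter_radius Probe radius r (m). Default 44.65 um.
#' @param hold_duration Hold length (s), >= 3 by default.
#' @param data_rate Sampling rate (Hz).
#' @param spring_constant Cantilever spring constant (N/m).
#' @param pre_contact_length Pre-contact approach travel (m).
#' @param noise_sd Gaussian noise on hold indentation (m).
#' @param seed Integer seed.
#' @param coefficients Optional override `list(C0, C1, C2)` replacing the
#'   values derived from `k_l`, `k_a`, `eta` (used to construct degenerate
#'   elastic-limit records with `C0 == C1`).
#'
#' @return A [force_curve()] with `extend` and `hold` segments and attribute
#'   `truth = list(k_l, k_a, eta, alpha, clamp_force, ramp_time)`.
#' @export
gen_creep_record <- function(k_l, k_a, eta, alpha = 1.5,
                             clamp_force = 30e-9, ramp_time = 1,
                             indenter_radius = 44.65e-6, hold_duration = 3,
                             data_rate = 200, spring_constant = 0.18,
                             pre_contact_length = 1e-6, noise_sd = 0,
                             seed = NULL, coefficients = NULL) {
  if (alpha <= 1 || alpha >= 2) stop_tm("alpha must be in (1, 2)",
                                        "tm_parameter_error")
  if (is.null(coefficients)) {
    if (k_l <= 0 || k_a <= 0 || eta <= 0) {
      stop_tm("k_l, k_a, eta must be > 0", "tm_parameter_error")
    }
    cf <- sls_coefficients(k_l, k_a, eta)
  } else {
    cf <- coefficients
  }
  if (hold_duration <= 0 || data_rate <= 0 || noise_sd < 0) {
    stop_tm("invalid acquisition parameter", "tm_parameter_error")
  }
  dt <- 1 / data_rate
  # pre-contact approach: slow enough that the approach takes ~1 s, giving
  # the fit a clean baseline window before the ramp
  approach_speed <- max(pre_contact_length, 1e-7)
  n_pre <- max(30L, ceiling(pre_contact_length / (approach_speed * dt)))
  t_pre <- (seq_len(n_pre) - 1) * dt
  z_pre <- t_pre * approach_speed
  z_c <- z_pre[n_pre] + approach_speed * dt  # contact at first ramp sample
  # ramp: force F(t) = F_c * (t/ramp_time)^alpha; indentation approximated by
  # the hold-entry value scaled elastically (only the hold is ever fitted)
  n_ramp <- ceiling(ramp_time / dt)
  t_ramp <- seq_len(n_ramp) * dt
  f_ramp <- clamp_force * (t_ramp / ramp_time)^alpha
  d0 <- .sls_delta_coef(0, cf$C0, cf$C1, cf$C2, alpha, clamp_force,
                        ramp_time, indenter_radius)
  d_ramp <- d0 * (f_ramp / clamp_force)^(2 / 3)
  z_ramp <- z_c + d_ramp + f_ramp / spring_constant
  # hold
  n_hold <- floor(hold_duration / dt) + 1L
  t_hold <- (seq_len(n_hold) - 1) * dt
  d_hold <- .sls_delta_coef(t_hold, cf$C0, cf$C1, cf$C2, alpha, clamp_force,
                            ramp_time, indenter_radius)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(sub_seed(seed, 2))
    d_hold <- d_hold + rnorm(n_hold, 0, noise_sd)
  }
  z_hold <- z_c + d_hold + clamp_force / spring_constant
  tt <- c(t_pre, t_pre[n_pre] + dt + c(t_ramp - dt, t_ramp[n_ramp] + t_hold))
  fc <- force_curve(
    tibble(time_s = tt,
           height_m = c(z_pre, z_ramp, z_hold),
           force_n = c(rep(0, n_pre), f_ramp, rep(clamp_force, n_hold)),
           segment = c(rep("extend", n_pre + n_ramp), rep("hold", n_hold))),
    spring_constant = spring_constant, bead_radius = indenter_radius,
    setpoint = clamp_force, approach_speed = approach_speed,
    data_rate = data_rate
  )
  attr(fc, "truth") <- list(k_l = if (is.null(coefficients)) k_l else NA,
                            k_a = if (is.null(coefficients)) k_a else NA,
                            eta = if (is.null(coefficients)) eta else NA,
                            alpha = alpha, clamp_force = clamp_force,
                            ramp_time = ramp_time, contact_height = z_c)
  fc
}

#' Generate a grid of Hertz curves with regional stiffness structure
#'
#' Each grid point carries a synthetic Hertz curve whose ground-truth modulus
#' is drawn around its region's median; a seeded choice of points is replaced
#' by unanalysable pure-noise curves.
#'
#' @param region_medians Named numeric vector of region medians (Pa). Regions
#'   are laid out as equal vertical bands (left to right) unless
#'   `region_masks` is given.
#' @param nrow,ncol Grid dimensions.
#' @param spacing Grid spacing (m).
#' @param spread Standard deviation (Pa) of the per-point modulus around its
#'   region median; `0` gives exactly the median everywhere.
#' @param na_fraction Fraction of points replaced by unanalysable curves;
#'   the count is `round(na_fraction * nrow * ncol)`, chosen by seeded
#'   sampling.
#' @param seed Integer seed.
#' @param region_masks Optional named list of logical `nrow x ncol` matrices
#'   (lower-left origin) overriding the vertical-band layout.
#' @param ... Passed to [gen_hertz_curve()] (e.g. `bead_radius`, `max_force`).
#'
#' @return A list with `curves` (tibble: `row`, `col`, `region`, `K_true`,
#'   `analysable`, `curve` list-column), `region_masks` (named list of logical
#'   matrices) and `spacing`.
#' @export
gen_stiffness_field <- function(region_medians, nrow = 6, ncol = 6,
                                spacing = 25e-6, spread = 0, na_fraction = 0,
                                seed = 1, region_masks = NULL, ...) {
  if (length(region_medians) < 1 || any(region_medians <= 0)) {
    stop_tm("region medians must be > 0", "tm_parameter_error")
  }
  if (na_fraction < 0 || na_fraction >= 1) {
    stop_tm("na_fraction must be in [0, 1)", "tm_parameter_error")
  }
  if (nrow < 1 || ncol < 1) stop_tm("empty grid", "tm_parameter_error")
  regions <- names(region_medians)
  if (is.null(regions)) regions <- paste0("region", seq_along(region_medians))
  if (is.null(region_masks)) {
    region_masks <- list()
    bands <- floor(seq(0, ncol, length.out = length(regions) + 1))
    for (i in seq_along(regions)) {
      m <- matrix(FALSE, nrow, ncol)
      cols <- (bands[i] + 1):bands[i + 1]
      m[, cols] <- TRUE
      region_masks[[regions[i]]] <- m
    }
  }
  n <- nrow * ncol
  set.seed(sub_seed(seed, 3))
  n_na <- round(na_fraction * n)
  na_idx <- if (n_na > 0) sample.int(n, n_na) else integer(0)
  grid <- tidyr::expand_grid(row = seq_len(nrow), col = seq_len(ncol))
  region_of <- function(r, c) {
    for (nm in names(region_masks)) if (region_masks[[nm]][r, c]) return(nm)
    NA_character_
  }
  grid$region <- purrr::map2_chr(grid$row, grid$col, region_of)
  set.seed(sub_seed(seed, 4))
  med <- unname(region_medians[grid$region])
  grid$K_true <- if (spread > 0) {
    pmax(rnorm(n, med, spread), 1)
  } else med
  cell <- (grid$col - 1) * nrow + grid$row
  grid$analysable <- !(cell %in% na_idx)
  grid$curve <- purrr::pmap(
    list(grid$K_true, grid$analysable, seq_len(n)),
    function(K, ok, i) {
      if (ok) {
        gen_hertz_curve(K_true = K, seed = sub_seed(seed, 100 + i), ...)
      } else {
        .gen_noise_curve(seed = sub_seed(seed, 100 + i), ...)
      }
    })
  list(curves = grid, region_masks = region_masks, spacing = spacing)
}

# An unanalysable curve: pure noise, no contact.
.gen_noise_curve <- function(seed = 1, bead_radius = 18.64e-6,
                             spring_constant = 0.03, max_force = 10e-9,
                             approach_speed = 5e-6, data_rate = 1000, ...) {
  set.seed(sub_seed(seed, 5))
  n <- 400L
  step <- approach_speed / data_rate
  z <- (seq_len(n) - 1) * step
  force_curve(
    tibble(time_s = z / approach_speed, height_m = z,
           force_n = rnorm(n, 0, 0.3 * max_force), segment = "extend"),
    spring_constant = spring_constant, bead_radius = bead_radius,
    setpoint = max_force, approach_speed = approach_speed,
    data_rate = data_rate
  )
}
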