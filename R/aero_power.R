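# Aerodynamic power model for flapping flight: mass-specific induced and
# profile power, flapping-wing Reynolds number, and constant-power isolines
# in the wingbeat frequency-amplitude plane.

#' Morphometric and aerodynamic parameters of the power model
#'
#' Bundles the wing, body, and air parameters required by the mass-specific
#' mechanical power model. All quantities are SI.
#'
#' @param F_t Total flight force (N). For hovering this is close to body
#'   weight.
#' @param R Wing length (m).
#' @param S Combined surface area of the two wings (m^2).
#' @param m_M Flight-muscle mass (kg).
#' @param rho Air density (kg m^-3).
#' @param g Gravitational acceleration (m s^-2).
#' @param kappa Induced-power correction factor (dimensionless, >= 1)
#'   accounting for the periodic vortex wake.
#' @param r3_hat_cubed Dimensionless third moment of wing area, cubed.
#' @param mean_abs_angvel_cubed Mean cube of the absolute dimensionless
#'   angular velocity of the wing over a stroke cycle, with stroke position
#'   normalized by the half-amplitude Phi/2 and time by the wingbeat period
#'   (the convention under which the 1/16 prefactor of the profile-power
#'   formula is dimensionally and physically exact). For purely sinusoidal
#'   flapping this equals (32/3)*pi^2 ~ 105.3.
#' @param cd_pro_fixed Optional fixed mean profile drag coefficient. When
#'   `NULL` (default) the Reynolds-number-based approximation 7/sqrt(Re) is
#'   used instead.
#' @param nu Kinematic viscosity of air (m^2 s^-1).
#' @return An object of class `"morphometrics"` (a validated named list).
#' @seealso [default_morphometrics()] for a documented Drosophila-like set.
#' @export
morphometrics <- function(F_t, R, S, m_M, rho = 1.2, g = 9.81, kappa = 1.2,
                          r3_hat_cubed = 0.195,
                          mean_abs_angvel_cubed = 32 * pi^2 / 3,
                          cd_pro_fixed = NULL, nu = 1.5e-5) {
  m <- list(F_t = F_t, R = R, S = S, m_M = m_M, rho = rho, g = g,
            kappa = kappa, r3_hat_cubed = r3_hat_cubed,
            mean_abs_angvel_cubed = mean_abs_angvel_cubed,
            cd_pro_fixed = cd_pro_fixed, nu = nu)
  num <- m[setdiff(names(m), "cd_pro_fixed")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1))))
    stop("all morphometric parameters must be finite scalars")
  pos <- c("R", "S", "m_M", "rho", "g", "nu", "r3_hat_cubed",
           "mean_abs_angvel_cubed")
  bad <- pos[vapply(pos, function(k) m[[k]] <= 0, logical(1))]
  if (length(bad)) stop("morphometric parameters must be positive: ",
                        paste(bad, collapse = ", "))
  if (m$F_t < 0) stop("F_t must be non-negative")
  if (m$kappa < 0) stop("kappa must be non-negative")
  # kappa = 0 is the documented profile-only diagnostic limit; values in
  # (0, 1) are physically doubtful
  if (m$kappa > 0 && m$kappa < 1)
    warning("kappa < 1 is outside the usual induced-power correction range")
  if (!is.null(cd_pro_fixed)) {
    if (!(is.numeric(cd_pro_fixed) && length(cd_pro_fixed) == 1L &&
          is.finite(cd_pro_fixed) && cd_pro_fixed > 0))
      stop("cd_pro_fixed must be a positive scalar or NULL")
  }
  structure(m, class = "morphometrics")
}

#' Default Drosophila-like morphometric parameter set
#'
#' A documented, plausible parameter set for a ~1 mg fruit fly, used as the
#' package's default fixture. These are round, field-typical values (wing
#' length 2.4 mm, two-wing area 3.6 mm^2, flight-muscle mass 0.3 mg, flight
#' force equal to the weight of 1 mg); they are not measurements of any
#' particular animal, and absolute power levels computed from them should be
#' read as order-of-magnitude realistic rather than calibrated.
#'
#' @param cd_pro_fixed Optional fixed mean profile drag coefficient passed
#'   through to [morphometrics()]; default `NULL` selects the 7/sqrt(Re)
#'   approximation.
#' @return A `"morphometrics"` object.
#' @export
default_morphometrics <- function(cd_pro_fixed = NULL) {
  morphometrics(
    F_t = 1.0e-5,         # N; weight of a 1.02 mg fly
    R = 2.4e-3,           # m
    S = 3.6e-6,           # m^2, both wings
    m_M = 3.0e-7,         # kg, ~30% of body mass
    rho = 1.2,
    g = 9.81,
    kappa = 1.2,
    r3_hat_cubed = 0.195, # r3_hat(S) ~ 0.58
    mean_abs_angvel_cubed = 32 * pi^2 / 3, # sinusoidal stroke
    cd_pro_fixed = cd_pro_fixed,
    nu = 1.5e-5
  )
}

#' @export
print.morphometrics <- function(x, ...) {
  cat("Morphometrics (SI units)\n")
  cd <- if (is.null(x$cd_pro_fixed)) "7/sqrt(Re)" else
    format(x$cd_pro_fixed)
  cat(sprintf("  F_t = %.3g N, R = %.3g m, S = %.3g m^2, m_M = %.3g kg\n",
              x$F_t, x$R, x$S, x$m_M))
  cat(sprintf("  rho = %.3g, nu = %.3g, kappa = %.3g, r3^3 = %.3g, <|dphi/dt|^3> = %.4g\n",
              x$rho, x$nu, x$kappa, x$r3_hat_cubed, x$mean_abs_angvel_cubed))
  cat("  mean profile drag coefficient:", cd, "\n")
  invisible(x)
}

#' Read and write morphometrics as flat YAML
#'
#' @param path File path. The file is a flat key-value YAML mapping with the
#'   argument names of [morphometrics()].
#' @return `read_morphometrics()` returns a `"morphometrics"` object;
#'   `write_morphometrics()` returns `path` invisibly.
#' @export
read_morphometrics <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(morphometrics, vals)
}

#' @rdname read_morphometrics
#' @param morph A `"morphometrics"` object.
#' @export
write_morphometrics <- function(morph, path) {
  stopifnot(inherits(morph, "morphometrics"))
  vals <- unclass(morph)
  vals$cd_pro_fixed <- morph$cd_pro_fixed # NULL dropped by yaml
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Wingbeat kinematic state
#'
#' Pairs a wingbeat frequency with a (peak-to-peak) stroke amplitude.
#' Public interfaces accept amplitude in degrees (the native unit of
#' wingbeat trackers); all internal evaluation is in radians.
#'
#' @param n Wingbeat frequency (Hz); vectorized.
#' @param phi Wingbeat amplitude, in the unit given by `unit`; vectorized
#'   (recycled against `n`).
#' @param unit `"deg"` (default) or `"rad"`.
#' @return An object of class `"kinematic_state"`: a list with vectors `n`
#'   (Hz) and `phi_rad` (radians).
#' @export
kinematic_state <- function(n, phi, unit = c("deg", "rad")) {
  unit <- match.arg(unit)
  if (!is.numeric(n) || !is.numeric(phi))
    stop("n and phi must be numeric")
  k <- max(length(n), length(phi))
  n <- rep_len(as.numeric(n), k)
  phi <- rep_len(as.numeric(phi), k)
  phi_rad <- if (unit == "deg") phi * pi / 180 else phi
  if (any(!is.finite(n)) || any(!is.finite(phi_rad)))
    stop("non-finite kinematic values")
  if (any(n <= 0)) stop("wingbeat frequency must be positive")
  if (any(phi_rad <= 0) || any(phi_rad >= 2 * pi))
    stop("wingbeat amplitude must lie in (0, 2*pi) radians")
  structure(list(n = n, phi_rad = phi_rad), class = "kinematic_state")
}

as_kinematic_state <- function(kin) {
  if (!inherits(kin, "kinematic_state"))
    stop("expected a 'kinematic_state'; build one with kinematic_state()")
  kin
}

#' Flapping-wing Reynolds number
#'
#' Re = S * n * Phi / nu, with S the combined area of the two wings, n the
#' wingbeat frequency, Phi the stroke amplitude in radians, and nu the
#' kinematic viscosity of air.
#'
#' @param kin A [kinematic_state()].
#' @param morph A [morphometrics()] object.
#' @return Dimensionless Reynolds number(s), one per kinematic sample.
#' @export
reynolds_number <- function(kin, morph) {
  kin <- as_kinematic_state(kin)
  stopifnot(inherits(morph, "morphometrics"))
  morph$S * kin$n * kin$phi_rad / morph$nu
}

#' Mean profile drag coefficient
#'
#' Returns the fixed coefficient stored in `morph$cd_pro_fixed` when one is
#' set; otherwise the Reynolds-number approximation 7/sqrt(Re).
#'
#' @param Re Reynolds number(s), positive.
#' @param morph A [morphometrics()] object.
#' @return Dimensionless drag coefficient(s) the same length as `Re`.
#' @export
profile_drag_coefficient <- function(Re, morph) {
  stopifnot(inherits(morph, "morphometrics"))
  if (any(!is.finite(Re)) || any(Re <= 0))
    stop("Re must be positive and finite")
  if (!is.null(morph$cd_pro_fixed)) rep_len(morph$cd_pro_fixed, length(Re))
  else 7 / sqrt(Re)
}

#' Mass-specific induced power
#'
#' The actuator-disc cost of lift per unit flight-muscle mass:
#' P*_ind = kappa * (F_t / m_M) * sqrt(F_t / (2 * rho * Phi * R^2)),
#' in W kg^-1. Monotonically decreasing in stroke amplitude Phi: a wider
#' stroke sweeps a larger actuator disc.
#'
#' @inheritParams reynolds_number
#' @return Induced power (W kg^-1) per kinematic sample.
#' @export
induced_power <- function(kin, morph) {
  kin <- as_kinematic_state(kin)
  stopifnot(inherits(morph, "morphometrics"))
  morph$kappa * (morph$F_t / morph$m_M) *
    sqrt(morph$F_t / (2 * morph$rho * kin$phi_rad * morph$R^2))
}

#' Mass-specific profile power
#'
#' The cost of wing drag per unit flight-muscle mass:
#' P*_pro = rho * S * n^3 * Phi^3 * R^3 * r3^3 * <|dphi/dt|^3> * CD_pro /
#' (16 * m_M), with CD_pro from [profile_drag_coefficient()]. With a fixed
#' drag coefficient this scales exactly as (n * Phi)^3; with the
#' Re-based coefficient the exponent drops to 2.5.
#'
#' @inheritParams reynolds_number
#' @return Profile power (W kg^-1) per kinematic sample.
#' @export
profile_power <- function(kin, morph) {
  kin <- as_kinematic_state(kin)
  stopifnot(inherits(morph, "morphometrics"))
  cd <- profile_drag_coefficient(reynolds_number(kin, morph), morph)
  morph$rho * morph$S * kin$n^3 * kin$phi_rad^3 * morph$R^3 *
    morph$r3_hat_cubed * morph$mean_abs_angvel_cubed * cd / (16 * morph$m_M)
}

#' Total mass-specific mechanical power
#'
#' Sum of induced and profile power, assuming the thorax stores and returns
#' the inertial power elastically so that it does not appear as a muscle
#' cost.
#'
#' @inheritParams reynolds_number
#' @return An object of class `"power_breakdown"`: a list with vectors
#'   `P_ind`, `P_pro`, `P_mech` (all W kg^-1), `Re`, and `cd_used`.
#' @export
mechanical_power <- function(kin, morph) {
  kin <- as_kinematic_state(kin)
  Re <- reynolds_number(kin, morph)
  cd <- profile_drag_coefficient(Re, morph)
  P_ind <- induced_power(kin, morph)
  P_pro <- profile_power(kin, morph)
  structure(list(P_ind = P_ind, P_pro = P_pro, P_mech = P_ind + P_pro,
                 Re = Re, cd_used = cd),
            class = "power_breakdown")
}

#' @export
print.power_breakdown <- function(x, ...) {
  k <- length(x$P_mech)
  cat(sprintf("Power breakdown (%d kinematic state%s), W kg^-1\n",
              k, if (k == 1) "" else "s"))
  show <- utils::head(data.frame(P_ind = x$P_ind, P_pro = x$P_pro,
                                 P_mech = x$P_mech, Re = x$Re,
                                 cd = x$cd_used), 6)
  print(show, digits = 4)
  if (k > 6) cat("  ...", k - 6, "more\n")
  invisible(x)
}

# P_pro = C(phi) * n^p with p = 3 (fixed cd) or 2.5 (Re-based cd).
profile_power_exponent <- function(morph) {
  if (is.null(morph$cd_pro_fixed)) 2.5 else 3
}

# Closed-form inverse of P_mech in n at fixed phi (radians): P_ind does not
# depend on n and P_pro is a pure power law in n, so the root is explicit.
freq_at_power <- function(phi_rad, P_level, morph) {
  p <- profile_power_exponent(morph)
  kin1 <- structure(list(n = rep(1, length(phi_rad)), phi_rad = phi_rad),
                    class = "kinematic_state")
  C <- profile_power(kin1, morph)
  head_room <- P_level - induced_power(kin1, morph)
  ifelse(head_room > 0, (head_room / C)^(1 / p), NA_real_)
}

#' Solve a constant-power isoline in the frequency-amplitude plane
#'
#' For each frequency on `n_grid`, root-finds the stroke amplitude Phi at
#' which total mass-specific mechanical power equals `P_level`. Because
#' induced power diverges as Phi -> 0 and profile power as Phi grows, the
#' power curve in Phi is U-shaped; the isoline tracks the ascending
#' (profile-dominated) branch, the one observed as the amplitude-frequency
#' tradeoff. Grid frequencies where no root exists inside `phi_bounds` are
#' omitted and recorded in the result's `omitted_n` attribute.
#'
#' @param P_level Target mass-specific power (W kg^-1), positive scalar.
#' @param n_grid Ascending wingbeat frequencies (Hz).
#' @param morph A [morphometrics()] object.
#' @param phi_bounds Search interval for Phi in radians.
#' @param rel_tol Relative tolerance on the power residual at each point.
#' @return An object of class `"power_isoline"`: a data frame with columns
#'   `n_hz`, `phi_rad`, `phi_deg`, `p_mech`, `residual`, plus attributes
#'   `P_level`, `morph`, and `omitted_n`.
#' @export
solve_isoline <- function(P_level, n_grid, morph,
                          phi_bounds = c(1e-3, 2 * pi - 1e-3),
                          rel_tol = 1e-9) {
  stopifnot(inherits(morph, "morphometrics"))
  if (!(is.numeric(P_level) && length(P_level) == 1L && P_level > 0))
    stop("P_level must be a positive scalar")
  if (is.unsorted(n_grid, strictly = TRUE))
    stop("n_grid must be strictly ascending")
  pm <- function(n, phi) {
    kin <- structure(list(n = n, phi_rad = phi), class = "kinematic_state")
    induced_power(kin, morph) + profile_power(kin, morph)
  }
  rows <- vector("list", length(n_grid))
  omitted <- numeric(0)
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    f <- function(phi) pm(n, phi) - P_level
    # locate the minimum of the U-shaped power curve, then root on the
    # ascending branch [phi_min, upper]
    opt <- stats::optimize(function(phi) pm(n, phi),
                           interval = phi_bounds, tol = 1e-10)
    lo <- opt$minimum
    if (opt$objective > P_level || f(phi_bounds[2]) < 0) {
      omitted <- c(omitted, n)
      next
    }
    root <- stats::uniroot(f, interval = c(lo, phi_bounds[2]),
                           tol = .Machine$double.eps^0.75,
                           maxiter = 2000)$root
    res <- f(root)
    if (abs(res) > rel_tol * P_level) {
      omitted <- c(omitted, n)
      next
    }
    rows[[i]] <- c(n, root, res + P_level)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("no isoline in range: P_level = ", P_level,
         " is unreachable for every frequency on the grid")
  m <- do.call(rbind, rows)
  out <- data.frame(n_hz = m[, 1], phi_rad = m[, 2],
                    phi_deg = m[, 2] * 180 / pi, p_mech = m[, 3],
                    residual = m[, 3] - P_level)
  structure(out, class = c("power_isoline", "data.frame"),
            P_level = P_level, morph = morph, omitted_n = omitted)
}

#' @export
print.power_isoline <- function(x, ...) {
  cat(sprintf("Power isoline at P_mech = %.6g W kg^-1 (%d points",
              attr(x, "P_level"), nrow(x)))
  om <- attr(x, "omitted_n")
  if (length(om)) cat(sprintf(", %d grid frequencies omitted", length(om)))
  cat(")\n")
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 6)
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
plot.power_isoline <- function(x, ...) {
  graphics::plot(x$phi_deg, x$n_hz, type = "l",
                 xlab = "wingbeat amplitude (deg)",
                 ylab = "wingbeat frequency (Hz)",
                 main = sprintf("P_mech = %.4g W kg^-1", attr(x, "P_level")),
                 ...)
  invisible(x)
}

#' Bounding power of a kinematic trajectory
#'
#' The smallest constant-power isoline level that contains an observed cloud
#' of (frequency, amplitude) samples, i.e. the maximum of P_mech over the
#' trajectory, together with where it occurs.
#'
#' @param kin A [kinematic_state()] holding the trajectory samples.
#' @param morph A [morphometrics()] object.
#' @return A list with `P_max` (W kg^-1), `index` of the arg-max sample, and
#'   the full `P_mech` vector.
#' @export
bounding_power <- function(kin, morph) {
  kin <- as_kinematic_state(kin)
  if (!length(kin$n)) stop("empty trajectory")
  pb <- mechanical_power(kin, morph)
  i <- which.max(pb$P_mech)
  list(P_max = pb$P_mech[i], index = i, P_mech = pb$P_mech)
}

#' Write or read an isoline as two-column CSV
#'
#' The file holds columns `n_hz`, `phi_deg`, preceded by `#` header comments
#' recording the power level and the full morphometric parameter set.
#'
#' @param iso A `"power_isoline"` object.
#' @param path File path.
#' @return `write_isoline()` returns `path` invisibly; `read_isoline()`
#'   returns a data frame with columns `n_hz` and `phi_deg` and a `P_level`
#'   attribute.
#' @export
write_isoline <- function(iso, path) {
  stopifnot(inherits(iso, "power_isoline"))
  morph <- attr(iso, "morph")
  pars <- unclass(morph)
  pars$cd_pro_fixed <- if (is.null(pars$cd_pro_fixed)) "Re-based" else
    pars$cd_pro_fixed
  hdr <- c(sprintf("# P_level_w_per_kg=%.17g", attr(iso, "P_level")),
           paste0("# params: ",
                  paste(sprintf("%s=%s", names(pars),
                                vapply(pars, format, character(1))),
                        collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(n_hz = iso$n_hz, phi_deg = iso$phi_deg),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isoline
#' @export
read_isoline <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  lev <- NA_real_
  m <- regmatches(hdr, regexpr("P_level_w_per_kg=[-0-9.eE+]+", hdr))
  if (length(m)) lev <- as.numeric(sub("P_level_w_per_kg=", "", m[[1]]))
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  attr(df, "P_level") <- lev
  df
}
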