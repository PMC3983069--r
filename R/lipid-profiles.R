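# Trans-monolayer lateral stress profiles and depth-dependent elastic moduli.
#
# Conventions used throughout the package:
#   * z is the depth coordinate of ONE monolayer in its own frame, measured
#     from the bilayer midplane (z = 0) outward to the polar surface (z = h).
#   * sigma(z) is tension-positive (lateral pressure is sigma < 0).
#   * The neutral plane sits at z0 = 2h/3, i.e. h/3 below the outer surface.
#   * The bending moment is tau = -\int (z - z0) sigma(z) dz, so that a flat
#     monolayer frustrated by a spontaneous curvature J_s carries
#     tau = kappa * J_s: lysolipid-like species (J_s > 0) crowd the headgroup
#     region and produce lateral pressure (sigma < 0) above the neutral
#     plane.

#' Lipid species with a spontaneous-curvature contribution
#'
#' @param name character name of the lipid.
#' @param zeta monolayer spontaneous-curvature contribution of the pure
#'   species, nm^-1.
#' @param area_fraction intra-monolayer area fraction in `[0, 1]`.
#' @return An object of class `lipid_species`.
#' @export
lipid_species <- function(name, zeta, area_fraction) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(zeta), length(zeta) == 1L, is.finite(zeta),
            is.numeric(area_fraction), length(area_fraction) == 1L)
  if (area_fraction < -1e-12 || area_fraction > 1 + 1e-12)
    stop("area_fraction must lie in [0, 1], got ", format(area_fraction))
  structure(list(name = name, zeta = zeta,
                 area_fraction = area_fraction),
            class = "lipid_species")
}

#' Default lipid spontaneous-curvature table
#'
#' Spontaneous-curvature contributions (nm^-1) of the lipid species used in
#' the ALPS composition analysis, consistent with published monolayer
#' curvature measurements.  The table can be overridden from a CSV file with
#' columns `name` and `zeta_per_nm` via [read_zeta_table()].
#'
#' @return data.frame with columns `name` and `zeta_per_nm`.
#' @export
lipid_zeta_table <- function() {
  data.frame(name = c("DOPC", "DOPE", "DOPS", "DAG"),
             zeta_per_nm = c(-0.115, -0.333, 0.068, -0.985),
             stringsAsFactors = FALSE)
}

#' Read a lipid spontaneous-curvature table from CSV
#'
#' @param path CSV file with columns `name`, `zeta_per_nm`.
#' @return data.frame like [lipid_zeta_table()].
#' @export
read_zeta_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "zeta_per_nm") %in% names(tab)))
    stop("zeta table must have columns 'name' and 'zeta_per_nm'")
  tab[c("name", "zeta_per_nm")]
}

#' Monolayer spontaneous curvature of a lipid mixture
#'
#' The monolayer spontaneous curvature of a mixture is the area-fraction
#' weighted sum of the contributions of its components,
#' `J_s^m = sum_i phi_i * zeta_i`.
#'
#' @param composition either a list of [lipid_species()] objects, or a named
#'   numeric vector of area fractions (names looked up in `zeta_table`).
#' @param zeta_table lookup table used when `composition` is a named vector;
#'   defaults to [lipid_zeta_table()].
#' @return Monolayer spontaneous curvature, nm^-1.
#' @export
composition_to_spontaneous_curvature <- function(composition,
                                                 zeta_table = lipid_zeta_table()) {
  if (is.numeric(composition)) {
    if (is.null(names(composition)))
      stop("numeric composition must be a named vector of area fractions")
    idx <- match(names(composition), zeta_table$name)
    if (anyNA(idx))
      stop("unknown lipid species: ",
           paste(names(composition)[is.na(idx)], collapse = ", "))
    phi <- as.numeric(composition)
    zeta <- zeta_table$zeta_per_nm[idx]
  } else {
    stopifnot(is.list(composition), length(composition) > 0L)
    phi <- vapply(composition, function(s) s$area_fraction, numeric(1))
    zeta <- vapply(composition, function(s) s$zeta, numeric(1))
  }
  residual <- sum(phi) - 1
  if (abs(residual) > 1e-9)
    stop("lipid area fractions must sum to 1; residual = ",
         format(residual, digits = 6))
  sum(phi * zeta)
}

#' Monolayer mechanical specification
#'
#' @param h monolayer thickness, nm.
#' @param kappa monolayer bending modulus, kT.
#' @param J_s monolayer spontaneous curvature, nm^-1.
#' @param gamma monolayer lateral tension, kT nm^-2.
#' @param z0 neutral-plane position, nm from the bilayer midplane; defaults
#'   to two thirds of the monolayer thickness.
#' @return Object of class `monolayer_spec`.
#' @export
monolayer_spec <- function(h = 2, kappa = 10, J_s = 0, gamma = 0,
                           z0 = 2 * h / 3) {
  stopifnot(is.numeric(h), h > 0, is.numeric(kappa), kappa > 0,
            is.numeric(J_s), is.numeric(gamma), is.numeric(z0))
  if (z0 <= 0 || z0 >= h)
    stop("neutral plane z0 must lie strictly inside (0, h)")
  if (abs(J_s) * h >= 1)
    stop("|J_s| * h = ", format(abs(J_s) * h),
         " violates the small-spontaneous-curvature regime |J_s| * h < 1")
  structure(list(h = h, kappa = kappa, J_s = J_s, gamma = gamma, z0 = z0),
            class = "monolayer_spec")
}

# Raised-cosine bump on |z - center| < width/2, zero outside.  Values only;
# normalisation is done discretely on the profile grid so that the moment
# constraints hold exactly under the trapezoid rule.
.cos_bump <- function(z, center, width) {
  u <- (z - center) / width
  out <- numeric(length(z))
  inside <- abs(u) < 0.5
  out[inside] <- cos(pi * u[inside])^2
  out
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# exact first moment about z0 of the piecewise-linear interpolant of
# (x, y): per segment, int z*y dz = dx * (y1*(2*x1 + x2) + y2*(x1 + 2*x2))/6
.moment1 <- function(x, y, z0 = 0) {
  n <- length(x)
  x1 <- x[-n]; x2 <- x[-1]; y1 <- y[-n]; y2 <- y[-1]
  dx <- x2 - x1
  m <- sum(dx * (y1 * (2 * x1 + x2) + y2 * (x1 + 2 * x2)) / 6)
  m - z0 * .trapz(x, y)
}

#' Shape parameters of the three-zone stress profile
#'
#' The trans-monolayer lateral stress profile is built from three smooth
#' zones: a headgroup zone near the outer surface, a narrow interfacial zone
#' at the neutral plane and a broad acyl-chain zone below.  Zone amplitudes
#' are solved from the tension and bending-moment constraints; the zone
#' geometry and the split of the moment-carrying modulation are controlled
#' here.
#'
#' @param head_center,head_width headgroup zone center/width, nm, measured
#'   like `z` (defaults: `h - 0.3` and 0.6).
#' @param interface_width interfacial zone width, nm (centered at the
#'   neutral plane).
#' @param chain_center,chain_width acyl-chain zone center/width, nm
#'   (defaults: `h/3` and 1.2).
#' @param w_head fraction of the bending-moment modulation carried by the
#'   headgroup/interface pair of zones (remainder by the interface/chain
#'   pair).  Default 1: composition changes act at the headgroup region.
#' @param frustration_amp amplitude (kT nm^-3, peak absolute stress) of the
#'   zero-tension zero-moment frustration component present even in an
#'   unstressed monolayer.  Default 0: the profile then measures the
#'   deviation from the unstressed reference state.
#' @param n_grid number of grid points of the returned profile.
#' @return list of shape parameters.
#' @export
profile_shape <- function(head_center = NULL, head_width = 0.6,
                          interface_width = 0.5,
                          chain_center = NULL, chain_width = 1.2,
                          w_head = 1, frustration_amp = 0,
                          n_grid = 2001) {
  list(head_center = head_center, head_width = head_width,
       interface_width = interface_width,
       chain_center = chain_center, chain_width = chain_width,
       w_head = w_head, frustration_amp = frustration_amp,
       n_grid = n_grid)
}

#' Build a trans-monolayer lateral stress profile
#'
#' Constructs a three-zone stress profile carrying exactly the lateral
#' tension `gamma` of the spec and the bending moment `tau = kappa * J_s`
#' (see the package conventions: `tau = -\int (z - z0) sigma dz`).
#'
#' @param spec a [monolayer_spec()].
#' @param shape shape parameters from [profile_shape()].
#' @param tau optional explicit bending moment, kT nm^-1; by default
#'   `spec$kappa * spec$J_s`.
#' @return Object of class `stress_profile` with fields `z_grid`, `sigma`,
#'   `z0`, `gamma`, `tau`, `h`.
#' @export
build_stress_profile <- function(spec, shape = profile_shape(), tau = NULL) {
  stopifnot(inherits(spec, "monolayer_spec"))
  h <- spec$h; z0 <- spec$z0
  if (is.null(tau)) tau <- spec$kappa * spec$J_s
  gamma <- spec$gamma
  hc <- if (is.null(shape$head_center)) h - 0.3 else shape$head_center
  cc <- if (is.null(shape$chain_center)) h / 3 else shape$chain_center
  widths <- c(shape$head_width, shape$interface_width, shape$chain_width)
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("infeasible shape parameters: zone widths must be positive")

  z <- seq(0, h, length.out = shape$n_grid)
  B_H <- .cos_bump(z, hc, shape$head_width)
  B_I <- .cos_bump(z, z0, shape$interface_width)
  B_C <- .cos_bump(z, cc, shape$chain_width)
  # normalise to unit zeroth moment under the trapezoid rule
  for (nm in c("B_H", "B_I", "B_C")) {
    b <- get(nm)
    s <- .trapz(z, b)
    if (s <= 1e-12)
      stop("infeasible shape parameters: zone '", nm,
           "' has no support inside the monolayer")
    assign(nm, b / s)
  }
  m_H <- .moment1(z, B_H, z0)
  m_I <- .moment1(z, B_I, z0)
  m_C <- .moment1(z, B_C, z0)
  if (abs(m_H - m_I) < 1e-9 || abs(m_I - m_C) < 1e-9 || abs(m_H - m_C) < 1e-9)
    stop("infeasible shape parameters: degenerate zone lever arms, ",
         "the moment constraint cannot be satisfied")

  # unit-tension basis (zero moment): headgroup/chain pair
  a_H <- -m_C / (m_H - m_C)
  a_C <- m_H / (m_H - m_C)
  b_gamma <- a_H * B_H + a_C * B_C
  # unit-moment basis (zero tension); tau(B) = -m(B)
  pair_HI <- (B_I - B_H) / (m_H - m_I)
  pair_CI <- (B_C - B_I) / (m_I - m_C)
  b_tau <- shape$w_head * pair_HI + (1 - shape$w_head) * pair_CI
  # zero-tension zero-moment frustration: pressure at heads and chains,
  # tension at the interface
  v <- -c(m_I - m_C, m_C - m_H, m_H - m_I)
  f_frust <- v[1] * B_H + v[2] * B_I + v[3] * B_C
  pk <- max(abs(f_frust))
  if (pk > 0) f_frust <- f_frust / pk

  sigma <- shape$frustration_amp * f_frust + gamma * b_gamma + tau * b_tau
  structure(list(z_grid = z, sigma = sigma, z0 = z0, h = h,
                 gamma = gamma, tau = tau),
            class = "stress_profile")
}

#' Integral moments of a stress profile
#'
#' @param p a `stress_profile` (or any list with `z_grid`, `sigma`, `z0`).
#' @return named numeric vector `c(gamma =, tau =)`: the lateral tension
#'   (zeroth moment, kT nm^-2) and bending moment
#'   `tau = -\int (z - z0) sigma dz` (kT nm^-1).
#' @export
profile_moments <- function(p) {
  z <- p$z_grid
  if (any(diff(z) <= 0)) stop("z_grid must be strictly increasing")
  c(gamma = .trapz(z, p$sigma),
    tau = -.moment1(z, p$sigma, p$z0))
}

#' Evaluate a stress profile at arbitrary depths
#'
#' Linear interpolation on the profile grid; zero outside `[0, h]`.
#'
#' @param p a `stress_profile`.
#' @param z depths in the monolayer's own frame, nm.
#' @return stress values, kT nm^-3.
#' @export
profile_at <- function(p, z) {
  out <- stats::approx(p$z_grid, p$sigma, xout = z,
                       yleft = 0, yright = 0)$y
  out[is.na(out)] <- 0
  out
}

#' @export
print.stress_profile <- function(x, ...) {
  m <- profile_moments(x)
  cat("Trans-monolayer stress profile: h =", x$h, "nm, z0 =",
      format(x$z0, digits = 4), "nm\n")
  cat("  gamma =", format(m["gamma"], digits = 6), "kT/nm^2,  tau =",
      format(m["tau"], digits = 6), "kT/nm\n")
  invisible(x)
}

#' Depth-dependent elastic moduli of a monolayer
#'
#' Two-zone Young's modulus profile (softer acyl chains below, stiffer
#' headgroup/interface region above a break depth) with uniform Poisson
#' ratio.  The zone ratio is fixed by requiring the neutral plane (where
#' stretching and bending decouple, `\int E (z - z0) dz = 0`) to sit at
#' `z0`, and the overall scale by calibrating the plane-strain bending
#' stiffness `\int E (z - z0)^2 dz / (1 - nu^2)` to the monolayer bending
#' modulus `kappa`.
#'
#' @param spec a [monolayer_spec()].
#' @param nu Poisson ratio (< 0.5), default 0.49 (near-incompressible).
#' @param z_break zone break depth, nm; default `h/2`.
#' @param n_grid grid resolution of the tabulated profile.
#' @return Object of class `moduli_profile` with fields `z_grid`, `youngs`,
#'   `poisson`, `z_break`, `E_tail`, `E_head`, `z0`, `h`.
#' @export
moduli_profile <- function(spec, nu = 0.49, z_break = spec$h / 2,
                           n_grid = 401) {
  stopifnot(inherits(spec, "monolayer_spec"))
  if (nu >= 0.5) stop("poisson ratio must be strictly below 0.5")
  h <- spec$h; z0 <- spec$z0
  if (z_break <= 0 || z_break >= h) stop("z_break must lie inside (0, h)")
  I1 <- z_break^2 / 2 - z0 * z_break
  I2 <- (h^2 - z_break^2) / 2 - z0 * (h - z_break)
  if (abs(I2) < 1e-12 || -I1 / I2 <= 0)
    stop("z_break incompatible with the neutral-plane position z0")
  ratio <- -I1 / I2                         # E_head / E_tail
  J1 <- ((z_break - z0)^3 - (0 - z0)^3) / 3
  J2 <- ((h - z0)^3 - (z_break - z0)^3) / 3
  E_tail <- spec$kappa * (1 - nu^2) / (J1 + ratio * J2)
  E_head <- ratio * E_tail
  z <- seq(0, h, length.out = n_grid)
  youngs <- ifelse(z > z_break, E_head, E_tail)
  structure(list(z_grid = z, youngs = youngs, poisson = nu,
                 z_break = z_break, E_tail = E_tail, E_head = E_head,
                 z0 = z0, h = h, kappa = spec$kappa),
            class = "moduli_profile")
}

#' Young's modulus at bilayer (lab-frame) depths
#'
#' The bilayer occupies `[-h, h]`; both monolayers share the moduli profile
#' mirrored about the midplane.
#'
#' @param mp a [moduli_profile()].
#' @param z_lab lab-frame depths, nm.
#' @return Young's modulus values, kT nm^-3.
#' @export
moduli_at <- function(mp, z_lab) {
  zeta <- abs(z_lab)
  ifelse(zeta > mp$z_break, mp$E_head, mp$E_tail)
}

#' Integrated plane-strain bending stiffness of a moduli profile
#'
#' @param mp a [moduli_profile()].
#' @return Bending stiffness `\int E (z-z0)^2 dz / (1 - nu^2)`, kT.
#' @export
bending_stiffness <- function(mp) {
  .trapz(mp$z_grid, mp$youngs * (mp$z_grid - mp$z0)^2) / (1 - mp$poisson^2)
}

#' Elastic stress profile of a mechanically strained monolayer
#'
#' The lateral stress carried by a monolayer whose material is strained as
#' `eps_xx(z) = strain0 + curvature * (z - z_neutral)` (plane strain):
#' `sigma(z) = E(z)/(1 - nu^2) * eps_xx(z)`.  This is the stress-profile
#' shape of the mechanically generated states (bending by external torque,
#' lateral stretching), as opposed to the composition-driven three-zone
#' modulation of [build_stress_profile()].
#'
#' @param moduli a [moduli_profile()].
#' @param strain0 uniform lateral strain component.
#' @param curvature bending strain gradient, nm^-1 (monolayer own frame,
#'   `z` outward).
#' @param z_neutral neutral depth of the bending strain, nm.  The neutral
#'   plane `z0` for a monolayer free to exchange lipids with a reservoir;
#'   `0` (the bilayer midplane) for bending at conserved per-monolayer
#'   lipid number, where the geometric area change at distance `z` from the
#'   midplane translates directly into material strain.
#' @param n_grid grid resolution.
#' @return A `stress_profile`.
#' @export
elastic_stress_profile <- function(moduli, strain0 = 0, curvature = 0,
                                   z_neutral = moduli$z0, n_grid = 2001) {
  h <- moduli$h
  zb <- moduli$z_break
  # resolve the modulus jump at the zone break so that the piecewise-linear
  # interpolant (and hence the integral moments) capture it exactly
  z <- sort(unique(c(seq(0, h, length.out = n_grid),
                     max(0, zb - 1e-9), min(h, zb + 1e-9))))
  Ep <- ifelse(z > zb, moduli$E_head, moduli$E_tail) /
    (1 - moduli$poisson^2)
  sigma <- Ep * (strain0 + curvature * (z - z_neutral))
  p <- structure(list(z_grid = z, sigma = sigma, z0 = moduli$z0, h = h,
                      gamma = NA_real_, tau = NA_real_),
                 class = "stress_profile")
  m <- profile_moments(p)
  p$gamma <- unname(m["gamma"]); p$tau <- unname(m["tau"])
  p
}

#' Sum of stress profiles
#'
#' @param p1,p2 `stress_profile` objects on the same monolayer.
#' @return Their pointwise sum (evaluated on the grid of `p1`).
#' @export
add_profiles <- function(p1, p2) {
  out <- p1
  out$sigma <- p1$sigma + profile_at(p2, p1$z_grid)
  m <- profile_moments(out)
  out$gamma <- unname(m["gamma"]); out$tau <- unname(m["tau"])
  out
}

#' Zero stress profile
#'
#' @param h monolayer thickness, nm.
#' @param z0 neutral plane, nm.
#' @param n_grid grid resolution.
#' @return A `stress_profile` with `sigma == 0`.
#' @export
zero_profile <- function(h = 2, z0 = 2 * h / 3, n_grid = 2001) {
  z <- seq(0, h, length.out = n_grid)
  structure(list(z_grid = z, sigma = numeric(n_grid), z0 = z0, h = h,
                 gamma = 0, tau = 0),
            class = "stress_profile")
}

#' Homogeneous moduli (verification fixtures)
#'
#' A `moduli_profile` with a single uniform Young's modulus, used by the
#' closed-form solver fixtures (uniform-tension slab, pure-bending plate).
#'
#' @param E Young's modulus, kT nm^-3.
#' @param nu Poisson ratio.
#' @param h monolayer thickness, nm.
#' @return A `moduli_profile`.
#' @export
uniform_moduli <- function(E, nu = 0.3, h = 2) {
  z <- seq(0, h, length.out = 101)
  structure(list(z_grid = z, youngs = rep(E, 101), poisson = nu,
                 z_break = h / 2, E_tail = E, E_head = E,
                 z0 = h / 2, h = h,
                 kappa = E * h^3 / (12 * (1 - nu^2))),
            class = "moduli_profile")
}

#' Export a stress profile as CSV
#'
#' @param p a `stress_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(p, path) {
  utils::write.csv(data.frame(z = p$z_grid, sigma = p$sigma), path,
                   row.names = FALSE)
  invisible(path)
}
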