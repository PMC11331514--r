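#' Local dielectric saturation model (linear permittivity ramp)
#'
#' Defines the distance-dependent relative permittivity used in the modified
#' restricted primitive model: \eqn{\epsilon_r(r)} equals the saturated
#' contact value \code{eps_c} for separations up to the contact distance
#' \code{d}, rises linearly to the bulk solvent value \code{eps_b} across a
#' solvent-layer thickness \code{delta}, and stays at \code{eps_b} beyond
#' \code{d + delta}. Setting \code{eps_c == eps_b} recovers the classic
#' uniform-permittivity RPM, which serves as the comparison mode.
#'
#' @param eps_c contact (saturated) relative permittivity; default 23.
#' @param eps_b bulk solvent relative permittivity; default 78.3.
#' @param delta ramp thickness in Angstrom (hydration-layer width); default 3.
#' @param d hard-sphere contact distance in Angstrom; default 3.
#' @return an object of class \code{dielectric_ramp}.
#' @examples
#' m <- dielectric_ramp()
#' epsilon_r(c(3, 4.5, 6), m)
#' @export
dielectric_ramp <- function(eps_c = 23, eps_b = 78.3, delta = 3, d = 3) {
  stopifnot(is.numeric(eps_c), is.numeric(eps_b), is.numeric(delta), is.numeric(d))
  if (eps_c < 1) stop("eps_c must be >= 1")
  if (eps_c > eps_b) stop("eps_c must not exceed eps_b")
  if (delta <= 0) stop("delta must be positive")
  if (d <= 0) stop("hard-sphere diameter d must be positive")
  structure(list(eps_c = eps_c, eps_b = eps_b, delta = delta, d = d),
            class = "dielectric_ramp")
}

#' @export
print.dielectric_ramp <- function(x, ...) {
  cat(sprintf(
    "Dielectric ramp: eps_c = %g at contact (d = %g A) -> eps_b = %g beyond %g A\n",
    x$eps_c, x$d, x$eps_b, x$d + x$delta))
  if (x$eps_c == x$eps_b) cat("  (uniform-permittivity RPM mode)\n")
  invisible(x)
}

#' Distance-dependent relative permittivity
#'
#' @param r ion-ion separation(s) in Angstrom; values below the contact
#'   distance return \code{eps_c} (irrelevant under the hard core but defined).
#' @param model a \code{\link{dielectric_ramp}} object.
#' @return permittivity value(s), continuous and nondecreasing in \code{r}.
#' @export
epsilon_r <- function(r, model) {
  stopifnot(inherits(model, "dielectric_ramp"))
  if (any(r < 0)) stop("negative separation: invalid geometry")
  frac <- pmin(1, pmax(0, (r - model$d) / model$delta))
  model$eps_c + (model$eps_b - model$eps_c) * frac
}

#' Bjerrum length
#'
#' Separation at which two unit charges interact with thermal energy
#' \eqn{k_B T}: \eqn{l_B = e_0^2 / (4 \pi \epsilon_0 \epsilon k_B T)}.
#'
#' @param eps relative permittivity (>= 1).
#' @param temperature temperature in K.
#' @return Bjerrum length in Angstrom.
#' @examples
#' bjerrum_length(78.3, 298)  # ~7.16 A in water at room temperature
#' @export
bjerrum_length <- function(eps, temperature = 298) {
  if (any(eps <= 0)) stop("permittivity must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  lb_m <- .codata$e0^2 / (4 * pi * .codata$eps0 * eps * .codata$kB * temperature)
  lb_m * 1e10
}

#' Debye screening length of a 1:1 electrolyte
#'
#' \eqn{\lambda_D = (8 \pi l_B n)^{-1/2}} with \eqn{n} the number density of
#' each ionic species; proportional to \eqn{c^{-1/2}}.
#'
#' @param c salt concentration in mol/L.
#' @param eps relative permittivity used for the Bjerrum length.
#' @param temperature temperature in K.
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(0.05)  # ~13.6 A
#' @export
debye_length <- function(c, eps = 78.3, temperature = 298) {
  if (any(c <= 0)) stop("concentration must be positive")
  n <- molar_to_density(c)
  1 / sqrt(8 * pi * bjerrum_length(eps, temperature) * n)
}

#' Pair interaction energy of two ions
#'
#' Charged hard spheres with a distance-dependent permittivity:
#' \eqn{\beta u(r) = z_i z_j \, l_B(\epsilon_r(r)) / r} for \eqn{r \ge d},
#' and \code{Inf} (hard-core sentinel, never an error) for \eqn{r < d}.
#' With \code{eps_c == eps_b} this is exactly the uniform-permittivity RPM.
#'
#' @param r separation(s) in Angstrom.
#' @param zi,zj ion valences in units of e0.
#' @param model a \code{\link{dielectric_ramp}} object.
#' @param temperature temperature in K.
#' @return energy in units of \eqn{k_B T}.
#' @examples
#' m <- dielectric_ramp()
#' pair_energy(3, +1, -1, m)   # contact ion pair, ~ -8.1 kT
#' @export
pair_energy <- function(r, zi, zj, model, temperature = 298) {
  stopifnot(inherits(model, "dielectric_ramp"))
  if (any(r < 0)) stop("negative separation: invalid geometry")
  u <- zi * zj * bjerrum_length(epsilon_r(r, model), temperature) / r
  u[r < model$d] <- Inf
  u
}
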