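# physical constants (CGS)
.kB <- 1.380649e-16      # erg/K
.R_gas <- 8.31446261815e7 # erg/mol/K
.N_A <- 6.02214076e23
.S_unit <- 1e-13          # 1 Svedberg in seconds
# standard water at 20 C, the conventional reference for s20,w
.rho_w20 <- 0.998234      # g/mL
.eta_w20 <- 0.010020      # poise

#' Hydrodynamic solution parameters
#'
#' Buffer density/viscosity, partial specific volume, temperature and rotor
#' speed for sedimentation-velocity analysis. The defaults are the dilute
#' potassium phosphate buffer conditions of the C-phycocyanin experiments
#' this package models (rho = 1.00980 g/mL, eta = 0.01029 P,
#' vbar = 0.73149 mL/g, 20 C, 60,000 rpm).
#'
#' @param rho solution density, g/mL.
#' @param eta solution viscosity, poise.
#' @param vbar protein partial specific volume, mL/g.
#' @param temperature K.
#' @param rotor_rpm rotor speed, revolutions per minute.
#' @return a `hydro_params` list; `omega2` (rad^2/s^2) is precomputed.
#' @export
hydro_params <- function(rho = 1.00980, eta = 0.01029, vbar = 0.73149,
                         temperature = 293.15, rotor_rpm = 60000) {
  stopifnot(rho > 0, eta > 0, vbar > 0, temperature > 0, rotor_rpm >= 0)
  if (1 - vbar * rho == 0) stop("buoyancy term (1 - vbar*rho) is zero")
  structure(list(rho = rho, eta = eta, vbar = vbar,
                 temperature = temperature, rotor_rpm = rotor_rpm,
                 omega2 = (rotor_rpm * 2 * pi / 60)^2),
            class = "hydro_params")
}

#' @export
print.hydro_params <- function(x, ...) {
  cat(sprintf("<hydro_params> rho %.5f g/mL, eta %.5f P, vbar %.5f mL/g, T %.2f K, %g rpm\n",
              x$rho, x$eta, x$vbar, x$temperature, x$rotor_rpm))
  invisible(x)
}

#' Standardize a sedimentation coefficient to water at 20 C
#'
#' `s20w = s_obs * (eta_buffer / eta_w20) * (1 - vbar*rho_w20) /
#' (1 - vbar*rho_buffer)` with the conventional standard-water constants
#' rho = 0.998234 g/mL and eta = 0.010020 P.
#'
#' @param s_obs observed sedimentation coefficient(s), Svedberg.
#' @param buffer a [hydro_params()].
#' @param vbar partial specific volume, mL/g (defaults to the buffer's).
#' @return s20,w in Svedberg.
#' @export
s20w_correction <- function(s_obs, buffer = hydro_params(),
                            vbar = buffer$vbar) {
  if (1 - vbar * buffer$rho <= 0)
    stop("(1 - vbar*rho) <= 0: particle is not denser than the solvent")
  s_obs * (buffer$eta / .eta_w20) *
    (1 - vbar * .rho_w20) / (1 - vbar * buffer$rho)
}

#' Diffusion coefficient from s and the frictional ratio
#'
#' The hydrodynamic scaling used by continuous c(s) analysis:
#' `D(s) = (sqrt(2)/(18*pi)) * kT * s^(-1/2) * (eta * f_ratio)^(-3/2) *
#' ((1 - vbar*rho) / vbar)^(1/2)` (CGS), i.e. every species shares one
#' frictional ratio f/f0.
#'
#' @param s sedimentation coefficient(s), Svedberg.
#' @param f_ratio frictional ratio f/f0 (>= 1).
#' @param buffer a [hydro_params()].
#' @param vbar partial specific volume, mL/g.
#' @return D in cm^2/s.
#' @export
diffusion_coefficient <- function(s, f_ratio, buffer = hydro_params(),
                                  vbar = buffer$vbar) {
  if (any(f_ratio < 1)) stop("f_ratio < 1 is unphysical")
  sqrt(2) / (18 * pi) * .kB * buffer$temperature *
    (s * .S_unit)^(-0.5) * (buffer$eta * f_ratio)^(-1.5) *
    ((1 - vbar * buffer$rho) / vbar)^0.5
}

#' Molecular weight from the Svedberg equation
#'
#' Solves the sphere-plus-frictional-ratio model for the molar mass:
#' `M^(2/3) = N_A * s * f_ratio * 6*pi*eta * (3*vbar/(4*pi*N_A))^(1/3) /
#' (1 - vbar*rho)`, then the diffusion coefficient from the Svedberg relation
#' `D = s*R*T / (M*(1 - vbar*rho))`.
#'
#' @param s_obs observed sedimentation coefficient(s), Svedberg.
#' @param f_ratio frictional ratio f/f0 (>= 1).
#' @param buffer a [hydro_params()].
#' @param vbar partial specific volume, mL/g.
#' @param loading optional loading (signal units) carried through.
#' @return a data frame of species estimates: `s_obs` (S), `s_20w` (S),
#'   `D` (cm^2/s), `M` (Da), `loading`.
#' @export
svedberg_mass <- function(s_obs, f_ratio, buffer = hydro_params(),
                          vbar = buffer$vbar, loading = NA_real_) {
  if (any(f_ratio < 1)) stop("f_ratio < 1 is unphysical")
  if (1 - vbar * buffer$rho <= 0)
    stop("(1 - vbar*rho) <= 0: particle is not denser than the solvent")
  m23 <- .N_A * (s_obs * .S_unit) * f_ratio * 6 * pi * buffer$eta *
    (3 * vbar / (4 * pi * .N_A))^(1 / 3) / (1 - vbar * buffer$rho)
  M <- m23^(3 / 2)
  D <- (s_obs * .S_unit) * .R_gas * buffer$temperature /
    (M * (1 - vbar * buffer$rho))
  data.frame(s_obs = s_obs, s_20w = s20w_correction(s_obs, buffer, vbar),
             D = D, M = M, loading = loading)
}

#' Sedimentation coefficient of a sphere of mass M
#'
#' Inverse of [svedberg_mass()] at a given frictional ratio; used for
#' round-trip checks and for placing expected oligomer positions.
#'
#' @param M molar mass, Da.
#' @param f_ratio frictional ratio f/f0.
#' @param buffer a [hydro_params()].
#' @param vbar partial specific volume, mL/g.
#' @return s in Svedberg.
#' @export
sphere_s <- function(M, f_ratio = 1, buffer = hydro_params(),
                     vbar = buffer$vbar) {
  M^(2 / 3) * (1 - vbar * buffer$rho) /
    (.N_A * f_ratio * 6 * pi * buffer$eta *
       (3 * vbar / (4 * pi * .N_A))^(1 / 3)) / .S_unit
}

#' C-phycocyanin concentration from a UV-vis spectrum
#'
#' The standard two-wavelength assay:
#' `concentration (mg/mL) = (A615 - 0.474 * A652) / 5.34`.
#'
#' @param a615,a652 absorbances at 615 and 652 nm.
#' @return concentration in mg/mL. Negative results (blank-subtraction
#'   artifacts) are returned with a warning.
#' @export
cpc_concentration <- function(a615, a652) {
  if (any(a615 < 0) || any(a652 < 0)) stop("absorbances must be non-negative")
  conc <- (a615 - 0.474 * a652) / 5.34
  if (any(conc < 0))
    warning("negative concentration (blank-subtraction artifact)", call. = FALSE)
  conc
}
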