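# Internal unit system: Hartree atomic units (hbar = 1, m_e = 1, bohr = 1).
# All interfaces speak angstrom / eV / fs / amu / kelvin; conversions are
# centralized here so no other file contains a physical constant.

.codata <- list(
  bohr_angstrom = 0.529177210903,   # 1 bohr in angstrom
  hartree_ev    = 27.211386245988,  # 1 hartree in eV
  autime_fs     = 2.4188843265857e-2, # 1 atomic time unit in fs
  amu_me        = 1822.888486209,   # 1 amu in electron masses
  kb_ev_k       = 8.617333262e-5,   # Boltzmann constant, eV/K
  hc_ev_nm      = 1239.841984332    # h*c, eV * nm
)

#' Unit system used by the simulator
#'
#' The simulator works internally in Hartree atomic units (\eqn{\hbar = 1});
#' user-facing interfaces use angstrom, eV, fs, amu and kelvin. This object
#' collects the conversion factors and fundamental constants so every
#' conversion in the package goes through one table.
#'
#' @return A list of class `unit_system` with components `hbar`, `kb`
#'   (atomic units, hartree/K), and the conversion factors
#'   `bohr_angstrom`, `hartree_ev`, `autime_fs`, `amu_me`,
#'   `velocity_angstrom_fs` (angstrom/fs per atomic velocity unit) and
#'   `hc_ev_nm`.
#' @examples
#' u <- unit_system()
#' u$hartree_ev
#' @export
unit_system <- function() {
  structure(
    list(
      hbar = 1.0,
      kb = .codata$kb_ev_k / .codata$hartree_ev,
      bohr_angstrom = .codata$bohr_angstrom,
      hartree_ev = .codata$hartree_ev,
      autime_fs = .codata$autime_fs,
      amu_me = .codata$amu_me,
      velocity_angstrom_fs = .codata$bohr_angstrom / .codata$autime_fs,
      hc_ev_nm = .codata$hc_ev_nm
    ),
    class = "unit_system"
  )
}

.unit_factor <- function(quantity) {
  u <- unit_system()
  switch(quantity,
    length   = u$bohr_angstrom,
    energy   = u$hartree_ev,
    time     = u$autime_fs,
    mass     = 1 / u$amu_me,
    velocity = u$velocity_angstrom_fs,
    force    = u$hartree_ev / u$bohr_angstrom,
    rlang::abort(paste0("unknown quantity '", quantity, "'"),
                 class = "rpdyn_unit_error")
  )
}

#' Convert between interface units and internal atomic units
#'
#' Interface units are angstrom (`length`), eV (`energy`), fs (`time`),
#' amu (`mass`), angstrom/fs (`velocity`) and eV/angstrom (`force`).
#'
#' @param x Numeric vector, matrix or array.
#' @param quantity One of `"length"`, `"energy"`, `"time"`, `"mass"`,
#'   `"velocity"`, `"force"`.
#' @return `x` converted to atomic units (`to_au`) or interface units
#'   (`from_au`), preserving shape.
#' @examples
#' from_au(to_au(1.5, "length"), "length") # 1.5
#' @export
to_au <- function(x, quantity) x / .unit_factor(quantity)

#' @rdname to_au
#' @export
from_au <- function(x, quantity) x * .unit_factor(quantity)

#' Photon energy of a laser wavelength
#'
#' @param lambda_nm Wavelength in nm.
#' @return Photon energy \eqn{h c / \lambda} in eV.
#' @examples
#' photon_energy_ev(266) # ~4.66 eV, a common UV detachment wavelength
#' @export
photon_energy_ev <- function(lambda_nm) {
  stopifnot(is.numeric(lambda_nm), all(lambda_nm > 0))
  unit_system()$hc_ev_nm / lambda_nm
}

#' Electron binding energy from photoelectron kinetic energy
#'
#' In a photodetachment measurement `E_b = h nu - eKE`: the photon energy
#' minus the kinetic energy of the detached electron.
#'
#' @param hnu_ev Photon energy, eV.
#' @param eke_ev Photoelectron kinetic energy, eV.
#' @return Binding energy in eV.
#' @export
eb_from_eke <- function(hnu_ev, eke_ev) {
  stopifnot(is.numeric(hnu_ev), is.numeric(eke_ev))
  hnu_ev - eke_ev
}

#' Thermodynamic context (temperature and inverse temperature)
#'
#' Either the temperature in kelvin or the inverse temperature `beta` in
#' atomic units (1/hartree) may be given; the other is derived through
#' \eqn{\beta = 1/k_B T}. Supplying `beta` directly is convenient for
#' model-unit studies (e.g. a harmonic oscillator with
#' \eqn{m = \omega = \hbar = 1}).
#'
#' @param temperature Temperature in K.
#' @param beta Inverse temperature in 1/hartree.
#' @return A list of class `thermo_context` with fields `temperature` (K),
#'   `beta` (1/hartree) and `kT` (hartree).
#' @examples
#' thermo_context(temperature = 300)
#' thermo_context(beta = 3) # model units
#' @export
thermo_context <- function(temperature = NULL, beta = NULL) {
  kb <- unit_system()$kb
  if (is.null(temperature) && is.null(beta)) {
    rlang::abort("supply `temperature` or `beta`", class = "rpdyn_unit_error")
  }
  if (!is.null(temperature)) {
    stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
    beta_derived <- 1 / (kb * temperature)
    if (!is.null(beta) && abs(beta - beta_derived) > 1e-9 * beta_derived) {
      rlang::abort("`temperature` and `beta` are inconsistent",
                   class = "rpdyn_unit_error")
    }
    beta <- beta_derived
  } else {
    stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
    temperature <- 1 / (kb * beta)
  }
  structure(
    list(temperature = temperature, beta = beta, kT = 1 / beta),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %.6g K, beta = %.6g /hartree\n",
              x$temperature, x$beta))
  invisible(x)
}
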