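# Quasi-harmonic configurational entropy from a covariance model, and the
# bound-minus-unbound entropy change -T*dS.

new_entropy_result <- function(method, S, temperature, n_retained, n_discarded,
                               minus_T_dS = NULL) {
  structure(
    list(method = method, S = S, minus_T_dS = minus_T_dS,
         temperature = temperature, n_modes_retained = n_retained,
         discarded_modes = n_discarded),
    class = "entropy_result"
  )
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("entropy [%s] S = %.6g kcal/(mol K) at %g K (%d modes, %d discarded)\n",
              x$method, x$S, x$temperature, x$n_modes_retained, x$discarded_modes))
  if (!is.null(x$minus_T_dS)) cat(sprintf("  -T dS = %.4f kcal/mol\n", x$minus_T_dS))
  invisible(x)
}

#' Quasi-harmonic configurational entropy
#'
#' Treats the fluctuations captured by a covariance model as effective
#' harmonic modes and sums per-mode entropies.
#'
#' Methods (eigenvalues lambda of the mass-weighted covariance, amu A^2):
#' * `andricioaei_karplus` (default): quantum quasi-harmonic estimate.
#'   Each retained mode has frequency omega = sqrt(k_B T / lambda) and
#'   alpha = hbar omega / (k_B T); its entropy contribution is
#'   k_B \[ alpha/(e^alpha - 1) - ln(1 - e^-alpha) \].
#' * `schlitter`: determinant upper bound
#'   S = (k_B/2) sum ln(1 + k_B T e^2 lambda / hbar^2) with e Euler's number;
#'   always >= the quantum quasi-harmonic value.
#' * `classical_gaussian`: (k_B/2) ln((2 pi e)^d det C). The argument of the
#'   log carries units, so the value is meaningful only inside
#'   [entropy_change()] where the unit-bearing factors cancel; it accepts
#'   unweighted covariances.
#'
#' Modes with eigenvalue <= `eig_floor` are discarded (post-fit residual
#' rigid-body modes would otherwise inject spurious contributions).
#'
#' @param model `covariance_model`; must be mass-weighted for the two
#'   quantum methods
#' @param thermo [thermo_params()]
#' @param method estimator tag
#' @param eig_floor eigenvalue floor, amu A^2 (A^2 for classical_gaussian)
#' @return `entropy_result` with `S` in kcal/(mol K)
#' @export
qh_entropy <- function(model, thermo = thermo_params(),
                       method = c("andricioaei_karplus", "schlitter",
                                  "classical_gaussian"),
                       eig_floor = 1e-8) {
  stopifnot(inherits(model, "covariance_model"))
  method <- match.arg(method)
  stopifnot(eig_floor >= 0)
  if (method %in% c("andricioaei_karplus", "schlitter") && !model$mass_weighted) {
    validation_error(method, " requires a mass-weighted covariance model")
  }
  lambda <- model$eigenvalues
  keep <- lambda > eig_floor
  n_ret <- sum(keep)
  n_disc <- length(lambda) - n_ret
  if (n_ret == 0) validation_error("no retained modes: all eigenvalues <= floor")
  lam <- lambda[keep]
  kB <- thermo$k_B
  TT <- thermo$temperature
  kT_int <- kB * TT * thermo$kcal_to_internal # amu A^2 / ps^2
  S <- switch(method,
    andricioaei_karplus = {
      omega <- sqrt(kT_int / lam)
      alpha <- thermo$hbar * omega / kT_int
      kB * sum(alpha / (exp(alpha) - 1) - log(1 - exp(-alpha)))
    },
    schlitter = {
      (kB / 2) * sum(log(1 + kT_int * exp(1)^2 * lam / thermo$hbar^2))
    },
    classical_gaussian = {
      (kB / 2) * sum(log(2 * pi * exp(1)) + log(lam))
    }
  )
  new_entropy_result(method, S, TT, n_ret, n_disc)
}

#' Configurational entropy change on binding
#'
#' dS = S_complex - S_apo - S_ligand, with the entropic free-energy term
#' -T dS reported at the bookkeeping temperature. All three inputs must come
#' from the same method and temperature. For the `classical_gaussian` method
#' the retained dimensionalities must satisfy
#' dim(complex) = dim(apo) + dim(ligand), the only case in which the
#' unit-bearing log factors cancel.
#'
#' @param S_complex,S_apo,S_ligand `entropy_result`s for the bound complex,
#'   unbound protein and unbound ligand
#' @param thermo [thermo_params()]
#' @return `entropy_result` carrying dS (kcal/(mol K)) and `minus_T_dS`
#'   (kcal/mol)
#' @export
entropy_change <- function(S_complex, S_apo, S_ligand, thermo = thermo_params()) {
  parts <- list(S_complex, S_apo, S_ligand)
  stopifnot(all(vapply(parts, inherits, logical(1), "entropy_result")))
  methods <- vapply(parts, `[[`, character(1), "method")
  temps <- vapply(parts, `[[`, numeric(1), "temperature")
  if (length(unique(methods)) != 1) validation_error("entropy method mismatch: ", paste(methods, collapse = ", "))
  if (length(unique(temps)) != 1) validation_error("entropy temperature mismatch")
  if (methods[1] == "classical_gaussian") {
    dims <- vapply(parts, function(p) p$n_modes_retained, numeric(1))
    if (dims[1] != dims[2] + dims[3]) {
      validation_error(
        "classical_gaussian entropy change needs dim(complex) = dim(apo) + ",
        "dim(ligand); got ", dims[1], " vs ", dims[2], " + ", dims[3]
      )
    }
  }
  dS <- S_complex$S - S_apo$S - S_ligand$S
  TT <- thermo$temperature
  new_entropy_result(
    methods[1], dS, TT,
    S_complex$n_modes_retained,
    S_complex$discarded_modes,
    minus_T_dS = -TT * dS
  )
}
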