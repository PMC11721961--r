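# Kinetic core: transition-state-theory rates from activation barriers,
# conformational equilibrium constants, IC50 <-> binding-energy conversions,
# the composite potency descriptor 1/(Ki'*Ka'), and the allosteric
# Michaelis-Menten inhibition model.

#' Gas constant in kJ mol^-1 K^-1
#' @keywords internal
.R_KJ <- 8.314e-3

#' Boltzmann constant in kJ mol^-1 K^-1 (identical to the molar gas constant
#' when energies are per mole)
#' @keywords internal
.KB_KJ <- 8.314e-3

#' Transition-state-theory rate constant from an activation barrier
#'
#' Converts an activation free energy into a rate constant
#' \eqn{k = A \exp(-\Delta G^\ddagger / RT)}. The default prefactor is the
#' unit prefactor \eqn{A = 1\,s^{-1}}, so the rate is the bare Boltzmann
#' factor of the barrier; the Eyring prefactor \eqn{k_B T / h} is available
#' via \code{prefactor = "eyring"}. For a conformational switch whose
#' attempt frequency is unknown, the unit convention makes rates directly
#' comparable across systems while leaving absolute time scales undefined.
#'
#' @param dG_barrier activation free energy barrier, kJ/mol (non-negative).
#' @param temperature temperature in Kelvin (default 310).
#' @param prefactor `"unit"` (default, A = 1 s^-1) or `"eyring"`
#'   (A = kB*T/h s^-1).
#' @return rate constant in s^-1.
#' @examples
#' tst_rate(70.28)           # ~1.44e-12
#' tst_rate(0, 310)          # 1
#' @export
tst_rate <- function(dG_barrier, temperature = 310, prefactor = c("unit", "eyring")) {
  prefactor <- match.arg(prefactor)
  if (any(!is.finite(dG_barrier)) || any(dG_barrier < 0))
    stop("invalid-parameter: barrier must be finite and >= 0 kJ/mol")
  if (temperature <= 0) stop("invalid-parameter: temperature must be > 0 K")
  A <- if (prefactor == "unit") 1 else 1.380649e-23 * temperature / 6.62607015e-34
  A * exp(-dG_barrier / (.R_KJ * temperature))
}

#' Equilibrium constant between two conformational states
#'
#' \eqn{K = k_{active} / k_{inactive}}. With rates from [tst_rate()] at the
#' same temperature this equals \eqn{\exp(-(\Delta G^\ddagger_a -
#' \Delta G^\ddagger_i)/RT)} exactly (detailed balance).
#'
#' @param k_active activation rate, s^-1 (> 0).
#' @param k_inactive inactivation rate, s^-1 (> 0).
#' @return dimensionless equilibrium constant.
#' @export
equilibrium_constant <- function(k_active, k_inactive) {
  if (any(k_active <= 0) || any(k_inactive <= 0))
    stop("invalid-parameter: rates must be > 0")
  k_active / k_inactive
}

#' Experimental binding free energy from an IC50
#'
#' \eqn{\Delta G_{exp} = RT \ln(\mathrm{IC50})} with the IC50 expressed in
#' micromolar, returned in kJ/mol. An IC50 of 1 uM therefore maps to 0.
#'
#' @param ic50 half-maximal inhibitory concentration in micromolar (> 0).
#' @param temperature Kelvin (default 310).
#' @return free energy in kJ/mol (negative for sub-micromolar potency).
#' @export
dg_exp_from_ic50 <- function(ic50, temperature = 310) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("invalid-parameter: IC50 must be finite and > 0 uM")
  .R_KJ * temperature * log(ic50)
}

#' Inhibitor dissociation constant from a binding free energy
#'
#' Standard Boltzmann inversion \eqn{K_i' = \exp(\Delta G_{bind}/RT)} with the
#' binding free energy in kJ/mol and the dissociation constant in mol/L on a
#' 1 mol/L standard state. Offered as a conversion only; dissociation
#' constants measured independently should be supplied as-is downstream.
#'
#' @param dG_bind binding free energy, kJ/mol.
#' @param temperature Kelvin (default 310).
#' @return dissociation constant in mol/L.
#' @export
ki_from_binding_energy <- function(dG_bind, temperature = 310) {
  if (any(!is.finite(dG_bind))) stop("invalid-parameter: dG_bind must be finite")
  exp(dG_bind / (.R_KJ * temperature))
}

#' Composite potency descriptor 1/(Ki' * Ka')
#'
#' Joint thermodynamic-kinetic descriptor of an allosteric inhibitor:
#' the reciprocal product of the inhibitor dissociation constant in the
#' closed state and the active/inactive conformational equilibrium constant
#' of the bound enzyme. Large values combine tight binding with strong
#' suppression of the activating transition.
#'
#' @param ki_prime inhibitor dissociation constant, mol/L (> 0).
#' @param ka_prime conformational equilibrium constant, dimensionless (> 0).
#' @return descriptor in L/mol.
#' @export
composite_potency <- function(ki_prime, ka_prime) {
  if (any(ki_prime <= 0) || any(ka_prime <= 0))
    stop("invalid-parameter: Ki' and Ka' must be > 0")
  1 / (ki_prime * ka_prime)
}

#' Parameter set of the allosteric Michaelis-Menten model
#'
#' @param Vmax maximal velocity (rate units, > 0).
#' @param KM Michaelis constant (concentration units, > 0).
#' @param Ki,Ki_prime inhibitor dissociation constants for the free enzyme
#'   and the enzyme-substrate complex, mol/L (> 0). `Ki` only enters when the
#'   conventional mixed-inhibition form is requested (see
#'   [interaction_constants()]).
#' @param Ka,Ka_prime active/inactive conformational equilibrium constants of
#'   the apo and inhibitor-bound enzyme, dimensionless (> 0).
#' @return an object of class `allosteric_params`.
#' @export
allosteric_params <- function(Vmax, KM, Ki = Inf, Ki_prime, Ka, Ka_prime) {
  vals <- c(Vmax = Vmax, KM = KM, Ki = Ki, Ki_prime = Ki_prime,
            Ka = Ka, Ka_prime = Ka_prime)
  if (any(is.na(vals)) || any(vals <= 0))
    stop("invalid-parameter: all model parameters must be positive")
  structure(as.list(vals), class = "allosteric_params")
}

#' Interaction constants alpha and alpha' of the allosteric inhibition model
#'
#' In the default form,
#' \deqn{\alpha = 1 + [I]/K_i' + 1/K_a + [I]/(K_i' K_a'),\qquad
#'       \alpha' = 1 + [I]/K_i'.}
#' Relative to a non-allosteric mixed inhibitor, \eqn{\alpha} carries the two
#' extra terms \eqn{1/K_a} and \eqn{[I]/(K_i' K_a')} coupling the apparent
#' Michaelis constant to the conformational equilibrium. The
#' `"conventional"` form replaces the \eqn{[I]/K_i'} term in \eqn{\alpha} by
#' \eqn{[I]/K_i}, the textbook mixed-inhibition convention in which the
#' free-enzyme and complex dissociation constants differ.
#'
#' @param params an [allosteric_params()] object.
#' @param inhibitor_conc inhibitor concentration \eqn{[I]}, mol/L (>= 0).
#' @param form `"allosteric"` (default) or `"conventional"`.
#' @return list with elements `alpha` and `alpha_prime`.
#' @export
interaction_constants <- function(params, inhibitor_conc,
                                  form = c("allosteric", "conventional")) {
  form <- match.arg(form)
  stopifnot(inherits(params, "allosteric_params"))
  if (any(inhibitor_conc < 0)) stop("invalid-parameter: [I] must be >= 0")
  I <- inhibitor_conc
  free_term <- if (form == "allosteric") I / params$Ki_prime else I / params$Ki
  alpha <- 1 + free_term + 1 / params$Ka + I / (params$Ki_prime * params$Ka_prime)
  alpha_prime <- 1 + I / params$Ki_prime
  list(alpha = alpha, alpha_prime = alpha_prime)
}

#' Velocity of the allosterically inhibited enzyme reaction
#'
#' \eqn{V = V_{max}[S] / (\alpha K_M + \alpha' [S])}, the double-reciprocal
#' form \eqn{1/V = (K_M/V_{max})\,\alpha\,(1/[S]) + \alpha'/V_{max}} made
#' explicit. Reduces to the classical Michaelis-Menten hyperbola when
#' \eqn{[I] = 0} and \eqn{K_a \to \infty}.
#'
#' @param S substrate concentration (> 0); vectorized.
#' @param I inhibitor concentration, mol/L (>= 0).
#' @inheritParams interaction_constants
#' @return reaction velocity, same units as `Vmax`.
#' @export
velocity <- function(S, I, params, form = c("allosteric", "conventional")) {
  if (any(S <= 0)) stop("invalid-parameter: [S] must be > 0")
  ic <- interaction_constants(params, I, form = match.arg(form))
  params$Vmax * S / (ic$alpha * params$KM + ic$alpha_prime * S)
}

#' Apparent Michaelis-Menten parameters under inhibition
#'
#' \eqn{K_{M,app} = \alpha K_M / \alpha'} and
#' \eqn{V_{max,app} = V_{max}/\alpha'}.
#'
#' @inheritParams velocity
#' @return list with `KM_app` and `Vmax_app`.
#' @export
apparent_parameters <- function(params, I, form = c("allosteric", "conventional")) {
  ic <- interaction_constants(params, I, form = match.arg(form))
  list(KM_app = ic$alpha * params$KM / ic$alpha_prime,
       Vmax_app = params$Vmax / ic$alpha_prime)
}

#' Classify the inhibition mode from the interaction constants
#'
#' With \eqn{\alpha > \alpha' > 1} the inhibitor binds both the free enzyme
#' and the complex but prefers the free enzyme: mixed (noncompetitive)
#' inhibition. \eqn{\alpha \approx \alpha' > 1} is pure noncompetitive,
#' \eqn{\alpha > 1, \alpha' \approx 1} competitive-like, and
#' \eqn{\alpha \approx \alpha' \approx 1} no inhibition.
#'
#' @param alpha,alpha_prime interaction constants (>= 1).
#' @param tolerance equality tolerance for the comparisons (default 1e-6).
#' @return a character label; warns if `alpha < alpha_prime` beyond
#'   tolerance, which violates the model's premise.
#' @export
classify_inhibition <- function(alpha, alpha_prime, tolerance = 1e-6) {
  if (alpha < 1 - tolerance || alpha_prime < 1 - tolerance)
    stop("invalid-parameter: interaction constants must be >= 1")
  if (alpha < alpha_prime - tolerance)
    warning("model violation: alpha < alpha', inconsistent with allosteric inhibition")
  a1 <- abs(alpha - 1) <= tolerance
  p1 <- abs(alpha_prime - 1) <= tolerance
  eq <- abs(alpha - alpha_prime) <= tolerance
  if (a1 && p1) return("no inhibition")
  if (p1) return("competitive-like")
  if (eq) return("pure noncompetitive")
  "noncompetitive (mixed), prefers free enzyme"
}

#' Regression of experimental potency against the composite descriptor
#'
#' Ordinary least squares of \eqn{\Delta G_{exp}} on
#' \eqn{\log_{10}(1/(K_i' K_a'))} across a panel of inhibitors. Because the
#' exact transform behind any published correlation on this quantity is
#' rarely stated, the fitted statistics are reported, not asserted against
#' external values.
#'
#' @param records data frame with numeric columns `dG_exp` (kJ/mol) and
#'   `composite` (L/mol); rows with either missing are dropped.
#' @return list with `slope`, `intercept`, `r`, `r_squared`, `n`, and a
#'   `degenerate` flag set when the response or predictor has zero variance.
#' @export
potency_correlation <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("dG_exp", "composite") %in% names(records)))
  keep <- is.finite(records$dG_exp) & is.finite(records$composite) &
    records$composite > 0
  d <- records[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("insufficient-data: need >= 3 records with dG_exp and composite")
  x <- log10(d$composite)
  y <- d$dG_exp
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_squared = NA_real_, n = nrow(d), degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2, n = nrow(d), degenerate = FALSE)
}

#' End-point binding free energy bookkeeping
#'
#' Assembles the standard end-point decomposition
#' \eqn{\Delta G_{bind} = \Delta E_{vdw} + \Delta E_{ele} + \Delta G_{GB} +
#' \Delta G_{SA} - (-T\Delta S)} with the entropy term defaulting to zero
#' (conformational entropy omitted for structurally similar ligand series).
#'
#' @param dE_vdw,dE_ele,dG_GB,dG_SA component energies, kJ/mol.
#' @param entropy_term \eqn{-T\Delta S}, kJ/mol (default 0).
#' @return an `energy_decomposition` list including the total `dG_bind`.
#' @export
energy_decomposition <- function(dE_vdw, dE_ele, dG_GB, dG_SA, entropy_term = 0) {
  comps <- c(dE_vdw = dE_vdw, dE_ele = dE_ele, dG_GB = dG_GB, dG_SA = dG_SA,
             entropy_term = entropy_term)
  if (any(!is.finite(comps))) stop("invalid-parameter: all subterms must be finite")
  out <- as.list(comps)
  out$dG_bind <- dE_vdw + dE_ele + dG_GB + dG_SA - entropy_term
  structure(out, class = "energy_decomposition")
}

#' @rdname energy_decomposition
#' @param decomp an `energy_decomposition` object.
#' @export
mmgbsa_total <- function(decomp) {
  stopifnot(inherits(decomp, "energy_decomposition"))
  decomp$dG_bind
}

#' Nonpolar solvation term from a buried surface area
#'
#' \eqn{\Delta G_{SA} = \gamma \times \Delta SASA} with the surface-tension
#' coefficient \eqn{\gamma} defaulting to 0.02267 kJ mol^-1 A^-2.
#'
#' @param delta_sasa change in solvent-accessible surface area, A^2.
#' @param gamma surface tension coefficient, kJ mol^-1 A^-2.
#' @return nonpolar solvation free energy, kJ/mol.
#' @export
nonpolar_term <- function(delta_sasa, gamma = 0.02267) {
  gamma * delta_sasa
}

#' Kinetic table: barriers to rates, equilibrium and potency descriptors
#'
#' Derives, for each system, the activation and inactivation rate constants
#' (unit-prefactor TST), the conformational equilibrium constant
#' \eqn{K_a' = k_{active}/k_{inactive}}, the experimental binding free energy
#' from the IC50 where given, and the composite descriptor
#' \eqn{1/(K_i' K_a')} where the dissociation constant is given.
#'
#' @param systems data frame with columns `system`, `dG_active_barrier`,
#'   `dG_inactive_barrier` (kJ/mol), and optionally `Ki_prime` (mol/L),
#'   `IC50_uM` and/or `dG_exp` (kJ/mol).
#' @param temperature Kelvin (default 310).
#' @param prefactor passed to [tst_rate()].
#' @return data frame with derived columns `k_active`, `k_inactive`,
#'   `Ka_prime`, `dG_exp`, `composite`.
#' @seealso [allokin_table1()] for the packaged example input panel.
#' @export
kinetic_table <- function(systems, temperature = 310, prefactor = "unit") {
  stopifnot(is.data.frame(systems),
            all(c("system", "dG_active_barrier", "dG_inactive_barrier") %in%
                  names(systems)))
  out <- systems
  out$k_active <- tst_rate(systems$dG_active_barrier, temperature, prefactor)
  out$k_inactive <- tst_rate(systems$dG_inactive_barrier, temperature, prefactor)
  out$Ka_prime <- out$k_active / out$k_inactive
  if (!"dG_exp" %in% names(out)) out$dG_exp <- NA_real_
  if ("IC50_uM" %in% names(out)) {
    has <- is.finite(out$IC50_uM)
    out$dG_exp[has] <- dg_exp_from_ic50(out$IC50_uM[has], temperature)
  }
  out$composite <- NA_real_
  if ("Ki_prime" %in% names(out)) {
    has <- is.finite(out$Ki_prime) & out$Ki_prime > 0
    out$composite[has] <- composite_potency(out$Ki_prime[has], out$Ka_prime[has])
  }
  out
}

#' Packaged inhibitor panel of printed inputs
#'
#' Reads the shipped CSV of per-system inputs (activation and inactivation
#' barriers in kJ/mol, inhibitor dissociation constants in mol/L, IC50
#' values in micromolar where published as such, otherwise the published
#' binding free energy). Only input columns ship; every derived quantity is
#' recomputed at run time by [kinetic_table()].
#'
#' @return data frame of systems.
#' @export
allokin_table1 <- function() {
  path <- system.file("extdata", "table1_inputs.csv", package = "allokin")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
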