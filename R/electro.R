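# Transepithelial electrophysiology: TER, GHK dilution-potential charge
# selectivity, and the Kimizuka-Koketsu conductance-permeability relation.
#
# Conventions: potentials are apical minus basolateral in mV, blank values
# are subtracted before any inversion, TER is in ohm cm^2, permeabilities
# in cm/s, and the Kimizuka-Koketsu reference concentration is the
# symmetric-side NaCl (mM, converted internally to mol/cm^3).

#' A raw transepithelial measurement
#'
#' @param raw_resistance_ohm,blank_resistance_ohm measured resistance with
#'   the monolayer and of the blank filter (ohm).
#' @param raw_potential_mV,blank_potential_mV measured transepithelial
#'   potential (apical minus basolateral) and blank potential (mV).
#' @param area_cm2 filter membrane area (cm^2); 1.12 for a 12-mm insert.
#' @param apical,basolateral [ion_solution()]s bathing the two sides.
#' @param temperature_K measurement temperature.
#' @return list of class `electro_record`.
#' @export
electro_record <- function(raw_resistance_ohm, blank_resistance_ohm,
                           raw_potential_mV, blank_potential_mV,
                           area_cm2 = 1.12, apical = solution_a(),
                           basolateral = solution_b(),
                           temperature_K = 310.15) {
  stopifnot(area_cm2 > 0, raw_resistance_ohm > 0, blank_resistance_ohm >= 0)
  structure(list(raw_resistance_ohm = raw_resistance_ohm,
                 blank_resistance_ohm = blank_resistance_ohm,
                 raw_potential_mV = raw_potential_mV,
                 blank_potential_mV = blank_potential_mV,
                 area_cm2 = area_cm2, apical = apical,
                 basolateral = basolateral, temperature_K = temperature_K),
            class = "electro_record")
}

#' Transepithelial electrical resistance
#'
#' Blank-subtracted and area-scaled: `(raw - blank) * area`.
#' @param record an [electro_record()].
#' @return TER in ohm cm^2.
#' @examples
#' r <- electro_record(200, 100, 1, 0, area_cm2 = 1.12)
#' compute_ter(r)  # 112
#' @export
compute_ter <- function(record) {
  d <- record$raw_resistance_ohm - record$blank_resistance_ohm
  if (d <= 0)
    stop("raw resistance does not exceed blank resistance: ",
         "monolayer leakier than the blank filter is unphysical")
  d * record$area_cm2
}

#' Goldman-Hodgkin-Katz dilution potential (forward direction)
#'
#' For monovalent Na+, K+ and Cl- with permeabilities expressed relative to
#' P_Cl (`beta = P_Na/P_Cl`, `kappa = P_K/P_Cl`, K+ treated like Na+ by
#' default), the zero-current membrane potential of the apical compartment
#' relative to the basolateral one is
#' `V = (RT/F) ln[(beta Na_ap + kappa K_ap + Cl_bl) /
#'               (beta Na_bl + kappa K_bl + Cl_ap)]`.
#' Divalent cations contribute only through their chloride counter-ions.
#'
#' @param beta P_Na/P_Cl ratio (> 0).
#' @param apical,basolateral [ion_solution()]s.
#' @param temperature_K absolute temperature.
#' @param kappa P_K/P_Cl; default equal to `beta`.
#' @return potential in mV; exactly 0 for identical solutions.
#' @export
ghk_dilution_potential <- function(beta, apical, basolateral,
                                   temperature_K = 310.15, kappa = beta) {
  stopifnot(beta > 0, kappa > 0)
  if (same_solution(apical, basolateral)) return(0)
  num <- beta * apical$Na + kappa * apical$K + basolateral$Cl
  den <- beta * basolateral$Na + kappa * basolateral$K + apical$Cl
  rt_over_f_mV(temperature_K) * log(num / den)
}

# Attainable potential interval for a solution pair (Nernst limits).
ghk_potential_limits <- function(apical, basolateral, temperature_K = 310.15) {
  rtf <- rt_over_f_mV(temperature_K)
  sort(c(rtf * log(basolateral$Cl / apical$Cl),              # beta -> 0
         rtf * log((apical$Na + apical$K) /
                     (basolateral$Na + basolateral$K))))     # beta -> Inf
}

#' Invert a dilution potential into the P_Na/P_Cl ratio
#'
#' Closed-form inversion of [ghk_dilution_potential()] when K+ is tied to
#' Na+ (`kappa = beta`), otherwise bracketed root finding to a relative
#' tolerance of 1e-12 on beta.  The blank-corrected potential must lie
#' strictly between the two Nernst limits for the solution pair.
#'
#' @param record an [electro_record()]; alternatively pass a corrected
#'   potential via `potential_mV` together with `apical`/`basolateral`.
#' @param potential_mV blank-corrected potential (mV), used when `record`
#'   is missing.
#' @param apical,basolateral,temperature_K solution pair and temperature
#'   (taken from `record` when given).
#' @param kappa P_K/P_Cl; `NULL` (default) ties K+ to Na+.
#' @return beta = P_Na/P_Cl.
#' @export
ghk_ratio <- function(record = NULL, potential_mV = NULL,
                      apical = solution_a(), basolateral = solution_b(),
                      temperature_K = 310.15, kappa = NULL) {
  if (!is.null(record)) {
    potential_mV <- record$raw_potential_mV - record$blank_potential_mV
    apical <- record$apical
    basolateral <- record$basolateral
    temperature_K <- record$temperature_K
  }
  if (is.null(potential_mV)) stop("need a record or a corrected potential")
  lim <- ghk_potential_limits(apical, basolateral, temperature_K)
  if (potential_mV <= lim[1] || potential_mV >= lim[2])
    stop(sprintf(
      "potential %.6g mV outside the attainable interval (%.6g, %.6g) mV: beta unbounded",
      potential_mV, lim[1], lim[2]))
  rtf <- rt_over_f_mV(temperature_K)
  e <- exp(potential_mV / rtf)
  if (is.null(kappa)) {
    beta <- (e * apical$Cl - basolateral$Cl) /
      (apical$Na + apical$K - e * (basolateral$Na + basolateral$K))
    return(beta)
  }
  f <- function(lb) ghk_dilution_potential(exp(lb), apical, basolateral,
                                           temperature_K, kappa) - potential_mV
  r <- stats::uniroot(f, lower = log(1e-8), upper = log(1e8),
                      tol = 1e-15, maxiter = 2000L)
  exp(r$root)
}

#' Kimizuka-Koketsu permeability decomposition
#'
#' Converts TER plus the permeability ratio into absolute permeabilities:
#' the total ionic permeability is `P_Na + P_Cl = RT / (F^2 TER C)` with C
#' the symmetric-side NaCl concentration in mol/cm^3, split as
#' `P_Na = beta/(1+beta)` and `P_Cl = 1/(1+beta)` of the total.
#'
#' @param TER_ohm_cm2 blank-corrected TER (ohm cm^2).
#' @param beta P_Na/P_Cl.
#' @param reference_NaCl_mM reference NaCl concentration (mM; 140 for the
#'   standard Ringer).
#' @param temperature_K absolute temperature.
#' @return list with `P_Na_cm_s`, `P_Cl_cm_s`, `P_total_cm_s`.
#' @export
kimizuka_koketsu <- function(TER_ohm_cm2, beta, reference_NaCl_mM = 140,
                             temperature_K = 310.15) {
  stopifnot(TER_ohm_cm2 > 0, beta > 0, reference_NaCl_mM > 0)
  k <- physical_constants(temperature_K)
  C <- reference_NaCl_mM * 1e-6  # mM -> mol/cm^3
  total <- k$R_J_mol_K * k$T_K / (k$F_C_mol^2 * TER_ohm_cm2 * C)
  list(P_Na_cm_s = beta / (1 + beta) * total,
       P_Cl_cm_s = total / (1 + beta),
       P_total_cm_s = total)
}

#' Full barrier analysis of raw electrophysiology records
#'
#' TER by blank subtraction, beta by GHK inversion of the blank-corrected
#' dilution potential, and absolute P_Na/P_Cl by Kimizuka-Koketsu.
#'
#' @param records list of [electro_record()]s.
#' @param reference_NaCl_mM,kappa see [kimizuka_koketsu()] and [ghk_ratio()].
#' @return data.frame of class `permeability_result` with one row per
#'   record: `TER_ohm_cm2`, `beta`, `P_Na_cm_s`, `P_Cl_cm_s`.
#' @export
analyze_electro <- function(records, reference_NaCl_mM = 140, kappa = NULL) {
  rows <- lapply(records, function(r) {
    ter <- compute_ter(r)
    beta <- ghk_ratio(r, kappa = kappa)
    kk <- kimizuka_koketsu(ter, beta, reference_NaCl_mM, r$temperature_K)
    data.frame(TER_ohm_cm2 = ter, beta = beta,
               P_Na_cm_s = kk$P_Na_cm_s, P_Cl_cm_s = kk$P_Cl_cm_s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("permeability_result", class(out))
  out
}

#' Specification of a simulated dilution-potential experiment
#'
#' Forward model for [generate_electro_dataset()]: true permeabilities fix
#' the true TER (inverse Kimizuka-Koketsu) and the true dilution potential
#' (forward GHK); blanks and Gaussian noise are then layered on top, and
#' raw records are emitted.
#'
#' @param true_P_Na,true_P_Cl ground-truth permeabilities (cm/s).
#' @param membrane_area_cm2 insert area (1.12 cm^2 for 12-mm filters).
#' @param solution_apical,solution_basolateral the bathing pair.
#' @param temperature_K assay temperature.
#' @param blank_resistance_ohm,blank_potential_mV blank-filter values.
#' @param resistance_noise_sd_ohm,potential_noise_sd_mV measurement noise.
#' @param reference_NaCl_mM Kimizuka-Koketsu reference concentration.
#' @param n_replicates number of records.
#' @param seed RNG seed.
#' @return validated list of class `electro_spec`.
#' @export
electro_spec <- function(true_P_Na = 1.5e-5, true_P_Cl = 2e-6,
                         membrane_area_cm2 = 1.12,
                         solution_apical = solution_a(),
                         solution_basolateral = solution_b(),
                         temperature_K = 310.15,
                         blank_resistance_ohm = 100,
                         blank_potential_mV = 0.5,
                         resistance_noise_sd_ohm = 0.5,
                         potential_noise_sd_mV = 0.1,
                         reference_NaCl_mM = 140,
                         n_replicates = 4L, seed = 1L) {
  stopifnot(true_P_Na > 0, true_P_Cl > 0, membrane_area_cm2 > 0,
            temperature_K > 0, n_replicates >= 1L,
            resistance_noise_sd_ohm >= 0, potential_noise_sd_mV >= 0)
  structure(list(true_P_Na = true_P_Na, true_P_Cl = true_P_Cl,
                 membrane_area_cm2 = membrane_area_cm2,
                 solution_apical = solution_apical,
                 solution_basolateral = solution_basolateral,
                 temperature_K = temperature_K,
                 blank_resistance_ohm = blank_resistance_ohm,
                 blank_potential_mV = blank_potential_mV,
                 resistance_noise_sd_ohm = resistance_noise_sd_ohm,
                 potential_noise_sd_mV = potential_noise_sd_mV,
                 reference_NaCl_mM = reference_NaCl_mM,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "electro_spec")
}

#' True TER implied by true permeabilities (inverse Kimizuka-Koketsu)
#' @param spec an [electro_spec()].
#' @return TER in ohm cm^2.
#' @export
true_ter <- function(spec) {
  k <- physical_constants(spec$temperature_K)
  C <- spec$reference_NaCl_mM * 1e-6
  k$R_J_mol_K * k$T_K / (k$F_C_mol^2 * (spec$true_P_Na + spec$true_P_Cl) * C)
}

#' Simulate raw dilution-potential records
#'
#' Uses the same forward GHK and Kimizuka-Koketsu relations as the analysis
#' path, so noiseless records invert exactly to the true permeabilities.
#'
#' @param spec an [electro_spec()].
#' @return list of [electro_record()]s.
#' @export
generate_electro_dataset <- function(spec) {
  stopifnot(inherits(spec, "electro_spec"))
  beta <- spec$true_P_Na / spec$true_P_Cl
  ter <- true_ter(spec)
  v <- ghk_dilution_potential(beta, spec$solution_apical,
                              spec$solution_basolateral, spec$temperature_K)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_replicates), function(i) {
      electro_record(
        raw_resistance_ohm = ter / spec$membrane_area_cm2 +
          spec$blank_resistance_ohm +
          stats::rnorm(1, sd = spec$resistance_noise_sd_ohm),
        blank_resistance_ohm = spec$blank_resistance_ohm,
        raw_potential_mV = v + spec$blank_potential_mV +
          stats::rnorm(1, sd = spec$potential_noise_sd_mV),
        blank_potential_mV = spec$blank_potential_mV,
        area_cm2 = spec$membrane_area_cm2,
        apical = spec$solution_apical,
        basolateral = spec$solution_basolateral,
        temperature_K = spec$temperature_K)
    })
  })
}
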