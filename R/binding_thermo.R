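# Molar gas constant, J mol^-1 K^-1. SI joules are used internally
# throughout; reports convert to kJ only for display.
R_GAS <- 8.314

#' Gibbs free energy from enthalpy and entropy
#'
#' \eqn{\Delta G = \Delta H - T \Delta S}; vectorized over `T`.
#'
#' @param dH Enthalpy change in J/mol.
#' @param dS Entropy change in J/(mol K).
#' @param T Temperature(s) in K, > 0.
#' @return Gibbs free energy change(s) in J/mol.
#' @export
gibbs <- function(dH, dS, T) {
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop("validation error: T must be positive (kelvin)", call. = FALSE)
  }
  dH - T * dS
}

#' Ross-Subramanian classification of the dominant binding force
#'
#' The signs of the binding enthalpy and entropy indicate the dominant
#' intermolecular force: both positive, hydrophobic interactions; both
#' negative, van der Waals contacts and hydrogen bonds; negative enthalpy
#' with positive entropy, electrostatic interactions. An enthalpy near zero
#' (within `near_zero_tol`) is also read as electrostatic.
#'
#' @param dH Enthalpy change in J/mol.
#' @param dS Entropy change in J/(mol K).
#' @param near_zero_tol Half-width of the "near zero" enthalpy band in
#'   J/mol; default 4000 (about RT at room temperature).
#' @return One of `"hydrophobic"`, `"vdW_hbond"`, `"electrostatic"`,
#'   `"indeterminate"`.
#' @export
classify_forces <- function(dH, dS, near_zero_tol = 4000) {
  if (!is.finite(near_zero_tol) || near_zero_tol < 0) {
    stop("validation error: near_zero_tol must be >= 0", call. = FALSE)
  }
  if (abs(dH) <= near_zero_tol) return("electrostatic")
  if (dH > 0 && dS > 0) return("hydrophobic")
  if (dH < 0 && dS < 0) return("vdW_hbond")
  if (dH < 0 && dS > 0) return("electrostatic")
  "indeterminate"
}

#' Van't Hoff analysis of binding constants
#'
#' Regresses \eqn{\ln K_a} on \eqn{1/T}:
#' \deqn{\ln K_a = -\frac{\Delta H}{R T} + \frac{\Delta S}{R}}
#' so \eqn{\Delta H = -R \cdot \mathrm{slope}} and
#' \eqn{\Delta S = R \cdot \mathrm{intercept}}. Gibbs energies at every
#' fitted temperature are then taken from the fitted parameters as
#' \eqn{\Delta G = \Delta H - T\Delta S} (not from \eqn{-RT\ln K_a}; the
#' latter is emitted as a per-temperature consistency diagnostic), and the
#' dominant force is classified per [classify_forces()].
#'
#' @param K_values Association constants in M^-1, all > 0.
#' @param T_values Matching temperatures in K, >= 2 distinct.
#' @param near_zero_tol Passed to [classify_forces()].
#' @return An object of class `thermo_result` with fields `dH` (J/mol),
#'   `dS` (J/(mol K)), `dG_by_T` (data frame of T, dG, -RT ln K,
#'   spontaneity flag), `r`, `gas_constant`, `force_class`.
#' @examples
#' vant_hoff_fit(c(1.25e4, 2.76e4, 5.24e4), c(287, 298, 307))
#' @export
vant_hoff_fit <- function(K_values, T_values, near_zero_tol = 4000) {
  if (length(K_values) != length(T_values)) {
    stop("K_values and T_values must have equal length", call. = FALSE)
  }
  if (any(!is.finite(K_values)) || any(K_values <= 0)) {
    stop("validation error: all K must be positive", call. = FALSE)
  }
  if (any(!is.finite(T_values)) || any(T_values <= 0)) {
    stop("validation error: all T must be positive (kelvin)", call. = FALSE)
  }
  if (length(unique(T_values)) < 2) {
    stop("fit error: need >= 2 distinct temperatures", call. = FALSE)
  }
  ord <- order(T_values)
  T_values <- T_values[ord]
  K_values <- K_values[ord]
  x <- 1 / T_values
  y <- log(K_values)
  line <- ols_line(x, y)
  dH <- -R_GAS * line$slope
  dS <- R_GAS * line$intercept
  dG <- gibbs(dH, dS, T_values)
  dG_lnK <- -R_GAS * T_values * y
  structure(list(
    dH = dH, dS = dS,
    dG_by_T = data.frame(temperature = T_values, dG = dG,
                         dG_from_lnK = dG_lnK,
                         spontaneous = dG < 0),
    r = line$r, gas_constant = R_GAS,
    force_class = classify_forces(dH, dS, near_zero_tol),
    K_values = K_values),
    class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %+.2f kJ/mol, dS = %+.2f J/(mol K), r = %.4f, force: %s\n",
              x$dH / 1000, x$dS, x$r, x$force_class))
  df <- x$dG_by_T
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  T = %g K: dG = %+.2f kJ/mol%s\n", df$temperature[i],
                df$dG[i] / 1000, if (df$spontaneous[i]) " (spontaneous)" else ""))
  }
  invisible(x)
}
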