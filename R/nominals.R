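#' Nominal quality and kinetic values for pre-cooked dried beans
#'
#' Reference group means and standard deviations for red kidney beans that
#' were soaked, cooked and then air- (AD), vacuum- (VD) or freeze-dried
#' (FD), with the freshly cooked bean as control: CIELAB colour, hardness,
#' gelatinisation/melting peak temperature, degree of starch retrogradation,
#' rehydration yield and relative rehydration moisture
#' (`bean_quality_nominals`), and Arrhenius-level kinetic constants of the
#' best-fitting rehydration models per drying method
#' (`bean_kinetic_nominals`, at a reference temperature of 353.15 K).
#'
#' These values parameterise the demonstration pipeline and the synthetic
#' generators, so that simulated data carry realistic group differences.
#'
#' @format `bean_quality_nominals`: a list of data frames (`color`,
#'   `hardness`, `thermal`, `rehydration`), each keyed by treatment.
#'   `bean_kinetic_nominals`: a data frame keyed by drying method with
#'   Weibull (`alpha_ref` min, `beta`), Peleg (`K1_ref` min/%db) and
#'   diffusion (`D_eff0` m^2/s, `G`) constants and activation energies
#'   (kJ/mol).
#' @name bean_nominals
NULL

#' @rdname bean_nominals
#' @export
bean_quality_nominals <- list(
  color = data.frame(
    treatment = c("control", "AD", "VD", "FD"),
    L = c(24.42, 20.72, 19.24, 31.32),
    L_sd = c(0.89, 0.93, 0.58, 1.55),
    a = c(18.31, 8.76, 9.10, 12.0),
    a_sd = c(0.53, 0.45, 0.13, 0.83),
    b = c(8.65, 2.73, 2.70, 4.50),
    b_sd = c(0.74, 0.24, 0.02, 0.47),
    delta_e_printed = c(NA, 11.85, 12.14, 10.26)),
  hardness = data.frame(
    treatment = c("control", "AD", "VD", "FD"),
    hardness_N = c(64.82, 62.90, 70.50, 48.21),
    hardness_sd = c(11.40, 12.86, 13.50, 9.74),
    n = 20L),
  thermal = data.frame(
    treatment = c("control", "AD", "VD", "FD"),
    T_peak_C = c(79.74, 57.57, 64.76, 58.33),
    T_peak_sd = c(0.06, 0.71, 0.74, 0.54),
    DR_pct = c(NA, 44.79, 28.89, 27.04),
    DR_sd = c(NA, 1.62, 1.47, 0.70)),
  rehydration = data.frame(
    treatment = c("AD", "VD", "FD"),
    Y = c(2.30, 2.28, 2.56),
    Y_sd = c(0.013, 0.043, 0.001),
    RRM = c(0.96, 0.93, 1.12),
    RRM_sd = c(0.008, 0.029, 0.001))
)

#' @rdname bean_nominals
#' @export
bean_kinetic_nominals <- data.frame(
  method = c("AD", "VD", "FD"),
  E_a_peleg = c(4.36, 13.32, 2.05),
  K1_ref = c(0.017, 0.020, 0.002),
  E_a_weibull = c(6.90, 14.37, 2.86),
  alpha_ref = c(4.77, 4.52, 0.61),
  E_a_fick = c(8.99, 14.70, 3.45),
  D_eff0 = c(5.53e-8, 6.533e-8, 6.093e-8),
  G = c(5.53, 6.53, 6.09)
)
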