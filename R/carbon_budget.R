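#' Carbon content of an added polysaccharide
#'
#' Millimoles of carbon in a mass of polymer, computed on the anhydro-sugar
#' monomer basis: `carbons_per_monomer * mass_mg / monomer_mass_g_mol`. The
#' default monomer (162.14 g/mol anhydroglucose, 6 carbons, natural isotope
#' abundance) covers starch, cellulose and glucan-basis hemicellulose alike,
#' so 150 mg of either treatment's polymer carries the same carbon.
#'
#' @param mass_mg Polymer mass added, mg.
#' @param monomer_mass_g_mol Formula mass of the anhydro monomer, g/mol.
#' @param carbons_per_monomer Carbon atoms per monomer.
#' @return Carbon, mmol.
#' @examples
#' polymer_carbon_mmol(150) # 5.55 mmol
#' @export
polymer_carbon_mmol <- function(mass_mg, monomer_mass_g_mol = 162.14,
                                carbons_per_monomer = 6) {
  if (any(mass_mg < 0)) stop_validation("mass_mg must be non-negative")
  if (any(monomer_mass_g_mol <= 0) || any(carbons_per_monomer <= 0)) {
    stop_validation("monomer mass and carbons per monomer must be positive")
  }
  # mg / (g/mol) = mmol of monomer
  carbons_per_monomer * mass_mg / monomer_mass_g_mol
}

#' Percent of added carbon mineralized to TIC
#'
#' @param tic_produced_mmol Net total inorganic carbon produced, mmol (>= 0).
#' @param carbon_added_mmol Carbon added as polymer, mmol (> 0).
#' @return Percentage, `100 * tic_produced / carbon_added`.
#' @examples
#' percent_mineralized(1.70, 5.55) # ~30.6, i.e. 31% to the nearest percent
#' @export
percent_mineralized <- function(tic_produced_mmol, carbon_added_mmol) {
  if (any(carbon_added_mmol <= 0)) {
    stop_undefined("carbon_added_mmol must be positive")
  }
  if (any(tic_produced_mmol < 0)) {
    stop_validation("tic_produced_mmol must be non-negative")
  }
  100 * tic_produced_mmol / carbon_added_mmol
}

#' Background-corrected TIC increase
#'
#' @param background_mean_mmol Mean TIC in substrate-free controls, mmol.
#' @param treatment_mean_mmol Mean TIC in amended microcosms, mmol.
#' @return `treatment_mean - background_mean`, mmol (may be negative).
#' @export
net_tic_increase <- function(background_mean_mmol, treatment_mean_mmol) {
  treatment_mean_mmol - background_mean_mmol
}

#' Mean over treatment means
#'
#' @param values Non-empty numeric vector of treatment means, mmol.
#' @return Arithmetic mean, mmol.
#' @export
pooled_mean <- function(values) {
  if (length(values) == 0L) {
    stop_validation("pooled_mean needs a non-empty vector")
  }
  mean(values)
}

#' Two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t-test (default) computed from group means,
#' standard deviations and sizes, with the Welch-Satterthwaite degrees of
#' freedom; set `var_equal = TRUE` for the pooled-variance Student flavour.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group a.
#' @param mean_b,sd_b,n_b Summary statistics of group b.
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @return A one-row tibble with `statistic` (t, sign follows `mean_a -
#'   mean_b`), `df` and the two-sided `p_value`.
#' @examples
#' welch_t_from_summary(1.36, 0.18, 5, 1.70, 0.15, 5)
#' @export
welch_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                 var_equal = FALSE) {
  if (n_a < 2 || n_b < 2) {
    stop_validation("both groups need n >= 2")
  }
  if (sd_a < 0 || sd_b < 0 || (sd_a == 0 && sd_b == 0)) {
    stop_validation("standard deviations must be non-negative, not both zero")
  }
  if (var_equal) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
    method <- "student"
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    method <- "welch"
  }
  t <- (mean_a - mean_b) / se
  tibble::tibble(
    statistic = t,
    df = df,
    p_value = 2 * pt(-abs(t), df),
    method = method
  )
}
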