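#' Simulate a microbial community profile
#'
#' Draws a long-tailed community of relative abundances (lognormal), per-taxon
#' genomic GC content (uniform) and a ground-truth labelling assignment:
#' exactly `round(labelled_fraction * n_taxa)` taxa carry the given 13C atom
#' fraction excess, all others carry 0.
#'
#' The default GC window (0.30--0.50) places unlabelled DNA around the light
#' fraction density of the default gradient (about 1.69--1.71 g/mL), matching
#' how sequencing fractions are chosen in practice: where the community's
#' unlabelled DNA actually bands.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param abundance_meanlog,abundance_sdlog Parameters of the lognormal
#'   abundance model (abundances are renormalised to sum to 1, so
#'   `abundance_meanlog` only sets the scale before normalisation).
#' @param gc_range Length-2 numeric: lower/upper bound of the uniform GC
#'   content model, inside `[0, 1]`.
#' @param labelled_fraction Fraction of taxa that assimilate the labelled
#'   substrate, in `[0, 1]`.
#' @param atom_excess 13C atom fraction excess of labelled taxa, in `[0, 1]`.
#' @param seed Integer seed; the profile is reproducible for a fixed seed.
#' @return A tibble of class `sip_community` with columns `otu_id`,
#'   `abundance`, `gc`, `atom_excess`, `labelled`.
#' @export
simulate_community <- function(n_taxa, abundance_meanlog = 0,
                               abundance_sdlog = 2,
                               gc_range = c(0.30, 0.50),
                               labelled_fraction = 0.05,
                               atom_excess = 1, seed) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 1 ||
      n_taxa != round(n_taxa)) {
    stop_validation("n_taxa must be a positive integer")
  }
  if (abundance_sdlog < 0) {
    stop_validation("abundance_sdlog must be non-negative")
  }
  if (length(gc_range) != 2L || any(gc_range < 0) || any(gc_range > 1) ||
      gc_range[1] > gc_range[2]) {
    stop_validation("gc_range must be an increasing pair inside [0, 1]")
  }
  if (labelled_fraction < 0 || labelled_fraction > 1) {
    stop_validation("labelled_fraction must lie in [0, 1]")
  }
  if (atom_excess < 0 || atom_excess > 1) {
    stop_validation("atom_excess must lie in [0, 1]")
  }
  if (missing(seed)) stop_validation("a seed is required for simulation")

  withr::with_seed(seed, {
    raw <- rlnorm(n_taxa, meanlog = abundance_meanlog, sdlog = abundance_sdlog)
    abundance <- raw / sum(raw)
    gc <- runif(n_taxa, gc_range[1], gc_range[2])
    n_labelled <- round(labelled_fraction * n_taxa)
    labelled_idx <- if (n_labelled > 0) {
      sample.int(n_taxa, n_labelled)
    } else {
      integer(0)
    }
    excess <- rep(0, n_taxa)
    excess[labelled_idx] <- atom_excess
    width <- max(4L, nchar(as.character(n_taxa)))
    out <- tibble::tibble(
      otu_id = sprintf(paste0("Otu%0", width, "d"), seq_len(n_taxa)),
      abundance = abundance,
      gc = gc,
      atom_excess = excess,
      labelled = excess > 0
    )
    structure(out, class = c("sip_community", "tbl_df", "tbl", "data.frame"),
              seed = seed)
  })
}

#' Buoyant density of DNA in a CsCl gradient
#'
#' Linear model in GC content and 13C atom fraction excess:
#' `rho = 1.660 + 0.098 * gc + 0.036 * atom_excess` (g/mL), i.e. the
#' standard GC dependence of CsCl buoyant density plus the full-labelling
#' density shift of about 0.036 g/mL.
#'
#' @param gc GC content in `[0, 1]` (vectorised).
#' @param atom_excess 13C atom fraction excess in `[0, 1]` (vectorised).
#' @return Buoyant density in g/mL, monotonically increasing in both inputs.
#' @examples
#' buoyant_density(0.5, 0) # 1.709
#' buoyant_density(0.5, 1) # 1.745
#' @export
buoyant_density <- function(gc, atom_excess = 0) {
  if (any(!is.finite(gc) | gc < 0 | gc > 1)) {
    stop_validation("gc must lie in [0, 1]")
  }
  if (any(!is.finite(atom_excess) | atom_excess < 0 | atom_excess > 1)) {
    stop_validation("atom_excess must lie in [0, 1]")
  }
  1.660 + 0.098 * gc + 0.036 * atom_excess
}

#' Configure the density gradient
#'
#' Describes the CsCl gradient as a set of contiguous, equal-width density
#' bins (fractions) covering a density range, plus the densities of the two
#' fractions selected for sequencing. Bins are left-closed, so each selected
#' density falls in exactly one fraction.
#'
#' @param n_fractions Number of fractions the gradient is separated into
#'   (default 12).
#' @param density_range Length-2 numeric, the density span of the gradient
#'   in g/mL (default 1.66--1.78).
#' @param heavy_density,light_density Densities (g/mL) of the fractions
#'   sequenced as heavy and light samples (defaults 1.725 and 1.700).
#' @param sigma_rho Within-taxon Gaussian spread of DNA around its mean
#'   buoyant density, in g/mL (default 0.006).
#' @param depth Reads sequenced per fraction sample (default 50000).
#' @return A list of class `gradient_config` with the above fields plus the
#'   bin `breaks`.
#' @export
gradient_config <- function(n_fractions = 12,
                            density_range = c(1.66, 1.78),
                            heavy_density = 1.725, light_density = 1.700,
                            sigma_rho = 0.006, depth = 50000) {
  if (n_fractions < 2 || n_fractions != round(n_fractions)) {
    stop_validation("n_fractions must be an integer >= 2")
  }
  if (length(density_range) != 2L || density_range[1] >= density_range[2]) {
    stop_validation("density_range must be an increasing pair")
  }
  if (sigma_rho <= 0) stop_validation("sigma_rho must be positive")
  if (depth < 0 || depth != round(depth)) {
    stop_validation("depth must be a non-negative integer")
  }
  breaks <- seq(density_range[1], density_range[2],
                length.out = n_fractions + 1)
  for (d in c(heavy = heavy_density, light = light_density)) {
    if (d < density_range[1] || d >= density_range[2]) {
      stop_validation(
        "heavy_density and light_density must fall inside the density range"
      )
    }
  }
  structure(
    list(
      n_fractions = as.integer(n_fractions),
      density_range = density_range,
      heavy_density = heavy_density,
      light_density = light_density,
      sigma_rho = sigma_rho,
      depth = as.integer(depth),
      breaks = breaks
    ),
    class = "gradient_config"
  )
}

#' @export
print.gradient_config <- function(x, ...) {
  cat(sprintf(
    "<gradient_config> %d fractions over %.3f-%.3f g/mL; heavy %.3f, light %.3f; sigma_rho %.4f; depth %d\n",
    x$n_fractions, x$density_range[1], x$density_range[2],
    x$heavy_density, x$light_density, x$sigma_rho, x$depth
  ))
  invisible(x)
}

# Index of the bin containing a density (left-closed bins).
fraction_index <- function(density, config) {
  findInterval(density, config$breaks, rightmost.closed = TRUE)
}

#' Distribute a taxon's DNA over gradient fractions
#'
#' The DNA of a taxon with mean buoyant density `mean_density` is spread as a
#' Gaussian with standard deviation `sigma_rho`; each fraction receives the
#' Gaussian probability mass falling inside its density bin, renormalised
#' over the gradient range (mass outside the gradient is discarded before
#' renormalisation).
#'
#' @param mean_density Mean buoyant densities, g/mL (vectorised over taxa).
#' @param sigma_rho Gaussian spread in g/mL; defaults to the value in
#'   `config`.
#' @param config A [gradient_config()].
#' @return A numeric vector of per-fraction proportions (summing to 1) for a
#'   single density, or a taxa-by-fractions matrix for several.
#' @export
fractionate_taxon <- function(mean_density, sigma_rho = config$sigma_rho,
                              config = gradient_config()) {
  if (sigma_rho <= 0) stop_validation("sigma_rho must be positive")
  breaks <- config$breaks
  nb <- length(breaks)
  cdf <- vapply(
    breaks,
    function(b) pnorm(b, mean = mean_density, sd = sigma_rho),
    numeric(length(mean_density))
  )
  cdf <- matrix(cdf, nrow = length(mean_density), ncol = nb)
  mass <- cdf[, -1L, drop = FALSE] - cdf[, -nb, drop = FALSE]
  total <- rowSums(mass)
  if (any(total <= 0)) {
    stop_validation(
      "a taxon has no probability mass inside the gradient density range"
    )
  }
  prop <- mass / total
  if (length(mean_density) == 1L) as.vector(prop) else prop
}

#' Draw multinomial sequencing reads
#'
#' @param composition Per-taxon proportions summing to 1.
#' @param depth Total number of reads (>= 0).
#' @param seed Optional integer seed for a reproducible draw.
#' @return Integer vector of read counts summing exactly to `depth`.
#' @export
sample_reads <- function(composition, depth, seed = NULL) {
  if (any(!is.finite(composition) | composition < 0)) {
    stop_validation("composition must be non-negative and finite")
  }
  if (abs(sum(composition) - 1) > 1e-6) {
    stop_validation("composition must sum to 1")
  }
  if (depth < 0 || depth != round(depth)) {
    stop_validation("depth must be a non-negative integer")
  }
  draw <- function() {
    if (depth == 0) {
      integer(length(composition))
    } else {
      as.integer(rmultinom(1L, size = depth, prob = composition))
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a four-sample DNA-SIP experiment
#'
#' Generates the canonical screening design: one light and one heavy fraction
#' sample for each of the 12C control and the 13C incubation. The 12C samples
#' are built with every taxon's atom excess forced to zero (the control
#' substrate is unlabelled); the 13C samples use the profile's atom excess,
#' so labelled taxa shift their buoyant density upward. Fraction-specific
#' compositions are abundance-weighted Gaussian fraction masses, renormalised
#' per fraction, and each sample is an independent multinomial read draw at
#' the configured depth.
#'
#' @param profile A [simulate_community()] profile.
#' @param config A [gradient_config()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param treatment Treatment label stamped into the sample metadata.
#' @return A list of class `sip_experiment` with elements `table` (a
#'   [sip_table()] of the four samples), `truth` (per-taxon tibble with
#'   `labelled`, `atom_excess`, `gc`, `abundance`), `composition` (list of
#'   taxa-by-fraction sample-composition matrices for `C12` and `C13`),
#'   `config`, `treatment` and `seed`.
#' @export
simulate_sip_experiment <- function(profile, config = gradient_config(),
                                    seed, treatment = "starch") {
  stopifnot(inherits(config, "gradient_config"))
  profile <- tibble::as_tibble(profile)
  needed <- c("otu_id", "abundance", "gc", "atom_excess")
  missing <- setdiff(needed, names(profile))
  if (length(missing) > 0L) {
    stop_validation(sprintf(
      "community profile is missing column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (missing(seed)) stop_validation("a seed is required for simulation")

  comp <- list(
    C12 = fraction_composition(profile, config, label_active = FALSE),
    C13 = fraction_composition(profile, config, label_active = TRUE)
  )
  idx <- c(
    light = fraction_index(config$light_density, config),
    heavy = fraction_index(config$heavy_density, config)
  )
  for (iso in names(comp)) {
    if (any(colSums(comp[[iso]][, idx, drop = FALSE]) <= 0)) {
      stop_validation(sprintf(
        "the %s heavy/light fractions received no DNA mass; community and gradient are mismatched",
        iso
      ))
    }
  }

  sample_ids <- paste(treatment,
                      c("C12_light", "C12_heavy", "C13_light", "C13_heavy"),
                      sep = "_")
  counts <- withr::with_seed(seed, {
    tibble::tibble(
      otu_id = profile$otu_id,
      !!sample_ids[1] := sample_reads(comp$C12[, idx[["light"]]], config$depth),
      !!sample_ids[2] := sample_reads(comp$C12[, idx[["heavy"]]], config$depth),
      !!sample_ids[3] := sample_reads(comp$C13[, idx[["light"]]], config$depth),
      !!sample_ids[4] := sample_reads(comp$C13[, idx[["heavy"]]], config$depth)
    )
  })
  meta <- tibble::tibble(
    sample_id = sample_ids,
    isotope = c("C12", "C12", "C13", "C13"),
    fraction_role = c("light", "heavy", "light", "heavy"),
    treatment = treatment,
    density = c(config$light_density, config$heavy_density)[c(1, 2, 1, 2)]
  )
  truth <- profile[, c("otu_id", "abundance", "gc", "atom_excess")]
  truth$labelled <- truth$atom_excess > 0

  structure(
    list(
      table = sip_table(counts, meta),
      truth = truth,
      composition = comp,
      config = config,
      treatment = treatment,
      seed = seed
    ),
    class = "sip_experiment"
  )
}

# Taxa-by-fraction matrix of sample compositions: column f holds the relative
# abundance of each taxon among the DNA recovered in fraction f.
fraction_composition <- function(profile, config, label_active) {
  excess <- if (label_active) profile$atom_excess else 0
  rho <- buoyant_density(profile$gc, excess)
  mass <- fractionate_taxon(rho, config$sigma_rho, config)
  mass <- matrix(mass, nrow = nrow(profile))
  w <- mass * profile$abundance
  totals <- colSums(w)
  # Fractions far from where the community bands can receive (numerically)
  # zero mass; their composition is undefined and set to zero. Sampling such
  # a fraction is refused downstream.
  comp <- sweep(w, 2L, pmax(totals, .Machine$double.xmin), "/")
  comp[, totals <= 0] <- 0
  comp
}

#' @export
print.sip_experiment <- function(x, ...) {
  cat(sprintf(
    "<sip_experiment> treatment '%s': %d taxa, %d labelled, depth %d, seed %s\n",
    x$treatment, nrow(x$truth), sum(x$truth$labelled), x$config$depth,
    format(x$seed)
  ))
  invisible(x)
}

#' Convert a refractive index to CsCl buoyant density
#'
#' Standard linear CsCl refractometry calibration,
#' `rho = 10.8601 * ri - 13.4974` (g/mL at 20 degrees C), as used to assign
#' densities to gradient fractions from AR200-type refractometer readings.
#'
#' @param ri Refractive index, in `[1.33, 1.46]` (vectorised).
#' @return Density in g/mL. A warning is raised for densities below the
#'   CsCl gradient working range (< 1.60 g/mL, e.g. near-water readings).
#' @examples
#' ri_to_density(1.4000) # 1.70674
#' @export
ri_to_density <- function(ri) {
  if (any(!is.finite(ri) | ri < 1.33 | ri > 1.46)) {
    stop_validation("refractive index must lie in [1.33, 1.46]")
  }
  rho <- 10.8601 * ri - 13.4974
  if (any(rho < 1.60)) {
    warning("density below the CsCl gradient working range (< 1.60 g/mL)",
            call. = FALSE)
  }
  rho
}
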