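#' Fit a MUF fluorescence standard curve
#'
#' Ordinary least-squares line `fluorescence = slope * concentration +
#' intercept` over a dilution series of the free fluorophore
#' (4-methylumbelliferone). A valid curve has positive slope; inversion
#' refuses otherwise.
#'
#' @param data Data frame with numeric columns `concentration` (uM) and
#'   `fluorescence` (arbitrary units). At least 3 distinct concentrations.
#' @return An object of class `standard_curve` with elements `slope` (AU per
#'   uM), `intercept` (AU), `r_squared`, `n` and the fitting `data`.
#' @examples
#' standards <- data.frame(
#'   concentration = c(0, 0.5, 1.0, 1.5, 2.0, 3.5, 7.5),
#'   fluorescence = 100 * c(0, 0.5, 1.0, 1.5, 2.0, 3.5, 7.5) + 50
#' )
#' fit_standard_curve(standards)
#' @export
fit_standard_curve <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("concentration", "fluorescence") %in% names(data))) {
    stop_validation(
      "standards need 'concentration' and 'fluorescence' columns"
    )
  }
  if (nrow(data) < 3L || length(unique(data$concentration)) < 3L) {
    stop_validation("a standard curve needs at least 3 distinct concentrations")
  }
  if (var(data$fluorescence) == 0) {
    stop_validation(
      "standard curve fit failed: fluorescence is constant across standards"
    )
  }
  fit <- lm(fluorescence ~ concentration, data = data)
  slope <- unname(coef(fit)[["concentration"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  if (!is.finite(slope) || slope <= 0) {
    stop_validation(
      "standard curve fit failed: slope must be positive (is the fluorescence constant?)"
    )
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((data$fluorescence - mean(data$fluorescence))^2)
  structure(
    list(
      slope = slope,
      intercept = intercept,
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      n = nrow(data),
      data = data
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> fluorescence = %.4g * conc + %.4g (n = %d, r^2 = %.4f)\n",
    x$slope, x$intercept, x$n, x$r_squared
  ))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' Back-calculate MUF concentrations from fluorescence
#'
#' Inverts the standard curve point-wise: `conc = (fluorescence - intercept)
#' / slope`. Values slightly below zero near the blank are retained, not
#' clipped, so zero-activity series stay unbiased.
#'
#' @param data Data frame with a `fluorescence` column (other columns pass
#'   through), or a bare numeric vector of fluorescence values.
#' @param curve A [fit_standard_curve()] object.
#' @return The input with a `concentration` column added (uM), or a numeric
#'   vector if `data` was one.
#' @export
fluorescence_to_concentration <- function(data, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) {
    stop_validation("cannot invert a standard curve with non-positive slope")
  }
  if (is.numeric(data) && is.null(dim(data))) {
    return((data - curve$intercept) / curve$slope)
  }
  data <- tibble::as_tibble(data)
  if (!"fluorescence" %in% names(data)) {
    stop_validation("data needs a 'fluorescence' column")
  }
  data$concentration <- (data$fluorescence - curve$intercept) / curve$slope
  data
}

#' Enzyme activity rate from a concentration time series
#'
#' OLS slope of released-MUF concentration against time, rescaled to uM per
#' hour. By default the full series is fitted; `method = "max_slope"` slides
#' a window of `span_minutes` over the series and reports the steepest
#' window, which is robust to late-assay substrate depletion.
#'
#' @param data Data frame with numeric columns `minutes` (strictly
#'   increasing) and `concentration` (uM).
#' @param window Optional length-2 numeric, restrict the fit to minutes in
#'   `[window[1], window[2]]`.
#' @param method `"full"` (default) or `"max_slope"`.
#' @param span_minutes Window width for `method = "max_slope"`.
#' @return Activity rate in uM per hour (scalar).
#' @export
activity_rate <- function(data, window = NULL, method = c("full", "max_slope"),
                          span_minutes = 60) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  if (!all(c("minutes", "concentration") %in% names(data))) {
    stop_validation("data needs 'minutes' and 'concentration' columns")
  }
  if (is.unsorted(data$minutes, strictly = TRUE)) {
    stop_validation("timestamps must be strictly increasing")
  }
  if (!is.null(window)) {
    data <- data[data$minutes >= window[1] & data$minutes <= window[2], ,
                 drop = FALSE]
  }
  if (nrow(data) < 3L) {
    stop_validation("rate fitting needs at least 3 points in the window")
  }
  slope_per_min <- function(d) {
    unname(coef(lm(concentration ~ minutes, data = d))[["minutes"]])
  }
  slope <- if (method == "full") {
    slope_per_min(data)
  } else {
    starts <- data$minutes[data$minutes + span_minutes <= max(data$minutes)]
    if (length(starts) == 0L) starts <- data$minutes[1L]
    best <- -Inf
    for (s in starts) {
      d <- data[data$minutes >= s & data$minutes <= s + span_minutes, ,
                drop = FALSE]
      if (nrow(d) >= 3L) best <- max(best, slope_per_min(d))
    }
    if (!is.finite(best)) {
      stop_validation("no sliding window contains 3 points")
    }
    best
  }
  slope * 60
}

#' Normalise an enzyme activity to gene copies
#'
#' Converts an in-assay rate (uM of MUF released per hour) to moles per hour
#' in the assay volume, divides by the number of 16S rRNA gene copies in the
#' assayed material, and expresses the result in attomoles (1 amol =
#' 1e-18 mol) per hour per gene copy.
#'
#' @param rate_um_per_h In-assay rate, uM/h (vectorised).
#' @param assay_volume_l Assay volume in litres; the default 200 uL reflects
#'   a 50 uL sample + 50 uL substrate + 100 uL buffer plate assay.
#' @param gene_copies 16S rRNA gene copies in the assayed material (> 0).
#' @return Per-copy activity in amol per hour per gene copy.
#' @examples
#' normalize_activity(1, assay_volume_l = 1e-3, gene_copies = 1e9) # 1 amol/h/copy
#' @export
normalize_activity <- function(rate_um_per_h, assay_volume_l = 200e-6,
                               gene_copies) {
  if (any(!is.finite(assay_volume_l)) || any(assay_volume_l <= 0)) {
    stop_validation("assay_volume_l must be positive")
  }
  if (any(!is.finite(gene_copies)) || any(gene_copies <= 0)) {
    stop_validation(
      "gene_copies must be positive; per-copy normalisation needs a qPCR copy number"
    )
  }
  mol_per_h <- rate_um_per_h * 1e-6 * assay_volume_l
  (mol_per_h / gene_copies) * 1e18
}

#' Process a plate-reader export into enzyme activities
#'
#' Full assay chain for a long-format fluorescence export: fit the standard
#' curve, optionally subtract a substrate-free blank series point-wise,
#' invert fluorescence to MUF concentration, fit the rate per well, and (if a
#' copy number is given) normalise per gene copy.
#'
#' @param plate Long data frame with columns `well`, `minutes`,
#'   `fluorescence` and optionally `substrate`.
#' @param standards Data frame for [fit_standard_curve()].
#' @param assay_volume_l Assay volume in litres (see [normalize_activity()]).
#' @param gene_copies Optional 16S rRNA gene copies in the assayed material.
#' @param blank_well Optional well id of a substrate-free blank to subtract.
#' @param ... Passed to [activity_rate()].
#' @return A tibble with one row per (non-blank) well: `well`, `substrate`,
#'   `rate_um_per_h` and, when `gene_copies` is given, `per_copy_amol_h`.
#' @export
process_enzyme_plate <- function(plate, standards, assay_volume_l = 200e-6,
                                 gene_copies = NULL, blank_well = NULL, ...) {
  plate <- tibble::as_tibble(plate)
  needed <- c("well", "minutes", "fluorescence")
  missing <- setdiff(needed, names(plate))
  if (length(missing) > 0L) {
    stop_validation(sprintf(
      "plate data is missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  if (!"substrate" %in% names(plate)) plate$substrate <- NA_character_
  curve <- fit_standard_curve(standards)

  if (!is.null(blank_well)) {
    blank <- plate[plate$well == blank_well, c("minutes", "fluorescence")]
    names(blank)[2L] <- "blank_fluorescence"
    plate <- plate[plate$well != blank_well, , drop = FALSE]
    plate <- dplyr::left_join(plate, blank, by = "minutes")
    plate$fluorescence <- plate$fluorescence -
      dplyr::coalesce(plate$blank_fluorescence, 0)
    plate$blank_fluorescence <- NULL
  }

  plate <- fluorescence_to_concentration(plate, curve)
  out <- plate |>
    dplyr::arrange(.data$well, .data$minutes) |>
    dplyr::group_by(.data$well, .data$substrate) |>
    dplyr::summarise(
      rate_um_per_h = activity_rate(
        dplyr::pick("minutes", "concentration"), ...
      ),
      .groups = "drop"
    )
  if (!is.null(gene_copies)) {
    out$per_copy_amol_h <- normalize_activity(
      out$rate_um_per_h, assay_volume_l, gene_copies
    )
  }
  out
}
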