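#' Build a SIP fraction count table
#'
#' A `sip_table` couples a taxa-by-samples matrix of amplicon read counts with
#' per-sample fraction metadata: which gradient fraction the sample came from
#' (heavy, light or other), which isotope incubation it belongs to (12C or
#' 13C), the treatment label, and optionally the fraction's buoyant density.
#'
#' @param counts Data frame whose first column holds taxon (OTU) identifiers
#'   and whose remaining columns hold non-negative integer read counts, one
#'   column per fraction sample.
#' @param meta Data frame of per-sample metadata with columns `sample_id`,
#'   `isotope` (`"C12"` or `"C13"`), `fraction_role` (`"heavy"`, `"light"` or
#'   `"other"`), `treatment`, and optionally `density` (g/mL, within
#'   1.60--1.80). Must describe exactly the sample columns of `counts`.
#'
#' @return An object of class `sip_table`: a list with tibbles `counts`
#'   (first column `otu_id`) and `meta`.
#' @examples
#' counts <- data.frame(
#'   otu_id = c("Otu001", "Otu002"),
#'   L12 = c(10L, 90L), H12 = c(10L, 90L), L13 = c(10L, 90L), H13 = c(30L, 70L)
#' )
#' meta <- data.frame(
#'   sample_id = c("L12", "H12", "L13", "H13"),
#'   isotope = c("C12", "C12", "C13", "C13"),
#'   fraction_role = c("light", "heavy", "light", "heavy"),
#'   treatment = "starch"
#' )
#' sip_table(counts, meta)
#' @export
sip_table <- function(counts, meta) {
  counts <- tibble::as_tibble(counts)
  if (ncol(counts) < 1L) {
    stop_validation("`counts` needs at least a taxon identifier column")
  }
  names(counts)[1L] <- "otu_id"
  counts$otu_id <- as.character(counts$otu_id)
  if (anyDuplicated(counts$otu_id)) {
    stop_validation(sprintf(
      "duplicate otu_id in counts: %s",
      paste(unique(counts$otu_id[duplicated(counts$otu_id)]), collapse = ", ")
    ))
  }
  for (j in setdiff(names(counts), "otu_id")) {
    x <- counts[[j]]
    if (!is.numeric(x)) {
      x <- suppressWarnings(as.numeric(as.character(x)))
    }
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad) > 0L) {
      stop_validation(sprintf(
        "counts must be non-negative integers; offending value '%s' at row %d (otu '%s'), column '%s'",
        as.character(counts[[j]][bad[1L]]), bad[1L], counts$otu_id[bad[1L]], j
      ))
    }
    counts[[j]] <- as.integer(round(x))
  }

  meta <- validate_fraction_meta(meta)
  sample_ids <- setdiff(names(counts), "otu_id")
  if (!setequal(meta$sample_id, sample_ids) ||
      nrow(meta) != length(sample_ids)) {
    stop_validation(
      "`meta` must contain exactly one row per sample column of `counts`"
    )
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]

  structure(list(counts = counts, meta = meta), class = "sip_table")
}

validate_fraction_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  required <- c("sample_id", "isotope", "fraction_role", "treatment")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop_validation(sprintf(
      "fraction metadata is missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  if (!"density" %in% names(meta)) meta$density <- NA_real_
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop_validation("duplicate sample_id in fraction metadata")
  }
  ok_iso <- is.na(meta$isotope) | meta$isotope %in% c("C12", "C13")
  if (!all(ok_iso)) {
    stop_validation(sprintf(
      "isotope must be 'C12' or 'C13' (sample '%s')",
      meta$sample_id[which(!ok_iso)[1L]]
    ))
  }
  ok_role <- is.na(meta$fraction_role) |
    meta$fraction_role %in% c("heavy", "light", "other")
  if (!all(ok_role)) {
    stop_validation(sprintf(
      "fraction_role must be 'heavy', 'light' or 'other' (sample '%s')",
      meta$sample_id[which(!ok_role)[1L]]
    ))
  }
  meta$density <- as.numeric(meta$density)
  ok_den <- is.na(meta$density) | (meta$density >= 1.60 & meta$density <= 1.80)
  if (!all(ok_den)) {
    stop_validation(sprintf(
      "fraction density must lie in [1.60, 1.80] g/mL (sample '%s')",
      meta$sample_id[which(!ok_den)[1L]]
    ))
  }
  meta[, c("sample_id", "isotope", "fraction_role", "treatment", "density")]
}

#' @export
print.sip_table <- function(x, ...) {
  cat(sprintf(
    "<sip_table> %d taxa x %d samples\n",
    nrow(x$counts), nrow(x$meta)
  ))
  print(x$meta)
  invisible(x)
}

#' @export
dim.sip_table <- function(x) c(nrow(x$counts), nrow(x$meta))

#' Per-sample total read counts
#'
#' @param x A [sip_table()].
#' @return Named integer vector of column sums (reads per sample).
#' @export
sample_totals <- function(x) {
  stopifnot(inherits(x, "sip_table"))
  m <- as.matrix(x$counts[, -1L, drop = FALSE])
  colSums(m)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.sip_table <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x$counts,
    cols = -"otu_id", names_to = "sample_id", values_to = "reads"
  )
  dplyr::left_join(long, x$meta, by = "sample_id")
}

# Resolve the four screening samples (isotope x heavy/light) for a treatment.
# Returns a named character vector with names C12.light, C12.heavy, C13.light,
# C13.heavy; errors (configuration) if any combination is missing/duplicated.
fraction_samples <- function(x, treatment = NULL) {
  stopifnot(inherits(x, "sip_table"))
  meta <- x$meta
  if (is.null(treatment)) {
    treatments <- unique(meta$treatment[!is.na(meta$treatment)])
    if (length(treatments) != 1L) {
      stop_config(
        "table holds multiple (or no) treatments; supply `treatment` explicitly"
      )
    }
    treatment <- treatments
  }
  meta <- meta[!is.na(meta$treatment) & meta$treatment == treatment, ,
               drop = FALSE]
  out <- character(0)
  for (iso in c("C12", "C13")) {
    for (role in c("light", "heavy")) {
      hit <- meta$sample_id[!is.na(meta$isotope) & meta$isotope == iso &
                              meta$fraction_role == role]
      if (length(hit) != 1L) {
        stop_config(sprintf(
          "treatment '%s' requires exactly one (%s, %s) sample; found %d",
          treatment, iso, role, length(hit)
        ))
      }
      out[paste(iso, role, sep = ".")] <- hit
    }
  }
  out
}
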