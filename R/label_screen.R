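#' Per-taxon odds ratio between heavy and light fractions
#'
#' The odds that a read belongs to the focal taxon in the heavy versus the
#' light fraction sample: `OR = (G_H / nG_H) / (G_L / nG_L)`, where `G` and
#' `nG` count reads belonging and not belonging to the taxon and the
#' subscripts name the heavy and light fraction samples.
#'
#' @param g_h,ng_h,g_l,ng_l Non-negative counts (vectorised): focal-taxon and
#'   other-taxa reads in the heavy sample, then in the light sample.
#' @param correction Zero-cell policy. `"haldane"` (default) adds 0.5 to all
#'   four cells of a table containing a zero (Haldane-Anscombe), keeping the
#'   odds ratio finite and positive; `"strict"` refuses zero cells.
#' @return Numeric vector of odds ratios.
#' @examples
#' odds_ratio(10, 90, 10, 90) # 1
#' odds_ratio(20, 80, 10, 90) # 2.25
#' @export
odds_ratio <- function(g_h, ng_h, g_l, ng_l,
                       correction = c("haldane", "strict")) {
  correction <- match.arg(correction)
  m <- cbind(g_h = g_h, ng_h = ng_h, g_l = g_l, ng_l = ng_l)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop_validation("counts must be finite and non-negative")
  }
  if (any(rowSums(m) == 0)) {
    stop_undefined("odds ratio undefined: all four counts are zero")
  }
  zero <- rowSums(m == 0) > 0
  if (any(zero)) {
    if (correction == "strict") {
      stop_undefined(
        "zero cell encountered with correction = 'strict'; use 'haldane'"
      )
    }
    m[zero, ] <- m[zero, , drop = FALSE] + 0.5
  }
  unname((m[, 1] / m[, 2]) / (m[, 3] / m[, 4]))
}

#' Assemble the two-stratum contingency table for one taxon
#'
#' For a given treatment, the screening design holds four samples (12C/13C
#' crossed with light/heavy fraction). For the focal taxon this yields one
#' 2x2 table per isotope stratum: focal vs other reads, heavy vs light
#' sample.
#'
#' @param table A [sip_table()].
#' @param otu_id Focal taxon identifier.
#' @param treatment Treatment label; may be omitted when the table holds a
#'   single treatment.
#' @return A tibble with one row per isotope stratum (`C12`, `C13`) and
#'   columns `g_h`, `ng_h`, `g_l`, `ng_l`.
#' @export
build_contingency <- function(table, otu_id, treatment = NULL) {
  stopifnot(inherits(table, "sip_table"))
  samp <- fraction_samples(table, treatment)
  i <- match(otu_id, table$counts$otu_id)
  if (is.na(i)) {
    stop_validation(sprintf("otu_id '%s' not present in table", otu_id))
  }
  totals <- sample_totals(table)
  g <- vapply(samp, function(s) as.numeric(table$counts[[s]][i]), numeric(1))
  tibble::tibble(
    isotope = c("C12", "C13"),
    g_h = c(g[["C12.heavy"]], g[["C13.heavy"]]),
    ng_h = c(totals[[samp[["C12.heavy"]]]] - g[["C12.heavy"]],
             totals[[samp[["C13.heavy"]]]] - g[["C13.heavy"]]),
    g_l = c(g[["C12.light"]], g[["C13.light"]]),
    ng_l = c(totals[[samp[["C12.light"]]]] - g[["C12.light"]],
             totals[[samp[["C13.light"]]]] - g[["C13.light"]])
  )
}

#' Haldane-Anscombe continuity correction for a contingency pair
#'
#' Adds 0.5 to all four cells of any stratum whose 2x2 table contains a zero,
#' leaving other strata untouched. Applied consistently to the odds ratios,
#' the Mantel-Haenszel pooled odds ratio and the Breslow-Day statistic so
#' that rare taxa stay testable.
#'
#' @param pair A contingency pair as returned by [build_contingency()].
#' @return The corrected pair, with a logical `corrected` column.
#' @export
haldane_correct <- function(pair) {
  pair <- check_pair(pair)
  cells <- as.matrix(pair[, c("g_h", "ng_h", "g_l", "ng_l")])
  zero <- rowSums(cells == 0) > 0
  cells[zero, ] <- cells[zero, , drop = FALSE] + 0.5
  pair$g_h <- cells[, "g_h"]
  pair$ng_h <- cells[, "ng_h"]
  pair$g_l <- cells[, "g_l"]
  pair$ng_l <- cells[, "ng_l"]
  pair$corrected <- zero
  pair
}

check_pair <- function(pair) {
  pair <- tibble::as_tibble(pair)
  needed <- c("g_h", "ng_h", "g_l", "ng_l")
  missing <- setdiff(needed, names(pair))
  if (length(missing) > 0L) {
    stop_validation(sprintf(
      "contingency pair is missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  cells <- as.matrix(pair[, needed])
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop_validation("contingency counts must be finite and non-negative")
  }
  pair
}

#' Mantel-Haenszel common odds ratio
#'
#' Pooled odds ratio over strata: `sum(a_s d_s / N_s) / sum(b_s c_s / N_s)`
#' with `(a, b, c, d) = (g_h, ng_h, g_l, ng_l)` and `N_s` the stratum total.
#' Strata with zero total are dropped, so a single informative stratum
#' reduces to its sample odds ratio.
#'
#' @param pair A contingency pair (see [build_contingency()]).
#' @return The pooled odds ratio (scalar).
#' @export
mh_common_odds_ratio <- function(pair) {
  pair <- check_pair(pair)
  n <- pair$g_h + pair$ng_h + pair$g_l + pair$ng_l
  keep <- n > 0
  if (!any(keep)) {
    stop_undefined("common odds ratio undefined: all strata are empty")
  }
  r <- sum((pair$g_h * pair$ng_l / n)[keep])
  s <- sum((pair$ng_h * pair$g_l / n)[keep])
  if (s == 0 || r == 0) {
    stop_undefined(
      "common odds ratio degenerate (zero numerator or denominator); apply haldane_correct() first"
    )
  }
  r / s
}

# Fitted focal-taxon heavy count per stratum under a common odds ratio psi:
# the admissible root of a (N - r1 - c1 + a) = psi (r1 - a)(c1 - a), with
# r1 the heavy-sample total and c1 the focal-taxon column total. Vectorised
# over strata/taxa.
bd_expected_a <- function(a, r1, c1, n, psi) {
  out <- numeric(length(a))
  lin <- abs(psi - 1) < 1e-12
  out[lin] <- (r1 * c1 / n)[lin]
  if (any(!lin)) {
    qa <- (1 - psi)[!lin]
    qb <- ((n - r1 - c1) + psi * (r1 + c1))[!lin]
    qc <- (-psi * r1 * c1)[!lin]
    disc <- sqrt(pmax(qb^2 - 4 * qa * qc, 0))
    root1 <- (-qb + disc) / (2 * qa)
    root2 <- (-qb - disc) / (2 * qa)
    lo <- pmax(0, (r1 + c1 - n))[!lin]
    hi <- pmin(r1, c1)[!lin]
    eps <- 1e-8 * pmax(n[!lin], 1)
    ok1 <- root1 >= lo - eps & root1 <= hi + eps
    out[!lin] <- ifelse(ok1, root1, root2)
  }
  out
}

# Vectorised Breslow-Day machinery over taxa: each argument is a vector with
# one element per taxon; suffix 1 = C12 stratum, 2 = C13 stratum. Inputs are
# assumed already continuity-corrected where needed (all margins positive).
bd_core <- function(a1, b1, c1, d1, a2, b2, c2, d2, tarone = FALSE) {
  n1 <- a1 + b1 + c1 + d1
  n2 <- a2 + b2 + c2 + d2
  psi <- (a1 * d1 / n1 + a2 * d2 / n2) / (b1 * c1 / n1 + b2 * c2 / n2)
  r1_1 <- a1 + b1; c1_1 <- a1 + c1
  r1_2 <- a2 + b2; c1_2 <- a2 + c2
  ea1 <- bd_expected_a(a1, r1_1, c1_1, n1, psi)
  ea2 <- bd_expected_a(a2, r1_2, c1_2, n2, psi)
  v1 <- 1 / (1 / ea1 + 1 / (r1_1 - ea1) + 1 / (c1_1 - ea1) +
               1 / (n1 - r1_1 - c1_1 + ea1))
  v2 <- 1 / (1 / ea2 + 1 / (r1_2 - ea2) + 1 / (c1_2 - ea2) +
               1 / (n2 - r1_2 - c1_2 + ea2))
  stat <- (a1 - ea1)^2 / v1 + (a2 - ea2)^2 / v2
  if (tarone) {
    stat <- stat - ((a1 - ea1) + (a2 - ea2))^2 / (v1 + v2)
  }
  stat <- pmax(stat, 0)
  list(
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    common_or = psi,
    expected_a = cbind(C12 = ea1, C13 = ea2),
    variance_a = cbind(C12 = v1, C13 = v2)
  )
}

#' Breslow-Day test for homogeneity of odds ratios
#'
#' Tests whether the heavy-vs-light odds ratio of a taxon is the same in the
#' 12C and 13C strata. For each stratum the focal-taxon heavy count fitted
#' under the Mantel-Haenszel common odds ratio is the admissible root of a
#' quadratic; the statistic sums the squared deviations of the observed
#' counts from these fitted counts, weighted by the inverse fitted variances,
#' and is referred to a chi-square distribution with `strata - 1` degrees of
#' freedom. Tarone's correction (subtracting the squared summed deviation
#' over the summed variance) is available behind a flag and off by default.
#'
#' @param pair A contingency pair with exactly two strata (rows); see
#'   [build_contingency()]. Cells must give positive margins -- apply
#'   [haldane_correct()] first for tables with zero cells.
#' @param tarone Apply Tarone's adjustment to the statistic.
#' @return An object of class `breslow_day` with elements `statistic`, `df`,
#'   `p_value`, `common_or`, `expected_a`, `variance_a`.
#' @examples
#' pair <- tibble::tibble(
#'   isotope = c("C12", "C13"),
#'   g_h = c(10, 30), ng_h = c(90, 70), g_l = c(10, 10), ng_l = c(90, 90)
#' )
#' breslow_day(pair)
#' @export
breslow_day <- function(pair, tarone = FALSE) {
  pair <- check_pair(pair)
  if (nrow(pair) < 2L) {
    stop_validation(
      "the Breslow-Day test needs two strata (df = strata - 1 would be 0)"
    )
  }
  if (nrow(pair) > 2L) {
    stop_validation("expected exactly two isotope strata")
  }
  r1 <- pair$g_h + pair$ng_h
  r2 <- pair$g_l + pair$ng_l
  cc1 <- pair$g_h + pair$g_l
  cc2 <- pair$ng_h + pair$ng_l
  if (any(c(r1, r2, cc1, cc2) == 0)) {
    stop_undefined(
      "degenerate margins (a zero row or column total); apply haldane_correct() first"
    )
  }
  res <- bd_core(
    pair$g_h[1], pair$ng_h[1], pair$g_l[1], pair$ng_l[1],
    pair$g_h[2], pair$ng_h[2], pair$g_l[2], pair$ng_l[2],
    tarone = tarone
  )
  structure(
    list(
      statistic = res$statistic,
      df = 1L,
      p_value = res$p_value,
      common_or = res$common_or,
      expected_a = c(C12 = res$expected_a[1, "C12"], C13 = res$expected_a[1, "C13"]),
      variance_a = c(C12 = res$variance_a[1, "C12"], C13 = res$variance_a[1, "C13"]),
      tarone = tarone
    ),
    class = "breslow_day"
  )
}

#' @export
print.breslow_day <- function(x, ...) {
  cat("Breslow-Day test for homogeneity of odds ratios\n")
  cat(sprintf(
    "X-squared = %.4f, df = %d, p-value = %.4g%s\n",
    x$statistic, x$df, x$p_value,
    if (x$tarone) " (Tarone-adjusted)" else ""
  ))
  cat(sprintf("common odds ratio (Mantel-Haenszel) = %.4f\n", x$common_or))
  invisible(x)
}

#' @export
tidy.breslow_day <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    common_or = x$common_or, tarone = x$tarone
  )
}

#' @export
glance.breslow_day <- function(x, ...) tidy(x)

#' Holm-Bonferroni step-down correction
#'
#' Orders the p-values of the `n` tested hypotheses ascending and tests the
#' `k`-th smallest against `alpha / (n + 1 - k)`, strictly: a hypothesis is
#' rejected only if `p(k) < alpha / (n + 1 - k)` and every lower-ranked
#' hypothesis was also rejected (the step-down stops at the first failure).
#' Ties are ranked stably in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise significance level in `(0, 1)`.
#' @return A tibble in input order with columns `p_value`, `rank`,
#'   `threshold` and `significant`.
#' @examples
#' holm_bonferroni(c(0.01, 0.02, 0.04), alpha = 0.05)
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must be a single value in (0, 1)")
  }
  if (length(p) == 0L) {
    return(tibble::tibble(
      p_value = numeric(0), rank = integer(0),
      threshold = numeric(0), significant = logical(0)
    ))
  }
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  n <- length(p)
  ord <- order(p) # stable: ties keep input order
  k <- seq_len(n)
  thresholds <- alpha / (n + 1 - k)
  rejected <- p[ord] < thresholds
  if (any(!rejected)) {
    first_fail <- which(!rejected)[1L]
    rejected[first_fail:n] <- FALSE
  }
  rank_of <- integer(n)
  rank_of[ord] <- k
  tibble::tibble(
    p_value = p,
    rank = rank_of,
    threshold = thresholds[rank_of],
    significant = rejected[rank_of]
  )
}

#' Classify the direction of a significant odds-ratio difference
#'
#' A significantly higher odds ratio in the 13C sample means the taxon is
#' more enriched in the heavy fraction of the 13C incubation, i.e. likely
#' 13C labelled; a significantly higher odds ratio in the 12C sample means
#' the taxon is relatively more enriched in the light fraction, i.e.
#' unlabelled. Non-significant taxa -- and the measure-zero case of exactly
#' equal odds ratios -- get direction `"none"`.
#'
#' @param or_c12,or_c13 Positive finite odds ratios (vectorised).
#' @param significant Logical vector of Holm-adjusted decisions.
#' @return Character vector in `c("labelled", "unlabelled", "none")`.
#' @export
classify_label <- function(or_c12, or_c13, significant) {
  if (any(!is.finite(or_c12) | !is.finite(or_c13) | or_c12 <= 0 | or_c13 <= 0)) {
    stop_validation("odds ratios must be finite and positive")
  }
  dplyr::case_when(
    !significant ~ "none",
    or_c13 > or_c12 ~ "labelled",
    or_c13 < or_c12 ~ "unlabelled",
    .default = "none"
  )
}

#' Screen a SIP count table for isotope-labelled taxa
#'
#' For every taxon, builds the two-stratum (12C/13C) heavy-vs-light
#' contingency pair, applies the zero-cell correction policy per stratum,
#' computes both odds ratios and the Breslow-Day homogeneity test, and
#' controls the family-wise error rate over all tested taxa with the
#' Holm-Bonferroni step-down procedure. Raw read counts are used directly:
#' no rarefaction and no relative-abundance transform, so statistical power
#' grows with per-sample sequencing depth.
#'
#' @param table A [sip_table()] containing the four screening samples for
#'   `treatment`.
#' @param treatment Treatment label; may be omitted when the table holds a
#'   single treatment.
#' @param alpha Family-wise significance level (default 0.05).
#' @param correction Zero-cell policy, `"haldane"` (default) or `"strict"`;
#'   see [odds_ratio()].
#' @param tarone Apply Tarone's adjustment to the Breslow-Day statistic.
#' @param min_total Minimum total reads over the four samples for a taxon to
#'   be tested (default 0: every taxon with at least one read is tested, and
#'   the Holm `n` equals the number of taxa actually tested).
#' @return A tibble of class `sip_screen`, one row per tested taxon, ordered
#'   by Holm rank, with columns `otu_id`, `or_c12`, `or_c13`, `corrected`,
#'   `or_mh`, `statistic`, `df`, `p_value`, `holm_rank`, `holm_threshold`,
#'   `significant`, `direction`.
#' @examples
#' profile <- simulate_community(n_taxa = 50, labelled_fraction = 0.1, seed = 1)
#' expt <- simulate_sip_experiment(profile, seed = 1)
#' run_labelling_screen(expt$table)
#' @export
run_labelling_screen <- function(table, treatment = NULL, alpha = 0.05,
                                 correction = c("haldane", "strict"),
                                 tarone = FALSE, min_total = 0) {
  stopifnot(inherits(table, "sip_table"))
  correction <- match.arg(correction)
  samp <- fraction_samples(table, treatment)
  treatment <- table$meta$treatment[match(samp[[1L]], table$meta$sample_id)]

  cm <- as.matrix(table$counts[, samp, drop = FALSE])
  storage.mode(cm) <- "numeric"
  rownames(cm) <- table$counts$otu_id
  totals <- colSums(cm)

  all_zero <- rowSums(cm) == 0
  if (any(all_zero)) {
    inform(sprintf(
      "skipping %d taxa with zero reads in all four samples", sum(all_zero)
    ))
    cm <- cm[!all_zero, , drop = FALSE]
  }
  if (min_total > 0) {
    cm <- cm[rowSums(cm) >= min_total, , drop = FALSE]
  }
  if (nrow(cm) == 0L) {
    return(new_sip_screen(empty_screen_tbl(), alpha, correction, tarone,
                          treatment, samp))
  }

  # Per-taxon stratum cells: a = focal heavy, b = other heavy, c = focal
  # light, d = other light.
  a1 <- cm[, samp[["C12.heavy"]]]
  b1 <- totals[[samp[["C12.heavy"]]]] - a1
  c1 <- cm[, samp[["C12.light"]]]
  d1 <- totals[[samp[["C12.light"]]]] - c1
  a2 <- cm[, samp[["C13.heavy"]]]
  b2 <- totals[[samp[["C13.heavy"]]]] - a2
  c2 <- cm[, samp[["C13.light"]]]
  d2 <- totals[[samp[["C13.light"]]]] - c2

  zero1 <- a1 == 0 | b1 == 0 | c1 == 0 | d1 == 0
  zero2 <- a2 == 0 | b2 == 0 | c2 == 0 | d2 == 0
  if (correction == "strict" && any(zero1 | zero2)) {
    stop_undefined(sprintf(
      "%d taxa have a zero cell; rerun with correction = 'haldane' or filter with min_total",
      sum(zero1 | zero2)
    ))
  }
  a1[zero1] <- a1[zero1] + 0.5; b1[zero1] <- b1[zero1] + 0.5
  c1[zero1] <- c1[zero1] + 0.5; d1[zero1] <- d1[zero1] + 0.5
  a2[zero2] <- a2[zero2] + 0.5; b2[zero2] <- b2[zero2] + 0.5
  c2[zero2] <- c2[zero2] + 0.5; d2[zero2] <- d2[zero2] + 0.5

  bd <- bd_core(a1, b1, c1, d1, a2, b2, c2, d2, tarone = tarone)

  res <- tibble::tibble(
    otu_id = rownames(cm),
    or_c12 = (a1 / b1) / (c1 / d1),
    or_c13 = (a2 / b2) / (c2 / d2),
    corrected = zero1 | zero2,
    or_mh = bd$common_or,
    statistic = bd$statistic,
    df = 1L,
    p_value = bd$p_value
  )
  # Rank ties deterministically: Holm's stable tie-break follows input
  # order, so feed taxa in lexicographic otu_id order.
  res <- dplyr::arrange(res, .data$otu_id)
  hb <- holm_bonferroni(res$p_value, alpha = alpha)
  res$holm_rank <- hb$rank
  res$holm_threshold <- hb$threshold
  res$significant <- hb$significant
  res$direction <- classify_label(res$or_c12, res$or_c13, res$significant)
  res <- dplyr::arrange(res, .data$holm_rank)
  new_sip_screen(res, alpha, correction, tarone, treatment, samp)
}

empty_screen_tbl <- function() {
  tibble::tibble(
    otu_id = character(0), or_c12 = numeric(0), or_c13 = numeric(0),
    corrected = logical(0), or_mh = numeric(0), statistic = numeric(0),
    df = integer(0), p_value = numeric(0), holm_rank = integer(0),
    holm_threshold = numeric(0), significant = logical(0),
    direction = character(0)
  )
}

new_sip_screen <- function(tbl, alpha, correction, tarone, treatment, samples) {
  structure(
    tbl,
    class = c("sip_screen", "tbl_df", "tbl", "data.frame"),
    alpha = alpha, correction = correction, tarone = tarone,
    treatment = treatment, samples = samples
  )
}

#' @export
tidy.sip_screen <- function(x, ...) {
  tibble::as_tibble(unclass_screen(x))
}

unclass_screen <- function(x) {
  attr(x, "alpha") <- NULL
  attr(x, "correction") <- NULL
  attr(x, "tarone") <- NULL
  attr(x, "treatment") <- NULL
  attr(x, "samples") <- NULL
  class(x) <- setdiff(class(x), "sip_screen")
  x
}

#' @export
glance.sip_screen <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    n_labelled = sum(x$direction == "labelled"),
    n_unlabelled = sum(x$direction == "unlabelled"),
    alpha = attr(x, "alpha"),
    correction = attr(x, "correction"),
    tarone = attr(x, "tarone"),
    treatment = attr(x, "treatment") %||% NA_character_
  )
}

#' Aggregate labelled taxa at a taxonomic rank
#'
#' Among taxa called `labelled`, sums the reads observed in the 13C heavy
#' fraction sample per taxonomic group at the requested rank and normalises
#' to relative abundance over the labelled taxa -- the composition of the
#' labelled community as seen in the heavy DNA.
#'
#' @param calls A [run_labelling_screen()] result.
#' @param taxonomy Taxonomy tibble from [read_taxonomy()] (or `NULL`, in
#'   which case everything is `"unclassified"`).
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param table The [sip_table()] the screen was run on.
#' @return A tibble of class `sip_composition` with columns `group`, `reads`
#'   and `rel_abundance` (summing to 1 when any taxon is labelled); empty
#'   when no taxon is labelled.
#' @export
aggregate_labelled_taxa <- function(calls, taxonomy = NULL, rank = "class",
                                    table) {
  rank <- match.arg(rank, tax_ranks)
  stopifnot(inherits(table, "sip_table"))
  samples <- attr(calls, "samples")
  if (is.null(samples)) {
    samples <- fraction_samples(table, attr(calls, "treatment"))
  }
  heavy13 <- samples[["C13.heavy"]]
  labelled <- calls$otu_id[calls$direction == "labelled"]
  if (length(labelled) == 0L) {
    out <- tibble::tibble(
      group = character(0), reads = numeric(0), rel_abundance = numeric(0)
    )
    return(structure(out, class = c("sip_composition", class(out)),
                     rank = rank))
  }
  reads <- table$counts[[heavy13]][match(labelled, table$counts$otu_id)]
  lin <- lookup_lineage(taxonomy, labelled)
  out <- tibble::tibble(group = lin[[rank]], reads = as.numeric(reads)) |>
    dplyr::summarise(reads = sum(.data$reads), .by = "group") |>
    dplyr::arrange(dplyr::desc(.data$reads), .data$group)
  total <- sum(out$reads)
  out$rel_abundance <- if (total > 0) out$reads / total else 0
  structure(out, class = c("sip_composition", "tbl_df", "tbl", "data.frame"),
            rank = rank)
}
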