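# Shared fixtures, built in code.

screen_meta <- function(treatment = "starch",
                        sample_ids = paste(treatment,
                                           c("C12_light", "C12_heavy",
                                             "C13_light", "C13_heavy"),
                                           sep = "_")) {
  tibble::tibble(
    sample_id = sample_ids,
    isotope = c("C12", "C12", "C13", "C13"),
    fraction_role = c("light", "heavy", "light", "heavy"),
    treatment = treatment,
    density = c(1.700, 1.725, 1.700, 1.725)
  )
}

# Two-taxon toy design: the focal taxon has (heavy, light) = (30, 10) of
# 100-read samples in the 13C stratum and (10, 10) in the 12C stratum.
toy_table <- function() {
  meta <- screen_meta()
  counts <- tibble::as_tibble(c(
    list(otu_id = c("Otu001", "Otu002")),
    stats::setNames(
      list(c(10L, 90L), c(10L, 90L), c(10L, 90L), c(30L, 70L)),
      meta$sample_id
    )
  ))
  sip_table(counts, meta)
}

write_mothur_fixture <- function(path,
                                 groups = c("s1", "s2"),
                                 otus = c("Otu001", "Otu002"),
                                 counts = rbind(c(5L, 7L), c(11L, 0L)),
                                 num_otus = length(otus)) {
  header <- paste(c("label", "Group", "numOtus", otus), collapse = "\t")
  rows <- vapply(seq_along(groups), function(i) {
    paste(c("0.03", groups[i], num_otus, counts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# Brute-force Breslow-Day oracle: numeric root search for the fitted heavy
# count, then the literal weighted sum of squared deviations.
bd_oracle <- function(pair, tarone = FALSE) {
  n <- pair$g_h + pair$ng_h + pair$g_l + pair$ng_l
  psi <- sum(pair$g_h * pair$ng_l / n) / sum(pair$ng_h * pair$g_l / n)
  ea <- numeric(nrow(pair))
  va <- numeric(nrow(pair))
  for (s in seq_len(nrow(pair))) {
    a <- pair$g_h[s]; b <- pair$ng_h[s]; c <- pair$g_l[s]; d <- pair$ng_l[s]
    r1 <- a + b; c1 <- a + c; nn <- a + b + c + d
    f <- function(x) x * (nn - r1 - c1 + x) - psi * (r1 - x) * (c1 - x)
    lo <- max(0, r1 + c1 - nn); hi <- min(r1, c1)
    ea[s] <- stats::uniroot(f, c(lo + 1e-12, hi - 1e-12), tol = 1e-12)$root
    va[s] <- 1 / (1 / ea[s] + 1 / (r1 - ea[s]) + 1 / (c1 - ea[s]) +
                    1 / (nn - r1 - c1 + ea[s]))
  }
  stat <- sum((pair$g_h - ea)^2 / va)
  if (tarone) stat <- stat - sum(pair$g_h - ea)^2 / sum(va)
  list(statistic = stat, expected_a = ea,
       p_value = stats::pchisq(stat, df = nrow(pair) - 1, lower.tail = FALSE))
}

random_corrected_pair <- function() {
  cells <- matrix(sample(0:50, 8, replace = TRUE), nrow = 2)
  pair <- tibble::tibble(
    isotope = c("C12", "C13"),
    g_h = cells[, 1], ng_h = cells[, 2], g_l = cells[, 3], ng_l = cells[, 4]
  )
  haldane_correct(pair)
}

# Literal transcription of the published step-down rule: order p ascending,
# reject the k-th while p(k) < alpha / (n + 1 - k), stop at the first failure.
holm_oracle <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  rejected <- logical(n)
  for (k in seq_len(n)) {
    if (p[ord[k]] < alpha / (n + 1 - k)) {
      rejected[ord[k]] <- TRUE
    } else {
      break
    }
  }
  rejected
}
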