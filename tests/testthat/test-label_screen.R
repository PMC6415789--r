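test_that("odds ratios follow the heavy/light definition and Haldane policy", {
  expect_equal(odds_ratio(10, 90, 10, 90), 1)
  expect_equal(odds_ratio(20, 80, 10, 90), (20 / 80) / (10 / 90))
  # zero cell: 0.5 added to all four cells under the default policy
  expect_equal(odds_ratio(0, 100, 10, 90), (0.5 / 100.5) / (10.5 / 90.5))
  expect_error(odds_ratio(0, 100, 10, 90, correction = "strict"),
               class = "siplabel_error_undefined")
  expect_error(odds_ratio(0, 0, 0, 0), class = "siplabel_error_undefined")
  expect_error(odds_ratio(-1, 1, 1, 1), class = "siplabel_error_validation")

  # scale invariance without correction
  withr::local_seed(11)
  for (i in 1:20) {
    cells <- sample(1:50, 4)
    k <- sample(2:9, 1)
    expect_equal(
      odds_ratio(cells[1], cells[2], cells[3], cells[4]),
      odds_ratio(k * cells[1], k * cells[2], k * cells[3], k * cells[4])
    )
  }
})

test_that("contingency pairs conserve sample totals", {
  pair <- build_contingency(toy_table(), "Otu001")
  expect_equal(pair$g_h, c(10, 30))
  expect_equal(pair$ng_h, c(90, 70))
  expect_equal(pair$g_l, c(10, 10))
  expect_equal(pair$ng_l, c(90, 90))
  # absent-from-table taxon errors; all-zero taxon gives nG = totals
  expect_error(build_contingency(toy_table(), "OtuX"),
               class = "siplabel_error_validation")

  meta <- screen_meta()
  counts <- toy_table()$counts
  counts[[meta$sample_id[4]]] <- c(0L, 100L)
  pair0 <- build_contingency(sip_table(counts, meta), "Otu001")
  expect_equal(pair0$g_h[2], 0)
  expect_equal(pair0$ng_h[2], 100)

  # a missing (isotope, role) sample is a configuration error naming it
  err <- expect_error(
    run_labelling_screen(sip_table(counts[, -2], meta[-1, ])),
    class = "siplabel_error_config"
  )
  expect_match(conditionMessage(err), "C12, light")
})

test_that("Mantel-Haenszel common OR pools strata and reduces correctly", {
  pair1 <- tibble::tibble(g_h = c(10, 10), ng_h = c(10, 10),
                          g_l = c(10, 10), ng_l = c(10, 10))
  expect_equal(mh_common_odds_ratio(pair1), 1)
  # empty second stratum drops out: single-stratum sample OR
  pair2 <- tibble::tibble(g_h = c(20, 0), ng_h = c(80, 0),
                          g_l = c(10, 0), ng_l = c(90, 0))
  expect_equal(mh_common_odds_ratio(pair2), (20 / 80) / (10 / 90))
  # hand-computed two-stratum value
  pair3 <- tibble::tibble(g_h = c(30, 10), ng_h = c(70, 90),
                          g_l = c(10, 10), ng_l = c(90, 90))
  r <- 30 * 90 / 200 + 10 * 90 / 200
  s <- 70 * 10 / 200 + 90 * 10 / 200
  expect_equal(mh_common_odds_ratio(pair3), r / s)
})

test_that("Breslow-Day matches the numeric-root oracle and handles edges", {
  # homogeneous strata: statistic exactly 0, p = 1
  pair <- tibble::tibble(isotope = c("C12", "C13"),
                         g_h = c(10, 10), ng_h = c(10, 10),
                         g_l = c(10, 10), ng_l = c(10, 10))
  bd <- breslow_day(pair)
  expect_equal(bd$statistic, 0)
  expect_equal(bd$p_value, 1)
  expect_equal(bd$df, 1L)

  # heterogeneous example frozen against an independent root-search oracle
  pair2 <- tibble::tibble(isotope = c("C12", "C13"),
                          g_h = c(10, 30), ng_h = c(10, 10),
                          g_l = c(10, 10), ng_l = c(10, 30))
  bd2 <- breslow_day(pair2)
  expect_equal(bd2$statistic, 7.445626465, tolerance = 1e-8)
  expect_equal(bd2$p_value, 0.006359078, tolerance = 1e-6)
  expect_equal(unname(bd2$expected_a[1]), 13.13859338, tolerance = 1e-7)
  expect_equal(bd2$common_or, 11 / 3)

  # single stratum: df would be 0
  expect_error(breslow_day(pair2[1, ]), class = "siplabel_error_validation")
  # degenerate margins point at the correction policy
  pair3 <- tibble::tibble(g_h = c(0, 5), ng_h = c(0, 5),
                          g_l = c(3, 5), ng_l = c(4, 5))
  expect_error(breslow_day(pair3), regexp = "haldane",
               class = "siplabel_error_undefined")

  # expected counts stay inside their admissible margin box
  withr::local_seed(21)
  for (i in 1:25) {
    p <- random_corrected_pair()
    bd <- breslow_day(p)
    r1 <- p$g_h + p$ng_h
    c1 <- p$g_h + p$g_l
    n <- r1 + p$g_l + p$ng_l
    expect_true(all(bd$expected_a >= pmax(0, r1 + c1 - n)))
    expect_true(all(bd$expected_a <= pmin(r1, c1)))
    expect_gte(bd$statistic, 0)
    expect_true(bd$p_value >= 0 && bd$p_value <= 1)
  }
})

test_that("closed-form expected counts agree with brute-force root search", {
  withr::local_seed(31)
  for (i in 1:100) {
    pair <- random_corrected_pair()
    oracle <- bd_oracle(pair)
    bd <- breslow_day(pair)
    expect_equal(unname(bd$expected_a), oracle$expected_a, tolerance = 1e-8)
    expect_equal(bd$statistic, oracle$statistic, tolerance = 1e-8)
  }
  # Tarone's adjustment only ever shrinks the statistic
  withr::local_seed(32)
  for (i in 1:20) {
    pair <- random_corrected_pair()
    expect_lte(breslow_day(pair, tarone = TRUE)$statistic,
               breslow_day(pair)$statistic + 1e-12)
    expect_equal(breslow_day(pair, tarone = TRUE)$statistic,
                 bd_oracle(pair, tarone = TRUE)$statistic, tolerance = 1e-8)
  }
})

test_that("Holm step-down implements the published threshold rule", {
  res <- holm_bonferroni(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_equal(res$threshold, c(0.05 / 3, 0.025, 0.05))
  expect_true(all(res$significant))

  res2 <- holm_bonferroni(c(0.02, 0.5), alpha = 0.05)
  expect_equal(res2$significant, c(TRUE, FALSE))

  expect_false(any(holm_bonferroni(c(1, 1), alpha = 0.05)$significant))

  # strict inequality: p equal to its threshold is not rejected
  expect_false(any(holm_bonferroni(c(0.025, 0.9), alpha = 0.05)$significant))

  # step-down stops at the first failure even if later p pass their level
  res3 <- holm_bonferroni(c(0.03, 0.04), alpha = 0.05)
  expect_equal(res3$significant, c(FALSE, FALSE))

  expect_equal(nrow(holm_bonferroni(numeric(0))), 0L)
  expect_error(holm_bonferroni(c(0.5, 1.2)), class = "siplabel_error_validation")
  expect_error(holm_bonferroni(0.5, alpha = 1), class = "siplabel_error_validation")
})

test_that("Holm decisions nest between Bonferroni and unadjusted", {
  withr::local_seed(41)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    p <- round(runif(n), sample(1:3, 1)) # ties on purpose
    alpha <- runif(1, 0.01, 0.2)
    res <- holm_bonferroni(p, alpha)
    expect_equal(res$significant, holm_oracle(p, alpha))
    bonf <- p < alpha / n
    expect_true(all(res$significant[bonf]))
    expect_true(all(p[res$significant] < alpha))
    # agreement with the standard adjusted-p formulation
    expect_equal(res$significant, stats::p.adjust(p, "holm") < alpha)
  }
})

test_that("direction classification follows the odds-ratio comparison", {
  expect_equal(classify_label(1, 5, TRUE), "labelled")
  expect_equal(classify_label(5, 1, TRUE), "unlabelled")
  expect_equal(classify_label(5, 1, FALSE), "none")
  expect_equal(classify_label(2, 2, TRUE), "none") # tie carries no direction
  expect_error(classify_label(0, 1, TRUE), class = "siplabel_error_validation")
})

test_that("screen on identical 12C/13C samples finds nothing", {
  meta <- screen_meta()
  counts <- toy_table()$counts
  counts[[meta$sample_id[3]]] <- counts[[meta$sample_id[1]]]
  counts[[meta$sample_id[4]]] <- counts[[meta$sample_id[2]]]
  scr <- run_labelling_screen(sip_table(counts, meta))
  expect_true(all(scr$statistic < 1e-10))
  expect_true(all(scr$p_value > 1 - 1e-6))
  expect_false(any(scr$significant))
  expect_true(all(scr$direction == "none"))
})

test_that("screen recovers strongly labelled taxa and respects its contracts", {
  hits <- 0
  for (seed in 1:20) {
    prof <- simulate_community(200, labelled_fraction = 5 / 200, seed = seed)
    expt <- simulate_sip_experiment(prof, seed = seed)
    scr <- suppressMessages(run_labelling_screen(expt$table))
    truth <- expt$truth
    lab <- scr$otu_id[scr$direction == "labelled"]
    hits <- hits + sum(truth$otu_id[truth$labelled] %in% lab)
    expect_equal(sum(lab %in% truth$otu_id[!truth$labelled]), 0)
    # step-down property: everything ranked below a rejection is rejected
    if (any(scr$significant)) {
      kmax <- max(scr$holm_rank[scr$significant])
      expect_true(all(scr$significant[scr$holm_rank <= kmax]))
      expect_true(all(scr$p_value[scr$significant] <
                        scr$holm_threshold[scr$significant]))
    }
    # directions require significance and the right OR ordering
    expect_true(all(scr$or_c13[scr$direction == "labelled"] >
                      scr$or_c12[scr$direction == "labelled"]))
    expect_true(all(scr$or_c13[scr$direction == "unlabelled"] <
                      scr$or_c12[scr$direction == "unlabelled"]))
    expect_true(all(scr$significant[scr$direction != "none"]))
  }
  expect_gte(hits / 20, 4 / 5 * 5)
})

test_that("screen options behave: min_total, strict policy, empty table", {
  tab <- toy_table()
  expect_equal(nrow(run_labelling_screen(tab, min_total = 1000)), 0L)
  scr <- run_labelling_screen(tab, min_total = 0)
  expect_equal(nrow(scr), 2L)
  # n in Holm equals the number of taxa actually tested
  expect_equal(scr$holm_threshold[scr$holm_rank == 1], 0.05 / 2)

  meta <- screen_meta()
  counts <- tab$counts
  counts[[meta$sample_id[2]]] <- c(0L, 100L)
  expect_error(
    run_labelling_screen(sip_table(counts, meta), correction = "strict"),
    class = "siplabel_error_undefined"
  )
  # haldane flags the corrected taxon
  scr2 <- run_labelling_screen(sip_table(counts, meta))
  expect_true(scr2$corrected[scr2$otu_id == "Otu001"])
  expect_true(all(is.finite(scr2$or_c12)) && all(scr2$or_c12 > 0))

  # all-zero taxa are skipped with a notice
  counts2 <- rbind(counts, tibble::tibble(
    otu_id = "Otu999",
    !!meta$sample_id[1] := 0L, !!meta$sample_id[2] := 0L,
    !!meta$sample_id[3] := 0L, !!meta$sample_id[4] := 0L
  ))
  expect_message(
    scr3 <- run_labelling_screen(sip_table(counts2, meta)),
    regexp = "zero reads"
  )
  expect_false("Otu999" %in% scr3$otu_id)
})

test_that("labelled-community aggregation normalizes heavy-fraction reads", {
  meta <- screen_meta()
  counts <- tibble::as_tibble(c(
    list(otu_id = c("OtuA1", "OtuA2", "OtuB1", "OtuC1")),
    stats::setNames(list(
      c(10L, 10L, 10L, 70L), c(10L, 10L, 10L, 70L),
      c(10L, 10L, 10L, 70L), c(30L, 10L, 60L, 0L)
    ), meta$sample_id)
  ))
  tab <- sip_table(counts, meta)
  tax <- tibble::tibble(
    otu_id = c("OtuA1", "OtuA2", "OtuB1"),
    domain = "Bacteria", phylum = "P", class = c("A", "A", "B"),
    order = "o", family = "f", genus = "g"
  )
  calls <- run_labelling_screen(tab)
  calls$direction <- c("labelled", "labelled", "labelled", "none")[
    match(calls$otu_id, c("OtuA1", "OtuA2", "OtuB1", "OtuC1"))
  ]
  comp <- aggregate_labelled_taxa(calls, tax, rank = "class", table = tab)
  expect_equal(comp$rel_abundance[comp$group == "A"], 0.4)
  expect_equal(comp$rel_abundance[comp$group == "B"], 0.6)

  # single labelled taxon: its class carries everything
  calls$direction <- ifelse(calls$otu_id == "OtuB1", "labelled", "none")
  comp1 <- aggregate_labelled_taxa(calls, tax, rank = "class", table = tab)
  expect_equal(comp1$rel_abundance, 1)
  expect_equal(comp1$group, "B")

  # no labelled taxa: empty result
  calls$direction <- "none"
  expect_equal(
    nrow(aggregate_labelled_taxa(calls, tax, rank = "class", table = tab)), 0L
  )
})

test_that("screen results expose tidy/glance summaries", {
  scr <- run_labelling_screen(toy_table())
  expect_s3_class(tidy(scr), "tbl_df")
  g <- glance(scr)
  expect_equal(g$n_tested, 2L)
  expect_equal(g$alpha, 0.05)
  expect_equal(g$treatment, "starch")
  expect_equal(g$n_labelled, sum(scr$direction == "labelled"))
})
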