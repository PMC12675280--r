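test_that("density is count over region size in either mode", {
  counts <- tibble::tibble(region_id = c(1L, 2L), subject_id = "a",
                           group = "FR", count = c(0L, 30L))
  ont <- tibble::tibble(id = c(1L, 2L), size_mm3 = c(1, 0.2))
  d <- make_density(counts, ont)
  expect_equal(d$density, c(0, 150))
  expect_equal(attr(d, "mode"), "3D")

  # slice-mode convention: 28.2 cells over 0.1 mm^2 -> 282 per mm^2
  counts2 <- tibble::tibble(region_id = 1L, subject_id = "a", group = "FR",
                            count = 28.2)
  ont2 <- tibble::tibble(id = 1L, size_mm3 = 0.1)
  expect_equal(make_density(counts2, ont2, mode = "2D")$density, 282)

  expect_error(make_density(counts, tibble::tibble(id = 1L, size_mm3 = 1)),
               "missing from the ontology")
  expect_error(make_density(counts, tibble::tibble(id = c(1L, 2L),
                                                   size_mm3 = c(1, 0))),
               "positive")
})

test_that("region filtering drops flagged rows, keeps children, logs reasons", {
  # synthetic ontology mirroring the atlas reduction: 839 segmented
  # regions of which 162 are flagged -> 677 analysable regions
  sim <- simulate_region_counts(region_sim_config(
    n_regions = 677, n_ventricular = 120, n_aggregate = 42, seed = 1))
  expect_equal(nrow(sim$ontology), 839)
  kept <- filter_regions(sim$counts, sim$ontology)
  expect_equal(dplyr::n_distinct(kept$region_id), 677)
  log <- attr(kept, "exclusion_log")
  expect_equal(nrow(log), 162)
  expect_setequal(unique(log$reason),
                  c("ventricular_niche", "aggregate_structure"))

  # flags off -> unchanged
  same <- filter_regions(sim$counts, sim$ontology,
                         drop_ventricular = FALSE, drop_aggregates = FALSE)
  expect_equal(nrow(same), nrow(sim$counts))

  # dropping an aggregate removes only its own row, not its children
  ont <- tibble::tibble(id = 1:3, acronym = c("AGG", "a", "b"),
                        name = c("agg", "a", "b"),
                        parent_id = c(NA, 1L, 1L), size_mm3 = 1,
                        is_ventricular = FALSE,
                        is_aggregate = c(TRUE, FALSE, FALSE))
  tbl <- tibble::tibble(region_id = 1:3, subject_id = "s", group = "FR",
                        count = 1L)
  out <- filter_regions(tbl, ont)
  expect_equal(out$region_id, c(2L, 3L))
})

test_that("fold changes divide group means by the reference mean", {
  d <- tibble::tibble(
    region_id = rep(1L, 10),
    group = c(rep("NoFC", 4), rep("FR", 3), rep("FC", 3)),
    density = c(2, 2, 2, 2, 6, 6, 6, 2, 2, 2)
  )
  fc <- fold_changes(d)
  expect_equal(fc$fold_change[fc$group == "FR"], 3)
  expect_equal(fc$fold_change[fc$group == "FC"], 1)
  expect_equal(fc$fold_change[fc$group == "NoFC"], 1)

  # zero reference mean -> undefined, flagged as NA (not infinite)
  d0 <- d
  d0$density[d0$group == "NoFC"] <- 0
  fc0 <- fold_changes(d0)
  expect_true(all(is.na(fc0$fold_change[fc0$group == "FR"])))

  # multiplying one group's values by c multiplies its FC by c exactly
  dc <- d
  dc$density[dc$group == "FR"] <- dc$density[dc$group == "FR"] * 2.5
  fcc <- fold_changes(dc)
  expect_equal(fcc$fold_change[fcc$group == "FR"], 3 * 2.5)

  expect_error(fold_changes(d, reference_group = "nope"), "not present")
})

test_that("Levene routing sends heteroscedastic regions down the rank path", {
  # group A constant, group B wildly dispersed (plus two quiet groups):
  # Brown-Forsythe on |deviations from group medians| must reject
  d <- tibble::tibble(
    region_id = 1L,
    group = rep(c("NoFC", "FC", "NoFR", "FR"), each = 4),
    value = c(5, 5, 5, 5, -10, 10, -10, 10, 1, 2, 1, 2, 1, 2, 1, 2)
  )
  scr <- screen_regions(d, min_n = 3)
  expect_equal(unique(scr$route), "kw_dunn")
  expect_lt(unique(scr$levene_p), 0.05)

  # hand Levene on the absolute deviations from group medians
  z <- abs(d$value - stats::ave(d$value, d$group, FUN = median))
  p_hand <- summary(stats::aov(z ~ factor(d$group)))[[1]][["Pr(>F)"]][1]
  expect_equal(unique(scr$levene_p), p_hand, tolerance = 1e-12)
})

test_that("routing and routed p-values agree with the standard tests", {
  # independent oracles on 200 random tables: car::leveneTest decides the
  # route; aov/TukeyHSD and kruskal.test reproduce the routed p-values
  set.seed(202)
  for (i in 1:200) {
    g <- rep(c("NoFC", "FC", "NoFR", "FR"), times = c(6, 4, 4, 4))
    v <- rnbinom(18, mu = 20, size = 2) *
      ifelse(g == "FR" & i %% 3 == 0, sample(1:3, 1), 1)
    if (length(unique(v)) == 1) next
    d <- tibble::tibble(region_id = 1L, group = g, value = as.numeric(v))
    scr <- screen_regions(d)

    lv <- suppressWarnings(car::leveneTest(v ~ factor(g), center = median))
    p_lv <- lv[["Pr(>F)"]][1]
    expect_equal(unique(scr$levene_p), p_lv, tolerance = 1e-10)
    route_oracle <- if (is.na(p_lv) || p_lv > 0.05) "anova_tukey" else "kw_dunn"
    expect_equal(unique(scr$route), route_oracle)

    if (route_oracle == "anova_tukey") {
      fit <- stats::aov(v ~ factor(g))
      expect_equal(unique(scr$omnibus_p),
                   summary(fit)[[1]][["Pr(>F)"]][1], tolerance = 1e-10)
      tk <- stats::TukeyHSD(fit)[[1]]
      ours <- scr$p[match(rownames(tk), scr$comparison)]
      expect_equal(unname(ours), unname(tk[, "p adj"]), tolerance = 1e-8)
    } else {
      expect_equal(unique(scr$omnibus_p),
                   stats::kruskal.test(v, factor(g))$p.value,
                   tolerance = 1e-10)
    }
  }
})

test_that("Dunn post hoc matches an independent rank computation", {
  set.seed(77)
  for (i in 1:25) {
    g <- rep(c("A", "B", "C"), times = c(5, 4, 6))
    v <- c(rnorm(5, 0, 1), rnorm(4, 2, 4), rnorm(6, 0, 0.2))
    ours <- gliatrace:::dunn_posthoc(v, g)

    # independent computation straight from the definition
    rk <- rank(v)
    n <- length(v)
    ties <- table(v)
    s2 <- (n * (n + 1) / 12) - sum(ties^3 - ties) / (12 * (n - 1))
    pair <- c("B-A", "C-A", "C-B")
    z <- vapply(list(c("B", "A"), c("C", "A"), c("C", "B")), function(ab) {
      (mean(rk[g == ab[1]]) - mean(rk[g == ab[2]])) /
        sqrt(s2 * (1 / sum(g == ab[1]) + 1 / sum(g == ab[2])))
    }, numeric(1))
    p <- pmin(1, 2 * pnorm(-abs(z)) * 3)
    expect_equal(ours$p[match(pair, ours$comparison)], p, tolerance = 1e-12)
  }
})

test_that("regions with insufficient or degenerate data are skipped", {
  d <- dplyr::bind_rows(
    tibble::tibble(region_id = 1L,
                   group = rep(c("NoFC", "FC", "NoFR", "FR"), each = 4),
                   value = rnorm(16)),
    tibble::tibble(region_id = 2L,                       # FR has n = 2 < 3
                   group = c(rep("NoFC", 4), rep("FC", 4), rep("NoFR", 4),
                             rep("FR", 2)),
                   value = rnorm(14)),
    tibble::tibble(region_id = 3L,                       # all identical
                   group = rep(c("NoFC", "FC", "NoFR", "FR"), each = 4),
                   value = 1)
  )
  scr <- screen_regions(d, min_n = 3)
  expect_equal(unique(scr$region_id), 1L)
  skipped <- attr(scr, "skipped")
  expect_equal(skipped$reason[skipped$region_id == 2], "insufficient_n")
  expect_equal(skipped$reason[skipped$region_id == 3], "degenerate_values")
  # skipped regions never enter the FDR family
  expect_equal(nrow(scr), 6)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03)$q, 0.03)            # single p: q = p
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))

  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p)$q, bh_brute_force(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # significance convention: q strictly below alpha
  out <- bh_adjust(c(0.04, 0.05), alpha = 0.05)
  expect_equal(out$significant, c(out$q[1] < 0.05, out$q[2] < 0.05))
})

test_that("ensemble correlation selects regions and matches Pearson", {
  # perfect anticorrelation by hand: x = 1,2,3 / y = 6,4,2 -> r = -1
  d <- tibble::tibble(region_id = 1:3, delta_a = c(1, 2, 3),
                      delta_b = c(6, 4, 2))
  res <- engram_correlation(d)
  expect_equal(res$r, -1)

  # identical deltas -> r = 1
  d2 <- tibble::tibble(region_id = 1:5, delta_a = rnorm(5))
  d2$delta_b <- d2$delta_a
  expect_equal(engram_correlation(d2)$r, 1)

  # selection bookkeeping mirroring the engram-region reduction:
  # 117 candidate regions, exclusions bring the analysis set to 75
  set.seed(1)
  d3 <- tibble::tibble(
    region_id = 1:117,
    delta_a = rnorm(117), delta_b = rnorm(117),
    engram_significant = TRUE,
    is_ventricular = c(rep(TRUE, 30), rep(FALSE, 87)),
    is_aggregate = c(rep(FALSE, 30), rep(TRUE, 12), rep(FALSE, 75))
  )
  res3 <- engram_correlation(d3)
  expect_equal(res3$n_regions, 75)
  expect_equal(sum(!res3$selection_log$kept), 42)
  expect_equal(res3$r, unname(stats::cor(d3$delta_a[43:117],
                                         d3$delta_b[43:117])))
  expect_equal(tidy(res3)$n_regions, 75)

  expect_error(engram_correlation(d[1:2, ]), "Fewer than 3")
  d4 <- tibble::tibble(region_id = 1:4, delta_a = 1, delta_b = rnorm(4))
  expect_error(engram_correlation(d4), "Zero variance")
})

test_that("screen glance summarises routes and discoveries", {
  sim <- simulate_region_counts(region_sim_config(
    n_regions = 40, effect_regions = 1:4, effect_multiplier = 4, seed = 2))
  kept <- filter_regions(make_density(sim$counts, sim$ontology), sim$ontology)
  scr <- screen_regions(kept)
  g <- glance(scr)
  expect_equal(g$n_regions, 40)
  expect_equal(g$n_comparisons, 40 * 6)
  expect_equal(g$n_anova_tukey + g$n_kw_dunn, 40)
  expect_true(all(scr$q >= scr$p))
  expect_identical(scr$significant, scr$q < 0.05)
  # fold-change column: FR-NoFC rows in effect regions are elevated
  fr_rows <- scr[scr$comparison %in% c("FR-NoFC", "NoFC-FR"), ]
  fc_eff <- fr_rows$fold_change[fr_rows$region_id %in% 1:4]
  fc_null <- fr_rows$fold_change[!fr_rows$region_id %in% 1:4]
  if (all(fr_rows$comparison == "NoFC-FR")) {
    expect_lt(mean(fc_eff), mean(fc_null))
  } else {
    expect_gt(mean(fc_eff), mean(fc_null))
  }
})
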