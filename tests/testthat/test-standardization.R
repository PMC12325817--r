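make_two_group_panel <- function() {
  # 2 groups x 10 persons: events 1/10 in G1, 5/10 in G2
  patient_panel(
    data.frame(
      person_id = sprintf("p%02d", 1:20),
      region_id = rep(c("R1", "R2"), 10L),
      popgroup_id = rep(c("G1", "G2"), each = 10L),
      macro_popgroup_id = "M1",
      age = 50L, sex = "female",
      hospitalization = c(rep(0, 9), 1, rep(1, 5), rep(0, 5)),
      stringsAsFactors = FALSE),
    outcome_types = c(hospitalization = "binary"))
}

test_that("national reference rates are stratum means of the pooled panel", {
  panel <- make_two_group_panel()
  ref <- national_reference_rates(panel, "hospitalization", "popgroup")
  expect_equal(ref$rate[ref$stratum_id == "G1"], 0.1)
  expect_equal(ref$rate[ref$stratum_id == "G2"], 0.5)

  # constant outcome: every stratum rate equals the constant
  const <- as.data.frame(panel); const$hospitalization <- 1
  refc <- national_reference_rates(
    patient_panel(const, outcome_types = outcome_types(panel)),
    "hospitalization", "popgroup")
  expect_true(all(refc$rate == 1))

  # single stratum: rate equals the national crude mean
  ref1 <- national_reference_rates(panel, "hospitalization", "crude")
  expect_equal(nrow(ref1), 1L)
  expect_equal(ref1$rate, mean(panel$hospitalization))
})

test_that("expected totals follow the indirect-standardization sum", {
  ref <- structure(data.frame(stratum_id = c("G1", "G2"),
                              n = c(10L, 10L), rate = c(0.1, 0.5)),
                   class = c("reference_rates", "data.frame"))
  counts <- data.frame(stratum_id = c("G1", "G2"), n = c(10L, 10L))
  expect_equal(expected_outcome(counts, ref), 6.0)
  ref0 <- ref; ref0$rate <- 0
  expect_equal(expected_outcome(counts, ref0), 0)
  expect_error(
    expected_outcome(data.frame(stratum_id = "G9", n = 1L), ref), "G9")
})

test_that("O/E ratio handles the worked example and edge cases", {
  expect_equal(oe_ratio(9, 21), 9 / 21)
  expect_equal(format_ratio(oe_ratio(9, 21)), 0.43)
  expect_equal(oe_ratio(5, 5), 1)
  expect_equal(oe_ratio(0, 10), 0)
  expect_warning(r <- oe_ratio(3, 0), "missing")
  expect_true(is.na(r))
  expect_error(oe_ratio(-1, 2), ">= 0")
})

test_that("identical per-group rates in every region give PGSOR of 1", {
  # deterministic outcome per group: no regional signal left
  panel <- toy_panel(n = 400L, J = 8L, K = 5L, seed = 4L)
  df <- as.data.frame(panel)
  df$hospitalization <- as.integer(df$popgroup_id %in% c("G01", "G03"))
  panel <- patient_panel(df, outcome_types = outcome_types(panel))
  res <- standardize_regions(panel, "hospitalization", "popgroup")
  expect_true(all(abs(res$ratio - 1) < 1e-9))
})

test_that("PGSOR matches an independent two-loop oracle", {
  panel <- toy_panel(n = 600L, J = 6L, K = 5L, seed = 8L)
  res <- standardize_regions(panel, "cost", "popgroup")
  df <- as.data.frame(panel)
  # brute force: loop regions x groups with explicit national means
  for (r in unique(df$region_id)) {
    exp_r <- 0
    for (g in unique(df$popgroup_id)) {
      n_rg <- sum(df$region_id == r & df$popgroup_id == g)
      exp_r <- exp_r + n_rg * mean(df$cost[df$popgroup_id == g])
    }
    obs_r <- sum(df$cost[df$region_id == r])
    expect_equal(res$ratio[res$region_id == r], obs_r / exp_r,
                 tolerance = 1e-12)
  }
})

test_that("conservation: pooled expected equals pooled observed", {
  panel <- toy_panel(n = 500L, J = 7L, K = 6L, seed = 12L)
  for (fl in c("crude", "age_sex", "popgroup")) {
    for (oc in c("hospitalization", "cost")) {
      res <- standardize_regions(panel, oc, fl)
      expect_lt(abs(sum(res$expected) - sum(res$observed)) /
                  sum(res$observed), 1e-9)
    }
  }
})

test_that("ratios are invariant to uniform rescaling of a continuous outcome", {
  panel <- toy_panel(n = 300L, J = 5L, seed = 6L)
  scaled <- as.data.frame(panel); scaled$cost <- scaled$cost * 37.5
  panel2 <- patient_panel(scaled, outcome_types = outcome_types(panel))
  r1 <- standardize_regions(panel, "cost", "popgroup")
  r2 <- standardize_regions(panel2, "cost", "popgroup")
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("with a single stratum every flavor reduces to the crude ratio", {
  panel <- toy_panel(n = 200L, J = 4L, K = 1L, seed = 9L)
  df <- as.data.frame(panel); df$age <- 52L; df$sex <- "male"
  panel <- patient_panel(df, outcome_types = outcome_types(panel))
  crude <- standardize_regions(panel, "cost", "crude")
  asor <- standardize_regions(panel, "cost", "age_sex")
  pgsor <- standardize_regions(panel, "cost", "popgroup")
  expect_identical(asor$ratio, crude$ratio)
  expect_identical(pgsor$ratio, crude$ratio)
})

test_that("small groups fall back to their macro group at the 1% rule", {
  # shares 60% / 39.5% / 0.5%: only G3 is aggregated
  n <- 200L
  g <- c(rep("G1", 120L), rep("G2", 79L), "G3")
  panel <- patient_panel(data.frame(
    person_id = sprintf("p%03d", seq_len(n)),
    region_id = rep(c("R1", "R2"), 100L),
    popgroup_id = g,
    macro_popgroup_id = ifelse(g == "G1", "M1", "M2"),
    age = 40L, sex = "female", stringsAsFactors = FALSE))
  catalog <- catalog_from_panel(panel)
  agg <- aggregate_small_popgroups(panel, catalog, threshold = 0.01)
  expect_equal(unique(agg$effective_group[agg$popgroup_id == "G1"]), "G1")
  expect_equal(unique(agg$effective_group[agg$popgroup_id == "G2"]), "G2")
  expect_equal(unique(agg$effective_group[agg$popgroup_id == "G3"]), "M2")

  # all groups above threshold: identity
  agg2 <- aggregate_small_popgroups(panel, catalog, threshold = 0.005)
  expect_identical(agg2$effective_group, agg2$popgroup_id)
  # threshold 0: identity by construction
  agg3 <- aggregate_small_popgroups(panel, catalog, threshold = 0)
  expect_identical(agg3$effective_group, agg3$popgroup_id)
  # the boundary is inclusive: share exactly 1% is retained
  g4 <- c(rep("G1", 99L), "G2")
  p4 <- patient_panel(data.frame(
    person_id = sprintf("q%03d", 1:100), region_id = "R1",
    popgroup_id = g4, macro_popgroup_id = ifelse(g4 == "G1", "M1", "M2"),
    age = 30L, sex = "male", stringsAsFactors = FALSE))
  agg4 <- aggregate_small_popgroups(p4, catalog_from_panel(p4),
                                    threshold = 0.01)
  expect_equal(unique(agg4$effective_group[agg4$popgroup_id == "G2"]), "G2")
})

test_that("region ranking sorts ascending with stable ties and exclusions", {
  res <- data.frame(region_id = c("A", "B", "C"),
                    ratio = c(1.2, 0.8, 1.0))
  rk <- rank_regions(res, top_k = 1L)
  expect_equal(rk$top$region_id, "B")
  expect_equal(rk$bottom$region_id, "A")

  ties <- data.frame(region_id = c("Z", "A", "M"), ratio = 1)
  expect_equal(rank_regions(ties, 3L)$ranked$region_id, c("A", "M", "Z"))

  withmiss <- data.frame(region_id = c("A", "B", "C"),
                         ratio = c(0.5, NA, 2))
  rkm <- rank_regions(withmiss, 2L)
  expect_equal(rkm$excluded, "B")
  expect_equal(nrow(rkm$ranked), 2L)

  set.seed(33)
  big <- data.frame(region_id = sprintf("R%03d", 1:96),
                    ratio = stats::rlnorm(96, 0, 0.3))
  rk96 <- rank_regions(big, 10L)
  ord <- big$region_id[order(big$ratio, big$region_id)]
  expect_equal(rk96$top$region_id, utils::head(ord, 10L))
  expect_equal(rk96$bottom$region_id, rev(utils::tail(ord, 10L)))
})

test_that("refining strata never moves the pooled national ratio off 1", {
  panel <- toy_panel(n = 400L, J = 5L, seed = 15L)
  for (fl in c("crude", "age_sex", "popgroup")) {
    res <- standardize_regions(panel, "hospitalization", fl)
    expect_equal(sum(res$observed) / sum(res$expected), 1,
                 tolerance = 1e-12)
  }
})
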