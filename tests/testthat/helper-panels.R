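# small deterministic panel builders used across the suite

toy_panel <- function(n = 60L, J = 3L, K = 4L, seed = 1L,
                      binary_rate = 0.3, cost_meanlog = 6) {
  set.seed(seed)
  groups <- sprintf("G%02d", seq_len(K))
  g <- sample(groups, n, replace = TRUE)
  macro <- sprintf("M%d", (match(g, groups) - 1L) %/% 2L + 1L)
  patient_panel(
    data.frame(
      person_id = sprintf("p%05d", seq_len(n)),
      region_id = sample(sprintf("R%02d", seq_len(J)), n, replace = TRUE),
      popgroup_id = g,
      macro_popgroup_id = macro,
      age = sample(0:90, n, replace = TRUE),
      sex = sample(c("female", "male"), n, replace = TRUE),
      hospitalization = stats::rbinom(n, 1L, binary_rate),
      cost = exp(stats::rnorm(n, cost_meanlog, 1)),
      stringsAsFactors = FALSE),
    outcome_types = c(hospitalization = "binary", cost = "continuous"))
}

catalog_from_panel <- function(panel, severity = NULL) {
  map <- unique(as.data.frame(panel)[, c("popgroup_id",
                                         "macro_popgroup_id")])
  map <- map[order(map$popgroup_id), , drop = FALSE]
  share <- table(panel$popgroup_id) / nrow(panel)
  popgroup_catalog(data.frame(
    popgroup_id = map$popgroup_id,
    macro_popgroup_id = map$macro_popgroup_id,
    severity_score = if (is.null(severity)) seq_len(nrow(map))
                     else severity,
    national_share = as.numeric(share[map$popgroup_id]),
    stringsAsFactors = FALSE))
}

# balanced two-level continuous panel: m persons in each of J regions
balanced_panel <- function(J = 30L, m = 40L, tau = 0.5, sigma = 1,
                           mu = 5, seed = 1L) {
  set.seed(seed)
  u <- stats::rnorm(J, 0, tau)
  region <- rep(sprintf("R%03d", seq_len(J)), each = m)
  y <- exp(mu + u[rep(seq_len(J), each = m)] + stats::rnorm(J * m, 0, sigma))
  patient_panel(
    data.frame(
      person_id = sprintf("p%06d", seq_len(J * m)),
      region_id = region,
      popgroup_id = "G01",
      macro_popgroup_id = "M1",
      age = 50L,
      sex = "female",
      cost = y,
      stringsAsFactors = FALSE),
    outcome_types = c(cost = "continuous"))
}
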