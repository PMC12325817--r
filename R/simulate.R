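#' Specify a synthetic claims-panel simulation
#'
#' Defines the study conditions for the synthetic generator: a national
#' population split over `n_regions` regions, classified into `n_popgroups`
#' mutually exclusive groups with a heavy-tailed size distribution (few large,
#' many tiny groups) nested in `n_macro_groups` macro groups. Outcomes follow
#' the two-level data-generating model the analysis framework assumes:
#'
#' * continuous (`cost`, EUR/year): `y_ij = exp(g0 + b_g + u_j + e_ij)` with
#'   regional intercepts `u_j ~ N(0, tau^2)` and residuals
#'   `e_ij ~ N(0, sigma^2)` on the log scale (log-normal outcome);
#' * binary (`hospitalization`): `y_ij ~ Bernoulli(plogis(g0 + b_g + u_j))`
#'   with `u_j ~ N(0, tau^2)` on the logit scale.
#'
#' `composition_shift` controls compositional confounding: per-region group
#' mixes are Dirichlet draws with concentration `composition_shift *`
#' national shares, so small values give regions very different case mixes
#' and `Inf` gives every region exactly the national mix.
#'
#' @param n_regions number of regions (default 96, the German spatial
#'   planning regions).
#' @param n_patients total persons in the panel.
#' @param n_popgroups number of classification groups.
#' @param n_macro_groups number of macro groups (default 10).
#' @param group_size_law `"zipf"` (default, exponent `zipf_exponent`) or
#'   `"uniform"` national group shares.
#' @param zipf_exponent exponent of the Zipf share law (default 1.1).
#' @param composition_shift Dirichlet concentration multiplier (> 0, may be
#'   `Inf`).
#' @param region_weights optional region size weights (default uniform).
#' @param continuous list for the continuous outcome: `name`, grand mean
#'   `gamma00` (log-EUR), group-effect spread `effect_sd` (log scale),
#'   regional-intercept SD `tau`, residual SD `sigma`.
#' @param binary list for the binary outcome: `name`, `gamma00` (logit),
#'   `effect_sd` (logit scale), `tau`.
#' @param shared_intercept if `TRUE` (default) both outcomes share one
#'   regional standard-normal draw, scaled by their respective `tau`.
#' @param seed integer master seed; all randomness flows from it via fixed
#'   substreams (1 = catalog, 2 = population, 3 = outcomes, 4 = region
#'   covariates).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_regions = 96L,
                            n_patients = 50000L,
                            n_popgroups = 300L,
                            n_macro_groups = 10L,
                            group_size_law = c("zipf", "uniform"),
                            zipf_exponent = 1.1,
                            composition_shift = 50,
                            region_weights = NULL,
                            continuous = list(),
                            binary = list(),
                            shared_intercept = TRUE,
                            seed = 1L) {
  group_size_law <- match.arg(group_size_law)
  cont <- utils::modifyList(
    list(name = "cost", gamma00 = 6.0, effect_sd = 0.8, tau = 0.5,
         sigma = 1.0),
    continuous)
  bin <- utils::modifyList(
    list(name = "hospitalization", gamma00 = -2.2, effect_sd = 0.7,
         tau = sqrt(0.3)),
    binary)
  spec <- list(n_regions = as.integer(n_regions),
               n_patients = as.integer(n_patients),
               n_popgroups = as.integer(n_popgroups),
               n_macro_groups = as.integer(n_macro_groups),
               group_size_law = group_size_law,
               zipf_exponent = zipf_exponent,
               composition_shift = composition_shift,
               region_weights = region_weights,
               continuous = cont, binary = bin,
               shared_intercept = isTRUE(shared_intercept),
               seed = as.integer(seed))
  if (spec$n_popgroups < 2L)
    stop("n_popgroups must be >= 2", call. = FALSE)
  if (spec$n_regions < 1L)
    stop("n_regions must be >= 1", call. = FALSE)
  if (spec$n_patients < spec$n_regions)
    stop("n_patients must be >= n_regions", call. = FALSE)
  if (spec$n_macro_groups < 1L || spec$n_macro_groups > spec$n_popgroups)
    stop("n_macro_groups must lie in [1, n_popgroups]", call. = FALSE)
  if (!(composition_shift > 0))
    stop("composition_shift must be > 0 (Inf allowed)", call. = FALSE)
  if (cont$tau < 0 || bin$tau < 0)
    stop("tau must be >= 0", call. = FALSE)
  if (cont$sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  if (!is.null(region_weights)) {
    if (length(region_weights) != spec$n_regions || any(region_weights <= 0))
      stop("region_weights must be ", spec$n_regions, " positive values",
           call. = FALSE)
  }
  class(spec) <- "simulation_spec"
  spec
}

# deterministic substream seeds derived from the master seed
.substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 101 * k) %% 2147483647)
}

#' Generate a synthetic PopGroup catalog
#'
#' Draws national group shares from the configured size law and a latent
#' severity gradient shared between the two outcomes: each group's continuous
#' and binary effects are `effect_sd` times one standard-normal latent value,
#' and the severity score is a monotone affine map of that latent value onto
#' the published score range (-0.4 to 13.1), so severity is increasing in the
#' group effect. Macro groups aggregate groups of similar severity.
#'
#' @param spec a [simulation_spec()].
#' @return A [popgroup_catalog()] whose `effects` attribute holds the true
#'   per-group outcome effects (`effect_continuous`, `effect_binary`).
#' @export
make_catalog <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  K <- spec$n_popgroups
  set.seed(.substream(spec$seed, 1L))
  shares <- switch(spec$group_size_law,
                   zipf = (seq_len(K))^(-spec$zipf_exponent),
                   uniform = rep(1, K))
  shares <- shares / sum(shares)
  z <- stats::rnorm(K)
  sev <- -0.4 + (z - min(z)) / (max(z) - min(z)) * (13.1 - (-0.4))
  macro_idx <- as.integer(cut(rank(z, ties.method = "first"),
                              breaks = spec$n_macro_groups, labels = FALSE))
  cat_df <- data.frame(
    popgroup_id = sprintf("PG%03d", seq_len(K)),
    macro_popgroup_id = sprintf("M%02d", macro_idx),
    severity_score = sev,
    national_share = shares,
    stringsAsFactors = FALSE)
  out <- popgroup_catalog(cat_df)
  attr(out, "effects") <- data.frame(
    popgroup_id = cat_df$popgroup_id,
    effect_continuous = spec$continuous$effect_sd * z,
    effect_binary = spec$binary$effect_sd * z,
    stringsAsFactors = FALSE)
  out
}

#' Simulate a synthetic study population (no outcomes)
#'
#' Allocates persons to regions (multinomially, proportional to the region
#' weights) and draws each region's group mix from a Dirichlet perturbation
#' of the national shares with concentration `composition_shift *` shares.
#' Ages and sexes are drawn from fixed demographic distributions (a gamma age
#' profile truncated at 100; balanced sexes).
#'
#' @param spec a [simulation_spec()].
#' @param catalog the matching [make_catalog()] output.
#' @return A [patient_panel()] without outcome columns.
#' @export
simulate_population <- function(spec, catalog) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(catalog, "popgroup_catalog"))
  set.seed(.substream(spec$seed, 2L))
  J <- spec$n_regions
  K <- nrow(catalog)
  w <- if (is.null(spec$region_weights)) rep(1, J) else spec$region_weights
  sizes <- as.vector(stats::rmultinom(1L, spec$n_patients, w / sum(w)))
  # every region must be populated
  while (any(sizes == 0L)) {
    i <- which.max(sizes); j <- which(sizes == 0L)[1L]
    sizes[i] <- sizes[i] - 1L; sizes[j] <- sizes[j] + 1L
  }
  shares <- catalog$national_share
  macro_of <- stats::setNames(catalog$macro_popgroup_id, catalog$popgroup_id)
  pieces <- vector("list", J)
  for (j in seq_len(J)) {
    p <- if (is.infinite(spec$composition_shift)) {
      shares
    } else {
      g <- stats::rgamma(K, shape = spec$composition_shift * shares)
      if (sum(g) <= 0) shares else g / sum(g)
    }
    gidx <- sample.int(K, sizes[j], replace = TRUE, prob = p)
    pieces[[j]] <- data.frame(
      region_id = sprintf("R%03d", j),
      popgroup_id = catalog$popgroup_id[gidx],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, pieces)
  n <- nrow(df)
  df <- data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    region_id = df$region_id,
    popgroup_id = df$popgroup_id,
    macro_popgroup_id = unname(macro_of[df$popgroup_id]),
    age = as.integer(pmin(100, round(stats::rgamma(n, shape = 2,
                                                   scale = 21)))),
    sex = sample(c("female", "male"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  patient_panel(df)
}

#' Simulate outcomes onto a population panel
#'
#' Draws one standard-normal regional deviate per region (shared across both
#' outcomes when `spec$shared_intercept`, independent otherwise), scales it
#' by each outcome's `tau`, and generates the continuous outcome as a
#' log-normal and the binary outcome as a Bernoulli under the two-level
#' model described in [simulation_spec()]. The true regional intercepts,
#' group effects, variance components and implied intraclass correlations
#' are attached as the panel's `ground_truth` attribute.
#'
#' @param panel a [simulate_population()] panel (group labels required).
#' @param spec the [simulation_spec()].
#' @param catalog the [make_catalog()] output carrying the true group
#'   effects.
#' @return The panel with outcome columns and a `ground_truth` attribute.
#' @export
simulate_outcomes <- function(panel, spec, catalog) {
  stopifnot(inherits(panel, "patient_panel"),
            inherits(spec, "simulation_spec"),
            inherits(catalog, "popgroup_catalog"))
  eff <- attr(catalog, "effects")
  if (is.null(eff))
    stop("catalog carries no group effects; use make_catalog()",
         call. = FALSE)
  unknown <- setdiff(panel$popgroup_id, eff$popgroup_id)
  if (length(unknown) > 0L)
    stop("panel contains group(s) unknown to the simulation spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  set.seed(.substream(spec$seed, 3L))
  regions <- sort(unique(panel$region_id))
  J <- length(regions)
  z <- stats::rnorm(J)
  u_cont <- spec$continuous$tau * z
  u_bin <- if (spec$shared_intercept) spec$binary$tau * z
           else spec$binary$tau * stats::rnorm(J)
  names(u_cont) <- names(u_bin) <- regions

  ec <- stats::setNames(eff$effect_continuous, eff$popgroup_id)
  eb <- stats::setNames(eff$effect_binary, eff$popgroup_id)
  n <- nrow(panel)
  eta_c <- spec$continuous$gamma00 + ec[panel$popgroup_id] +
    u_cont[panel$region_id]
  eta_b <- spec$binary$gamma00 + eb[panel$popgroup_id] +
    u_bin[panel$region_id]
  out <- as.data.frame(panel)
  out[[spec$continuous$name]] <-
    exp(eta_c + stats::rnorm(n, 0, spec$continuous$sigma))
  out[[spec$binary$name]] <- stats::rbinom(n, 1L, stats::plogis(eta_b))
  ot <- stats::setNames(c("continuous", "binary"),
                        c(spec$continuous$name, spec$binary$name))
  panel2 <- patient_panel(out, outcome_types = ot)

  tau2_c <- spec$continuous$tau^2
  tau2_b <- spec$binary$tau^2
  sigma2 <- spec$continuous$sigma^2
  truth <- list(
    regions = data.frame(region_id = regions, z = z,
                         u_continuous = unname(u_cont),
                         u_binary = unname(u_bin),
                         stringsAsFactors = FALSE),
    group_effects = eff,
    gamma00_continuous = spec$continuous$gamma00,
    gamma00_binary = spec$binary$gamma00,
    tau2_continuous = tau2_c,
    sigma2 = sigma2,
    tau2_binary = tau2_b,
    icc_continuous = if (tau2_c + sigma2 > 0) tau2_c / (tau2_c + sigma2)
                     else 0,
    icc_binary = tau2_b / (tau2_b + pi^2 / 3))
  class(truth) <- "ground_truth"
  attr(panel2, "ground_truth") <- truth
  panel2
}

#' Ground truth attached to a simulated panel
#'
#' @param panel a panel produced by [simulate_outcomes()].
#' @return The `ground_truth` list (true regional intercepts, group effects,
#'   variance components, implied ICCs).
#' @export
ground_truth <- function(panel) {
  attr(panel, "ground_truth")
}

#' Simulate synthetic region covariates
#'
#' Regional characteristics of the kind used as level-2 covariates:
#' demographic (average population age, population density), supply-side
#' (GPs per 10,000 insured, inpatient beds per 1,000), an ordinal
#' urbanization level and a standardized deprivation index. Values are drawn
#' independently of the simulated regional outcome intercepts.
#'
#' @param spec a [simulation_spec()].
#' @return A [region_covariates()] table with `spec$n_regions` rows.
#' @export
simulate_region_covariates <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(.substream(spec$seed, 4L))
  J <- spec$n_regions
  region_covariates(data.frame(
    region_id = sprintf("R%03d", seq_len(J)),
    avg_population_age = stats::rnorm(J, 44, 2),
    population_density = round(exp(stats::rnorm(J, 5.2, 0.9))),
    gp_per_10k = stats::rnorm(J, 7, 1),
    beds_per_1k = stats::rnorm(J, 6, 1.2),
    urbanization = sample(1:4, J, replace = TRUE),
    deprivation = stats::rnorm(J),
    stringsAsFactors = FALSE))
}

#' One-shot synthetic claims simulation
#'
#' Convenience wrapper chaining [make_catalog()], [simulate_population()],
#' [simulate_outcomes()] and [simulate_region_covariates()].
#'
#' @param spec a [simulation_spec()].
#' @return List with elements `panel`, `catalog`, `regions`, `truth`.
#' @export
simulate_claims <- function(spec) {
  catalog <- make_catalog(spec)
  panel <- simulate_population(spec, catalog)
  panel <- simulate_outcomes(panel, spec, catalog)
  list(panel = panel, catalog = catalog,
       regions = simulate_region_covariates(spec),
       truth = ground_truth(panel))
}
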