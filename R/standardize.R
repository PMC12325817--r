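#' Observed-to-expected ratio
#'
#' The elementary indirect-standardization ratio: observed outcome total of a
#' region divided by the total expected under the reference population's
#' stratum-specific rates. A ratio of 1 marks the national average; values
#' above 1 mark outcome levels above it.
#'
#' @param observed non-negative observed total(s).
#' @param expected non-negative expected total(s).
#' @return `observed/expected`; `NA` (with a warning) where `expected` is 0.
#' @export
oe_ratio <- function(observed, expected) {
  if (any(is.na(observed)) || any(is.na(expected)))
    stop("observed/expected must be non-missing", call. = FALSE)
  if (any(observed < 0) || any(expected < 0))
    stop("observed and expected must be >= 0", call. = FALSE)
  out <- ifelse(expected > 0, observed / expected, NA_real_)
  if (any(expected == 0))
    warning("expected value of 0: O/E ratio reported as missing",
            call. = FALSE)
  out
}

# stratum labels for a panel under a given stratification
.strata_labels <- function(panel, stratification, age_band = 5L,
                           group_col = "popgroup_id") {
  switch(stratification,
         crude = rep("all", nrow(panel)),
         popgroup = panel[[group_col]],
         age_sex = {
           lo <- age_band * (panel$age %/% age_band)
           sprintf("A%03d|%s", lo, panel$sex)
         },
         stop("unknown stratification: ", stratification, call. = FALSE))
}

.check_outcome <- function(panel, outcome) {
  if (!outcome %in% names(panel))
    stop("outcome '", outcome, "' not present in panel", call. = FALSE)
  v <- panel[[outcome]]
  if (any(is.na(v)))
    stop("outcome '", outcome, "' has missing values; filter the panel ",
         "to the eligible population first", call. = FALSE)
  v
}

#' National reference rates per stratum
#'
#' The reference population is the pooled national study population itself:
#' for every stratum (PopGroup, or age-band x sex cell) the national mean of
#' the outcome per person — an event rate for binary outcomes, a mean cost or
#' day count for continuous ones.
#'
#' @param panel a `patient_panel`.
#' @param outcome outcome column name.
#' @param stratification `"popgroup"`, `"age_sex"`, or `"crude"` (one single
#'   stratum).
#' @param age_band width in years of the age bands for `"age_sex"`
#'   (default 5).
#' @param group_col group column used for `"popgroup"` stratification
#'   (default `popgroup_id`; use `effective_group` after
#'   [aggregate_small_popgroups()]).
#' @return A `reference_rates` data.frame: `stratum_id`, `n`, `rate`.
#' @export
national_reference_rates <- function(panel, outcome,
                                     stratification = c("popgroup",
                                                        "age_sex", "crude"),
                                     age_band = 5L,
                                     group_col = "popgroup_id") {
  stratification <- match.arg(stratification)
  v <- .check_outcome(panel, outcome)
  s <- .strata_labels(panel, stratification, age_band, group_col)
  n <- tapply(v, s, length)
  tot <- tapply(v, s, sum)
  out <- data.frame(stratum_id = names(n), n = as.integer(n),
                    rate = as.numeric(tot / n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "stratification") <- stratification
  class(out) <- c("reference_rates", "data.frame")
  out
}

#' Per-region stratum counts and observed sums
#'
#' @inheritParams national_reference_rates
#' @return data.frame `region_id`, `stratum_id`, `n`, `observed_sum`.
#' @export
strata_counts <- function(panel, outcome,
                          stratification = c("popgroup", "age_sex", "crude"),
                          age_band = 5L, group_col = "popgroup_id") {
  stratification <- match.arg(stratification)
  v <- .check_outcome(panel, outcome)
  key <- data.frame(region_id = panel$region_id,
                    stratum_id = .strata_labels(panel, stratification,
                                                age_band, group_col),
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(key)), observed_sum = v),
                          by = key, FUN = sum)
  agg$n <- as.integer(agg$n)
  agg[order(agg$region_id, agg$stratum_id), , drop = FALSE]
}

#' Expected outcome total for one region
#'
#' Indirect standardization: the region's expected total is the sum over
#' strata of the region's person count times the national per-person rate,
#' `sum(N_stratum * rate_stratum)`.
#'
#' @param region_counts data.frame with columns `stratum_id` and `n` (one
#'   region's strata).
#' @param reference a [national_reference_rates()] table.
#' @return The expected outcome total (a single number).
#' @export
expected_outcome <- function(region_counts, reference) {
  stopifnot(is.data.frame(region_counts),
            all(c("stratum_id", "n") %in% names(region_counts)))
  idx <- match(region_counts$stratum_id, reference$stratum_id)
  if (any(is.na(idx)))
    stop("stratum missing from reference rates: ",
         paste(region_counts$stratum_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  sum(region_counts$n * reference$rate[idx])
}

#' Standardized observed-to-expected ratios per region
#'
#' Computes one O/E ratio per region for the chosen standardization flavor:
#' `"crude"` (no standardization: a single stratum), `"age_sex"` (the
#' age-sex-standardized outcome ratio, ASOR), or `"popgroup"` (the
#' PopGroup-standardized outcome ratio, PGSOR). The reference rates are
#' computed from the pooled panel itself, so the all-region pooled O/E is 1
#' by construction.
#'
#' @inheritParams national_reference_rates
#' @param flavor standardization flavor.
#' @param group_col group column for the `"popgroup"` flavor; pass
#'   `"effective_group"` to standardize on the aggregated groups of
#'   [aggregate_small_popgroups()].
#' @return A `standardization_result` data.frame: `region_id`, `n_persons`,
#'   `observed`, `expected`, `ratio`, `flavor`.
#' @export
standardize_regions <- function(panel, outcome,
                                flavor = c("crude", "age_sex", "popgroup"),
                                age_band = 5L, group_col = "popgroup_id") {
  flavor <- match.arg(flavor)
  strat <- if (flavor == "crude") "crude" else flavor
  ref <- national_reference_rates(panel, outcome, strat, age_band, group_col)
  cnt <- strata_counts(panel, outcome, strat, age_band, group_col)
  regions <- sort(unique(cnt$region_id))
  res <- lapply(regions, function(r) {
    rc <- cnt[cnt$region_id == r, , drop = FALSE]
    data.frame(region_id = r,
               n_persons = sum(rc$n),
               observed = sum(rc$observed_sum),
               expected = expected_outcome(rc, ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$ratio <- oe_ratio(out$observed, out$expected)
  out$flavor <- flavor
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  class(out) <- c("standardization_result", "data.frame")
  out
}

#' Aggregate small PopGroups onto macro groups
#'
#' Multilevel regression on several hundred group dummies is fragile when
#' per-region group sizes are small, so groups below a population-share
#' threshold (default 1% of the panel, inclusive at the boundary) are
#' replaced by their macro group. The result is an `effective_group` column;
#' groups at or above the threshold keep their own label.
#'
#' @param panel a `patient_panel`.
#' @param catalog a `popgroup_catalog` providing the (total) macro mapping.
#' @param threshold share threshold in `[0,1]`; groups with share `>=`
#'   threshold are retained (default 0.01).
#' @return The panel with an added `effective_group` column.
#' @export
aggregate_small_popgroups <- function(panel, catalog, threshold = 0.01) {
  stopifnot(inherits(panel, "patient_panel"),
            inherits(catalog, "popgroup_catalog"),
            threshold >= 0, threshold <= 1)
  unknown <- setdiff(panel$popgroup_id, catalog$popgroup_id)
  if (length(unknown) > 0L)
    stop("macro mapping not total for panel group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  share <- table(panel$popgroup_id) / nrow(panel)
  keep <- names(share)[as.numeric(share) >= threshold]
  macro_of <- stats::setNames(catalog$macro_popgroup_id, catalog$popgroup_id)
  out <- as.data.frame(panel)
  out$effective_group <- ifelse(out$popgroup_id %in% keep,
                                out$popgroup_id,
                                unname(macro_of[out$popgroup_id]))
  res <- patient_panel(out, outcome_types = outcome_types(panel))
  attr(res, "ground_truth") <- attr(panel, "ground_truth")
  res
}

#' Rank regions by their standardized ratio
#'
#' Ascending sort by ratio (best performers first when lower outcomes are
#' better), with stable ties broken by region identifier. Regions with a
#' missing ratio are excluded from the ranking and reported separately.
#'
#' @param results a `standardization_result` (or any data.frame with
#'   `region_id` and `ratio`).
#' @param top_k number of regions in the top/bottom slices (default 10).
#' @return A `region_ranking` list: `ranked` (all rankable regions,
#'   ascending, with a `rank` column), `top` (the `top_k` smallest ratios),
#'   `bottom` (the `top_k` largest, largest first), `excluded` (region ids
#'   with missing ratios).
#' @export
rank_regions <- function(results, top_k = 10L) {
  stopifnot(is.data.frame(results), nrow(results) > 0L,
            all(c("region_id", "ratio") %in% names(results)))
  excl <- results$region_id[is.na(results$ratio)]
  ok <- results[!is.na(results$ratio), , drop = FALSE]
  ok <- ok[order(ok$ratio, ok$region_id), , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  rownames(ok) <- NULL
  k <- min(top_k, nrow(ok))
  out <- list(ranked = ok,
              top = utils::head(ok, k),
              bottom = ok[rev(utils::tail(seq_len(nrow(ok)), k)), ,
                          drop = FALSE],
              excluded = excl)
  class(out) <- "region_ranking"
  out
}

#' @export
print.region_ranking <- function(x, ...) {
  cat(sprintf("region_ranking: %d regions ranked, %d excluded (missing)\n",
              nrow(x$ranked), length(x$excluded)))
  cat("top (smallest ratios):\n")
  print(utils::head(x$top, 5L))
  cat("bottom (largest ratios):\n")
  print(utils::head(x$bottom, 5L))
  invisible(x)
}

#' Round ratios for tabular display
#'
#' Ratios are reported at 2 decimals in tables; full precision is retained
#' in all machine-readable output.
#'
#' @param x numeric ratios.
#' @return `x` rounded to 2 decimals.
#' @export
format_ratio <- function(x) round(x, 2L)
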