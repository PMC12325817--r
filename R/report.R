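#' Ranked distribution diagram of regional performance
#'
#' The standard graphic for regional comparison: one bar per region, ranked
#' ascending by the base series (typically the crude ratio), with an overlay
#' series (e.g. the PopGroup-standardized ratio or the regional odds ratio)
#' drawn over the base bars and a reference line at 1 marking the national
#' average. Regions whose overlay value lies on the other side of 1 than
#' their base value ("side switchers": regions that move from below- to
#' above-average performance after standardization, or vice versa) are
#' visually distinguished.
#'
#' @param base data.frame with `region_id` and a value column (`ratio` or
#'   `value`), used for ranking.
#' @param overlay optional second series over the same regions.
#' @param base_label,overlay_label legend labels.
#' @param file optional output path; the figure is written with the device
#'   implied by the extension (`.pdf` or `.svg`; vector output keeps the
#'   rendering deterministic).
#' @param width,height device size in inches.
#' @return Invisibly, a list with `plot` (the ggplot object) and `data` (the
#'   plotted table, ordered as drawn, with a `side_switcher` flag).
#' @export
distribution_diagram <- function(base, overlay = NULL,
                                 base_label = "crude",
                                 overlay_label = "standardized",
                                 file = NULL, width = 10, height = 5) {
  b <- .series_values(base)
  if (nrow(b) < 2L)
    stop("at least 2 regions with non-missing values required",
         call. = FALSE)
  if (!is.null(overlay)) {
    o <- .series_values(overlay)
    if (!setequal(b$region_id, o$region_id))
      stop("base and overlay series must cover the same regions",
           call. = FALSE)
    b$overlay <- o$value[match(b$region_id, o$region_id)]
  }
  b <- b[order(b$value, b$region_id), , drop = FALSE]
  b$rank <- seq_len(nrow(b))
  b$side_switcher <- if (is.null(overlay)) FALSE
                     else (b$value - 1) * (b$overlay - 1) < 0
  rownames(b) <- NULL

  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$value, fill = base_label),
                      width = 0.85) +
    ggplot2::scale_fill_manual(
      name = NULL, values = stats::setNames("grey70", base_label)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "solid",
                        colour = "black") +
    ggplot2::labs(x = sprintf("regions ranked by %s ratio", base_label),
                  y = "O/E ratio (1 = national average)") +
    ggplot2::theme_minimal()
  if (!is.null(overlay)) {
    p <- p +
      ggplot2::geom_col(
        data = b,
        ggplot2::aes(y = .data$overlay, alpha = .data$side_switcher),
        width = 0.45, fill = "goldenrod") +
      ggplot2::scale_alpha_manual(
        name = overlay_label,
        values = c(`FALSE` = 0.6, `TRUE` = 1),
        labels = c(`FALSE` = "same side", `TRUE` = "side switcher"))
  }
  if (!is.null(file))
    ggplot2::ggsave(file, p, width = width, height = height)
  invisible(list(plot = p, data = b))
}

.series_values <- function(x) {
  stopifnot(is.data.frame(x), "region_id" %in% names(x))
  val_col <- intersect(c("ratio", "value"), names(x))[1L]
  if (is.na(val_col))
    stop("series needs a 'ratio' or 'value' column", call. = FALSE)
  out <- data.frame(region_id = as.character(x$region_id),
                    value = x[[val_col]], stringsAsFactors = FALSE)
  out[!is.na(out$value), , drop = FALSE]
}

#' Long-format comparison of standardization flavors
#'
#' Computes the per-region ratio under each requested flavor (`crude`,
#' `age_sex`, `popgroup`, and `regression` for the regression-based adjusted
#' O/E), ranks regions within each flavor (ascending, ties by region id) and
#' reports the rank shift of every flavor relative to the first one. Input
#' tables are never modified; the report is exactly reconstructible from the
#' standardization and performance outputs.
#'
#' @param panel a `patient_panel`.
#' @param outcome outcome column name.
#' @param flavors subset of `c("crude", "age_sex", "popgroup",
#'   "regression")`.
#' @param fit `multilevel_fit` (required for the `"regression"` flavor).
#' @param group_col group column for the `"popgroup"` flavor.
#' @return data.frame `region_id`, `flavor`, `value`, `rank`, `rank_shift`.
#' @export
comparison_report <- function(panel, outcome,
                              flavors = c("crude", "popgroup"),
                              fit = NULL, group_col = "popgroup_id") {
  flavors <- unique(flavors)
  stopifnot(length(flavors) >= 1L)
  bad <- setdiff(flavors, c("crude", "age_sex", "popgroup", "regression"))
  if (length(bad) > 0L)
    stop("unknown flavor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  pieces <- lapply(flavors, function(fl) {
    if (fl == "regression") {
      if (is.null(fit))
        stop("the 'regression' flavor needs a multilevel fit", call. = FALSE)
      tab <- regression_adjusted_oe(fit, panel)
      data.frame(region_id = tab$region_id, flavor = fl,
                 value = tab$value, stringsAsFactors = FALSE)
    } else {
      res <- standardize_regions(panel, outcome, flavor = fl,
                                 group_col = group_col)
      data.frame(region_id = res$region_id, flavor = fl,
                 value = res$ratio, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, pieces)
  out$rank <- NA_integer_
  for (fl in flavors) {
    sel <- out$flavor == fl
    ord <- order(out$value[sel], out$region_id[sel])
    out$rank[sel][ord] <- seq_len(sum(sel))
  }
  base_rank <- out[out$flavor == flavors[1L], c("region_id", "rank")]
  out$rank_shift <- out$rank -
    base_rank$rank[match(out$region_id, base_rank$region_id)]
  rownames(out) <- NULL
  out
}
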