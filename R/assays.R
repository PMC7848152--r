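#' XTT viability index per gram of tissue
#'
#' Background-corrected XTT absorbance (450 nm reading minus the 690 nm
#' reference) normalised by tissue wet weight and by the pooled
#' XTT + DMSO extraction volume, giving absorbance per gram per millilitre.
#' Negative corrected absorbances are a measurement outcome: they are
#' returned unchanged, flagged via the `"negative"` attribute, and reported
#' with a warning rather than clipped.
#'
#' @param a450,a690 absorbance readings (vectorised).
#' @param tissue_weight tissue wet weight, g; must be positive.
#' @param pooled_volume pooled XTT + DMSO volume, mL; must be positive.
#' @return Numeric vector of viability indices (absorbance g^-1 mL^-1) with
#'   logical attribute `negative`.
#' @examples
#' xtt_score(0.75, 0.05, tissue_weight = 0.5, pooled_volume = 1.5)  # 0.933
#' @export
xtt_score <- function(a450, a690, tissue_weight, pooled_volume) {
  if (any(!is.finite(tissue_weight)) || any(tissue_weight <= 0))
    stop("tissue_weight must be positive (g)")
  if (any(!is.finite(pooled_volume)) || any(pooled_volume <= 0))
    stop("pooled_volume must be positive (mL)")
  if (any(a450 < 0) || any(a690 < 0))
    stop("absorbances must be non-negative")
  score <- (a450 - a690) / tissue_weight / pooled_volume
  neg <- score < 0
  if (any(neg))
    warning(sum(neg), " reading(s) have 690 nm background above the 450 nm ",
            "signal; negative viability indices returned as-is")
  attr(score, "negative") <- neg
  score
}

#' Glucose consumption per gram of tissue per day
#'
#' The glucose amount consumed is the concentration drop from fresh to
#' conditioned medium times the medium volume; dividing by tissue weight and
#' by days in culture gives mg glucose per gram per day. Concentrations are
#' mg/dL and volume is mL, so the amount is `(fresh - conditioned) *
#' medium_volume / 100` mg. Negative consumption (conditioned above fresh)
#' is returned with a warning and flagged, not clipped.
#'
#' @param fresh,conditioned glucose concentrations, mg/dL.
#' @param medium_volume medium volume, mL; positive.
#' @param tissue_weight tissue wet weight, g; positive.
#' @param days_in_culture days over which the medium was conditioned;
#'   positive.
#' @return Numeric vector, mg glucose g^-1 day^-1, with logical attribute
#'   `negative`.
#' @examples
#' glucose_consumption(100, 80, medium_volume = 50,
#'                     tissue_weight = 2, days_in_culture = 4)  # 1.25
#' @export
glucose_consumption <- function(fresh, conditioned, medium_volume,
                                tissue_weight, days_in_culture) {
  if (any(!is.finite(medium_volume)) || any(medium_volume <= 0))
    stop("medium_volume must be positive (mL)")
  if (any(!is.finite(tissue_weight)) || any(tissue_weight <= 0))
    stop("tissue_weight must be positive (g)")
  if (any(!is.finite(days_in_culture)) || any(days_in_culture <= 0))
    stop("days_in_culture must be positive")
  if (any(fresh < 0) || any(conditioned < 0))
    stop("glucose concentrations must be non-negative")
  used_mg <- (fresh - conditioned) * medium_volume / 100  # mg/dL * dL
  rate <- used_mg / tissue_weight / days_in_culture
  neg <- rate < 0
  if (any(neg))
    warning(sum(neg), " record(s) show conditioned glucose above fresh; ",
            "negative consumption returned as-is")
  attr(rate, "negative") <- neg
  rate
}

#' Summarise histomorphometry fields per criterion and group
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' field values for every criterion x group combination.
#'
#' @param table data frame with columns `group`, `criterion`, `value` (field
#'   observations; extra columns ignored).
#' @return Data frame with `criterion`, `group`, `n`, `mean`, `sd`;
#'   `sd` is `NA` (flagged undefined) for a single field.
#' @export
summarize_fields <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("group", "criterion", "value") %in% names(table)))
  if (nrow(table) == 0L) stop("empty table")
  out <- aggregate(value ~ criterion + group, data = table,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = if (length(v) > 1) sd(v) else NA_real_))
  data.frame(criterion = out$criterion, group = out$group,
             n = as.integer(out$value[, "n"]),
             mean = out$value[, "mean"], sd = out$value[, "sd"],
             stringsAsFactors = FALSE)
}

#' Compare groups per criterion by ANOVA with Tukey HSD post hoc
#'
#' One-way ANOVA per criterion across groups, followed by Tukey honest
#' significant difference pairwise comparisons. Field observations are
#' nested within samples; by default fields are averaged to sample level
#' before testing to avoid pseudo-replication (`level = "field"` tests the
#' raw fields instead and is flagged in the report). Criteria with a
#' degenerate variance structure (all residuals zero) are reported as such,
#' not errors.
#'
#' @param table data frame with columns `group`, `sample`, `criterion`,
#'   `value`.
#' @param alpha family-wise significance level (default 0.05).
#' @param level `"sample"` (default; fields averaged per sample) or
#'   `"field"`.
#' @return A list of class `comparison_report` with elements `summary`
#'   (per-criterion group means +/- SD at the analysis level), `anova`
#'   (omnibus p per criterion), `pairwise` (Tukey-adjusted p and verdict per
#'   group pair; verdict is `"NS"` iff adjusted p >= alpha), `alpha`,
#'   `level`.
#' @export
compare_groups <- function(table, alpha = 0.05,
                           level = c("sample", "field")) {
  stopifnot(is.data.frame(table),
            all(c("group", "sample", "criterion", "value") %in% names(table)))
  level <- match.arg(level)
  stopifnot(alpha > 0, alpha < 1)
  if (length(unique(table$group)) < 2L)
    stop("need at least two groups to compare")

  dat <- if (level == "sample") {
    aggregate(value ~ criterion + group + sample, data = table, FUN = mean)
  } else table
  counts <- table(dat$criterion, dat$group)
  if (any(counts < 2L))
    stop("need at least two observations per group per criterion")

  anova_rows <- list(); pair_rows <- list()
  for (cr in unique(as.character(dat$criterion))) {
    d <- dat[dat$criterion == cr, ]
    d$group <- factor(d$group)
    if (stats::var(d$value) == 0 ||
        all(tapply(d$value, d$group, stats::var) == 0)) {
      anova_rows[[cr]] <- data.frame(criterion = cr, p = NA_real_,
                                     degenerate = TRUE)
      cmb <- utils::combn(levels(d$group), 2)
      pair_rows[[cr]] <- data.frame(
        criterion = cr, comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
        diff = NA_real_, p_adj = NA_real_, verdict = "degenerate",
        stringsAsFactors = FALSE)
      next
    }
    fit <- aov(value ~ group, data = d)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    anova_rows[[cr]] <- data.frame(criterion = cr, p = p, degenerate = FALSE)
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
    pair_rows[[cr]] <- data.frame(
      criterion = cr, comparison = rownames(tk),
      diff = tk[, "diff"], p_adj = tk[, "p adj"],
      verdict = ifelse(tk[, "p adj"] >= alpha, "NS", "significant"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(summary = summarize_fields(dat),
                 anova = do.call(rbind, c(anova_rows, make.row.names = FALSE)),
                 pairwise = do.call(rbind, c(pair_rows, make.row.names = FALSE)),
                 alpha = alpha, level = level),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> ANOVA + Tukey HSD at alpha = %g (%s level)\n",
              x$alpha, x$level))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
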