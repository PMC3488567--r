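#' Immunohistochemistry calling thresholds
#'
#' @param positivity_pct DEK/MSH6 are positive when strictly more than this
#'   percentage of tumor cells show nuclear staining (1%).
#' @param mvd_high_min microvessel density is high when strictly more than
#'   this many vessels per arrayed spot (100).
#' @param mvd_low_max low when strictly fewer than this many (50); counts in
#'   between are indeterminate.
#' @param spot_area_mm2 arrayed spot area the counts refer to (0.036 mm2).
#' @return list of class `"ihc_thresholds"`.
#' @export
ihc_thresholds <- function(positivity_pct = 1.0, mvd_high_min = 100L,
                           mvd_low_max = 50L, spot_area_mm2 = 0.036) {
  stopifnot(positivity_pct >= 0, positivity_pct <= 100,
            mvd_low_max < mvd_high_min)
  structure(list(positivity_pct = positivity_pct,
                 mvd_high_min = mvd_high_min, mvd_low_max = mvd_low_max,
                 spot_area_mm2 = spot_area_mm2), class = "ihc_thresholds")
}

#' Call the three marker statuses of an IHC profile
#'
#' Vectorised over profiles.
#'
#' @param mvd_count vessels per spot.
#' @param dek_pct,msh6_pct percentage of positive tumor cells.
#' @param thresholds an [ihc_thresholds()].
#' @return data.frame: mvd (`high`/`low`/`indeterminate`), dek, msh6
#'   (`pos`/`neg`).
#' @export
call_marker_status <- function(mvd_count, dek_pct, msh6_pct,
                               thresholds = ihc_thresholds()) {
  stopifnot(all(mvd_count >= 0), all(dek_pct >= 0 & dek_pct <= 100),
            all(msh6_pct >= 0 & msh6_pct <= 100))
  data.frame(
    mvd = ifelse(mvd_count > thresholds$mvd_high_min, "high",
                 ifelse(mvd_count < thresholds$mvd_low_max, "low",
                        "indeterminate")),
    dek = ifelse(dek_pct > thresholds$positivity_pct, "pos", "neg"),
    msh6 = ifelse(msh6_pct > thresholds$positivity_pct, "pos", "neg"),
    stringsAsFactors = FALSE)
}

#' Assign a tumor group from marker status
#'
#' The rule: group A = high MVD with DEK and MSH6 positive; group B = MSH6
#' negative (any MVD, any DEK); group C = low MVD with DEK and MSH6
#' positive; everything else is unassigned. The function is total over the
#' 3 x 2 x 2 status space and its preimages are disjoint.
#'
#' @param status data.frame from [call_marker_status()].
#' @return character vector in `{A, B, C, unassigned}`.
#' @export
assign_group_by_markers <- function(status) {
  ifelse(status$msh6 == "neg", "B",
         ifelse(status$mvd == "high" & status$dek == "pos", "A",
                ifelse(status$mvd == "low" & status$dek == "pos", "C",
                       "unassigned")))
}

#' Cross-tabulate an annotation level against assigned groups
#'
#' For each level of `annotation_values`, the count per group and the row
#' percentage (count over row total, rounded half away from zero to
#' integers; `digits = 1` keeps one decimal).
#'
#' @param annotation_values factor-like vector (e.g. histological subtype).
#' @param groups group labels, same length/order.
#' @param digits 0 for integer percentages, 1 for one decimal.
#' @return list: `counts` (table), `percent` (matrix), `row_totals`.
#' @export
classification_table <- function(annotation_values, groups, digits = 0L) {
  stopifnot(length(annotation_values) == length(groups))
  counts <- table(annotation_values, groups)
  totals <- rowSums(counts)
  pct <- 100 * sweep(unclass(counts), 1L, totals, "/")
  round_half_away <- function(x, d) {
    f <- 10^d
    sign(x) * floor(abs(x) * f + 0.5) / f
  }
  list(counts = counts, percent = round_half_away(pct, digits),
       row_totals = totals)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator; censored times reduce the risk set without
#' introducing steps.
#'
#' @param time positive follow-up times (months).
#' @param event 1 = death, 0 = censored.
#' @return data.frame: time, n_risk, n_event, survival (the step function
#'   evaluated just after each observed time).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1L, all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' k-group log-rank test
#'
#' Observed-minus-expected event accumulation over the pooled event times;
#' the statistic is chi-square distributed with k - 1 degrees of freedom
#' under the null of equal survival.
#'
#' @param time,event as in [kaplan_meier()].
#' @param group group label per record (>= 2 groups, >= 1 event).
#' @return list: statistic, df, p_value.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L) stop("need at least 2 non-empty groups")
  if (any(table(group) == 0L)) stop("a group has no records")
  if (sum(event) < 1L) stop("need at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}
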