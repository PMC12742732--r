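# Libet-clock judgment errors and per-subject intentional binding scores.

#' Signed judgment error in milliseconds
#'
#' Angular error wrapped to (-180, 180] degrees and mapped to the clock
#' period: positive values mean the event was reported *later* than it
#' occurred.
#'
#' @param actual_deg actual clock angle(s) in degrees
#' @param reported_deg reported angle(s) in degrees
#' @param clock_period_ms clock rotation period (default 2560 ms)
#' @return signed error(s) in ms
#' @export
judgment_error_ms <- function(actual_deg, reported_deg, clock_period_ms = 2560) {
  delta <- ((reported_deg - actual_deg + 180) %% 360) - 180
  delta / 360 * clock_period_ms
}

#' The shipped binding sign convention
#' @export
binding_convention <- function() {
  paste("action_binding = mean(agency action error) - mean(action-only error);",
        "tone_binding = mean(agency tone error) - mean(tone-only error);",
        "total_binding = action_binding - tone_binding",
        "(positive total = mutual attraction of action and tone)")
}

#' Per-subject intentional binding scores
#'
#' Action binding is the shift of action judgments in agency blocks
#' relative to the action-only baseline; tone binding likewise for tone
#' judgments.  Total binding is `action_binding - tone_binding`, so
#' mutual attraction (action perceived later, tone earlier) is positive.
#' Trials with a missing report are excluded and counted.
#'
#' @param trials data frame with columns `condition`, `actual_deg`,
#'   `reported_deg` and (optionally) `clock_period_ms`
#' @param subject subject identifier carried into the result
#' @param clock_period_ms clock period; default taken from the trials
#' @return one-row data frame: subject, action_binding_ms,
#'   tone_binding_ms, total_binding_ms, n_valid_* per condition, plus a
#'   `convention` attribute (also printed by [binding_convention()])
#' @export
binding_scores <- function(trials, subject = NA,
                           clock_period_ms = NULL) {
  stopifnot(all(c("condition", "actual_deg", "reported_deg") %in% names(trials)))
  period <- clock_period_ms %||% trials$clock_period_ms[1] %||% 2560
  valid <- complete.cases(trials[, c("actual_deg", "reported_deg")])
  trials <- trials[valid, , drop = FALSE]
  err <- judgment_error_ms(trials$actual_deg, trials$reported_deg, period)
  conds <- binding_conditions()
  n_valid <- vapply(conds, function(cc) sum(trials$condition == cc), numeric(1))
  empty <- conds[n_valid == 0]
  if (length(empty))
    stop_invalid("no valid trials in condition(s): ", paste(empty, collapse = ", "))
  m <- vapply(conds, function(cc) mean(err[trials$condition == cc]), numeric(1))
  action <- m[["agency_judge_action"]] - m[["action_only"]]
  tone <- m[["agency_judge_tone"]] - m[["tone_only"]]
  out <- data.frame(subject = subject,
                    action_binding_ms = action,
                    tone_binding_ms = tone,
                    total_binding_ms = action - tone,
                    n_action_only = n_valid[["action_only"]],
                    n_tone_only = n_valid[["tone_only"]],
                    n_agency_judge_action = n_valid[["agency_judge_action"]],
                    n_agency_judge_tone = n_valid[["agency_judge_tone"]],
                    n_excluded = sum(!valid))
  attr(out, "convention") <- binding_convention()
  out
}

#' Group summary of binding scores: mean (SD) per group and measure
#'
#' @param scores data frame of [binding_scores()] rows with a `group`
#'   column
#' @return data frame `(group, measure, mean, sd, n)`; `sd` is the
#'   sample SD (n-1), `NA` for groups of fewer than 2 subjects
#' @export
group_binding_table <- function(scores) {
  stopifnot("group" %in% names(scores))
  measures <- c(action = "action_binding_ms", tone = "tone_binding_ms",
                total = "total_binding_ms")
  rows <- list()
  for (g in unique(scores$group)) {
    sub <- scores[scores$group == g, , drop = FALSE]
    for (mn in names(measures)) {
      v <- sub[[measures[[mn]]]]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, measure = mn, mean = mean(v),
        sd = if (length(v) >= 2) sd(v) else NA_real_, n = length(v))
    }
  }
  do.call(rbind, rows)
}
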