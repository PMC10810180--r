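#' Categorize a sample for one classification task
#'
#' Every (sample, task) pair falls in exactly one evaluation category:
#' \describe{
#'   \item{cross_reactivity}{the sample's own value for the task is
#'     unrepresented — the model must answer although no output class is
#'     correct (e.g. a 70+ patient under an age model whose outputs are 40s
#'     and 60s);}
#'   \item{population_shift}{the own value is represented but some other
#'     attribute of the sample is unrepresented;}
#'   \item{represented}{every attribute value is represented.}
#' }
#' Own-task status dominates: a sample that is cross-reactive for the task
#' and also shifted on other attributes is categorized cross_reactivity.
#'
#' @param sample a `decreg_sample` with complete attributes.
#' @param task task name.
#' @param schema an [attr_schema()].
#' @return list with `category` (character) and `shifted_attributes` (the
#'   tasks whose value is unrepresented).
#' @export
categorize <- function(sample, task, schema) {
  if (!(task %in% schema$tasks)) stop_decreg("unknown task '%s'", task)
  shifted <- character(0)
  for (tk in schema$tasks) {
    v <- sample$attributes[[tk]]
    if (!(v %in% schema$values[[tk]]))
      stop_decreg("sample '%s': value '%s' unknown to schema task '%s'",
                  sample$sample_id, v, tk)
    if (!(v %in% schema$represented[[tk]])) shifted <- c(shifted, tk)
  }
  category <- if (task %in% shifted) "cross_reactivity"
              else if (length(shifted) > 0) "population_shift"
              else "represented"
  list(category = category, shifted_attributes = shifted)
}

#' Correct-classification rates under population shift
#'
#' Among the samples categorized population_shift for the task, reports per
#' true class the percentage correctly classified. An empty class is
#' reported with count 0 and an `NA` rate.
#'
#' @param predictions character vector (or 1-column of a [classify()] matrix)
#'   of predicted labels for the task, aligned with `samples`.
#' @param samples list of `decreg_sample`.
#' @param task task name.
#' @param schema an [attr_schema()].
#' @return data frame of class `shift_report`: columns `task`, `class`,
#'   `percent_correct`, `n_correct`, `count`.
#' @export
population_shift_rates <- function(predictions, samples, task, schema) {
  keep <- vapply(samples, function(s)
    categorize(s, task, schema)$category == "population_shift", logical(1))
  truth <- vapply(samples[keep], function(s) s$attributes[[task]],
                  character(1))
  pred <- predictions[keep]
  rows <- lapply(schema$classes[[task]], function(cl) {
    idx <- truth == cl
    n <- sum(idx)
    correct <- sum(pred[idx] == cl)
    data.frame(task = task, class = cl,
               percent_correct = if (n > 0) 100 * correct / n else NA_real_,
               n_correct = correct, count = n, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("shift_report", "data.frame"))
}

#' Class-assignment rates under cross-reactivity
#'
#' For the samples whose own value for the task is unrepresented, reports per
#' unrepresented group the percentage assigned to each model output class;
#' per group the percentages sum to 100. This exposes where the model sends
#' patients it cannot classify correctly (e.g. what share of never-seen race
#' groups is labeled with each represented race).
#'
#' @inheritParams population_shift_rates
#' @return data frame of class `cross_reactivity_report`: columns `task`,
#'   `group` (the unrepresented true value), `class`, `percent`, `count`
#'   (group size).
#' @export
cross_reactivity_rates <- function(predictions, samples, task, schema) {
  keep <- vapply(samples, function(s)
    categorize(s, task, schema)$category == "cross_reactivity", logical(1))
  truth <- vapply(samples[keep], function(s) s$attributes[[task]],
                  character(1))
  pred <- predictions[keep]
  groups <- setdiff(schema$values[[task]], schema$represented[[task]])
  rows <- list()
  for (g in groups) {
    idx <- truth == g
    n <- sum(idx)
    for (cl in schema$classes[[task]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, group = g, class = cl,
        percent = if (n > 0) 100 * sum(pred[idx] == cl) / n else NA_real_,
        count = n, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    rows <- list(data.frame(task = character(0), group = character(0),
                            class = character(0), percent = numeric(0),
                            count = integer(0)))
  structure(do.call(rbind, rows),
            class = c("cross_reactivity_report", "data.frame"))
}

#' Does the shift behavior agree with the detected preferred class?
#'
#' Checks, per task, whether the model's behavior on unrepresented cohorts
#' points in the direction predicted by the decision-region analysis:
#' \itemize{
#'   \item (a) population shift — the correct-classification rate of the
#'     preferred class exceeds that of the non-preferred class (the model
#'     rarely misses members of the class it over-assigns);
#'   \item (b) cross-reactivity — unrepresented groups are assigned to the
#'     preferred class more often than to any other class.
#' }
#' Margins below `min_margin` percentage points, or a missing cohort, yield
#' an indeterminate (`NA`) verdict rather than an error, so symmetric models
#' are not over-interpreted.
#'
#' @param shift a `shift_report` for the task (or `NULL` if no shifted
#'   cohort exists).
#' @param cross a `cross_reactivity_report` for the task (or `NULL`; tasks
#'   whose every value is represented have no cross-reactive cohort).
#' @param preferred a `preferred_class_report`.
#' @param task task name.
#' @param min_margin margin (percentage points) below which a criterion is
#'   indeterminate.
#' @return list with `task`, `preferred`, `agreement` (TRUE/FALSE/NA),
#'   `shift_ok`, `cross_ok`, `shift_margin`, `cross_margin`.
#' @export
preferred_class_agreement <- function(shift, cross, preferred, task,
                                      min_margin = 1) {
  pc <- preferred[[task]]$preferred
  shift_ok <- NA; shift_margin <- NA_real_
  if (!is.null(shift) && nrow(shift) > 0 && pc %in% shift$class) {
    pref_rate <- shift$percent_correct[shift$class == pc]
    other <- shift$percent_correct[shift$class != pc]
    if (length(other) > 0 && !anyNA(c(pref_rate, other))) {
      shift_margin <- pref_rate - max(other)
      if (abs(shift_margin) >= min_margin) shift_ok <- shift_margin > 0
    }
  }
  cross_ok <- NA; cross_margin <- NA_real_
  if (!is.null(cross) && nrow(cross) > 0) {
    pooled <- tapply(cross$percent * cross$count, cross$class, sum) /
      tapply(cross$count, cross$class, sum)
    if (!anyNA(pooled) && pc %in% names(pooled) && length(pooled) > 1) {
      cross_margin <- pooled[pc] - max(pooled[names(pooled) != pc])
      if (abs(cross_margin) >= min_margin) cross_ok <- cross_margin > 0
    }
  }
  verdicts <- c(shift_ok, cross_ok)
  agreement <- if (all(is.na(verdicts))) NA
               else all(verdicts[!is.na(verdicts)])
  list(task = task, preferred = pc, agreement = agreement,
       shift_ok = shift_ok, cross_ok = cross_ok,
       shift_margin = unname(shift_margin),
       cross_margin = unname(cross_margin))
}
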