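#' Attribute schema for classification tasks
#'
#' Defines the classification tasks of an audit, the model output classes for
#' each task, which attribute values were represented in model development
#' data, and which output class is scored as "positive" by the classifier.
#' An attribute may take values beyond the model's output classes (for
#' example a race value that the model cannot emit); such values drive the
#' cross-reactivity evaluation.
#'
#' @param tasks character vector of task names, in canonical order. Subgroups
#'   are tuples of attribute values in this order.
#' @param classes named list (one entry per task) of the model's output class
#'   labels; each task must have at least two classes. The package's decision
#'   rule is binary per task.
#' @param represented named list (one entry per task) of the attribute values
#'   present in model development data. May include values that are not model
#'   output classes.
#' @param positive named character vector (one entry per task): the class
#'   reported when the task score meets or exceeds the decision threshold.
#' @param values optional named list of all attribute values known for each
#'   task (defaults to the union of classes and represented values). Samples
#'   carrying a value outside this set are rejected.
#' @return an object of class `attr_schema`.
#' @examples
#' sch <- attr_schema(
#'   tasks = c("sex", "covid"),
#'   classes = list(sex = c("F", "M"), covid = c("negative", "positive")),
#'   represented = list(sex = c("F", "M"), covid = c("negative", "positive")),
#'   positive = c(sex = "F", covid = "positive"))
#' @export
attr_schema <- function(tasks, classes, represented, positive, values = NULL) {
  tasks <- as.character(tasks)
  if (anyDuplicated(tasks)) stop_decreg("duplicate task names in schema")
  for (tk in tasks) {
    cl <- classes[[tk]]
    if (is.null(cl) || length(cl) < 2)
      stop_decreg("task '%s' must have >= 2 model output classes", tk)
    if (is.null(represented[[tk]]))
      stop_decreg("task '%s' has no represented values", tk)
    if (is.na(positive[tk]) || !(positive[tk] %in% cl))
      stop_decreg("positive class of task '%s' is not an output class", tk)
  }
  if (is.null(values)) {
    values <- lapply(tasks, function(tk) union(classes[[tk]], represented[[tk]]))
    names(values) <- tasks
  } else {
    for (tk in tasks) {
      values[[tk]] <- union(values[[tk]], union(classes[[tk]], represented[[tk]]))
    }
  }
  structure(list(tasks = tasks,
                 classes = classes[tasks],
                 represented = represented[tasks],
                 positive = positive[tasks],
                 values = values[tasks]),
            class = "attr_schema")
}

#' @export
print.attr_schema <- function(x, ...) {
  cat("Attribute schema:", length(x$tasks), "task(s)\n")
  for (tk in x$tasks) {
    cat(sprintf("  %s: classes [%s], represented [%s], positive = %s\n",
                tk, paste(x$classes[[tk]], collapse = ", "),
                paste(x$represented[[tk]], collapse = ", "),
                x$positive[tk]))
  }
  invisible(x)
}

#' Construct a sample
#'
#' A sample couples one grayscale image with its patient identity and the
#' attribute value for every schema task. Pixel intensities are stored in
#' \[0, 1\] (8-bit inputs are divided by 255 at load time).
#'
#' @param sample_id,patient_id character scalars; the patient is the unit of
#'   partitioning.
#' @param pixels numeric matrix of intensities.
#' @param attributes named character vector, one value per schema task.
#' @return an object of class `decreg_sample`.
#' @export
new_sample <- function(sample_id, patient_id, pixels, attributes) {
  if (!is.matrix(pixels)) stop_decreg("pixels must be a 2-D matrix")
  structure(list(sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 pixels = pixels,
                 attributes = attributes),
            class = "decreg_sample")
}

#' @export
print.decreg_sample <- function(x, ...) {
  cat(sprintf("sample %s (patient %s), %dx%d image, attributes: %s\n",
              x$sample_id, x$patient_id, nrow(x$pixels), ncol(x$pixels),
              paste(names(x$attributes), x$attributes, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Subgroup of a sample
#'
#' The subgroup is the ordered tuple of the sample's attribute values, one per
#' schema task and in schema task order (e.g. female-black-negative-40s for a
#' four-task schema).
#'
#' @param sample a `decreg_sample` with complete attributes.
#' @param schema an [attr_schema()].
#' @return character vector of attribute values in schema task order.
#' @export
assign_subgroup <- function(sample, schema) {
  vals <- sample$attributes[schema$tasks]
  if (anyNA(vals) || any(!nzchar(vals)))
    stop_decreg("sample '%s' has missing attributes", sample$sample_id)
  unname(vals)
}

#' Split a cohort into represented and unrepresented samples
#'
#' A sample is represented if and only if every one of its attribute values
#' belongs to the represented set of its task; a single unrepresented value
#' (e.g. an Asian patient under a schema whose represented races are black and
#' white) places the whole sample in the unrepresented pool, which is withheld
#' from development-style partitioning and used for the shift evaluations.
#'
#' @param samples list of `decreg_sample`.
#' @param schema an [attr_schema()] with represented values for every task.
#' @return list with order-preserving components `represented` and
#'   `unrepresented`.
#' @export
split_represented <- function(samples, schema) {
  is_rep <- vapply(samples, function(s) {
    for (tk in schema$tasks) {
      v <- s$attributes[[tk]]
      if (!(v %in% schema$values[[tk]]))
        stop_decreg("sample '%s': value '%s' unknown to schema task '%s'",
                    s$sample_id, v, tk)
      if (!(v %in% schema$represented[[tk]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  list(represented = samples[is_rep], unrepresented = samples[!is_rep])
}

# Group a cohort by subgroup key; returns a named list of sample lists.
#' @export
#' @rdname split_represented
#' @param samples list of `decreg_sample`.
group_by_subgroup <- function(samples, schema) {
  keys <- vapply(samples, function(s) subgroup_key(assign_subgroup(s, schema)),
                 character(1))
  split(samples, factor(keys, levels = unique(keys)))
}
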