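#' Decision-region composition of one triplet
#'
#' Tallies, per task, the fraction of virtual samples classified as each
#' output class. Because the lattice points are evenly distributed over the
#' triangle spanned by the triplet, these fractions are a proxy for the area
#' of the decision region dedicated to each class in the vicinity of the
#' triplet. The `same_class` entry is the fraction matching the triplet
#' subgroup's own value for the task; when that value is not a model output
#' class (a cross-reactive subgroup) it is 0 by definition.
#'
#' @param predictions n_points x n_tasks character matrix of predicted class
#'   labels, rows in lattice order (from [classify()]).
#' @param triplet the `triplet` the virtual samples came from.
#' @param schema an [attr_schema()].
#' @param triplet_id optional identifier carried into exports.
#' @return an object of class `triplet_composition`: list with `triplet_id`,
#'   `subgroup`, `fractions` (per task, named numeric over output classes),
#'   `same_class` (named numeric per task) and `n_points`.
#' @export
triplet_composition <- function(predictions, triplet, schema,
                                triplet_id = NA_character_) {
  if (is.null(dim(predictions)))
    predictions <- matrix(predictions, ncol = length(schema$tasks),
                          dimnames = list(NULL, schema$tasks))
  n <- nrow(predictions)
  fractions <- list()
  same_class <- numeric(0)
  for (ti in seq_along(schema$tasks)) {
    tk <- schema$tasks[ti]
    cls <- schema$classes[[tk]]
    counts <- vapply(cls, function(cl) sum(predictions[, tk] == cl),
                     numeric(1))
    if (sum(counts) != n)
      stop_decreg("task '%s': %d prediction(s) outside the output classes",
                  tk, n - sum(counts))
    fractions[[tk]] <- counts / n
    own <- triplet$subgroup[ti]
    same_class[tk] <- if (own %in% cls) fractions[[tk]][own] else 0
  }
  structure(list(triplet_id = triplet_id, subgroup = triplet$subgroup,
                 fractions = fractions, same_class = same_class,
                 n_points = n),
            class = "triplet_composition")
}

#' Synthesize, classify and compose one triplet
#'
#' Convenience wrapper running the full per-triplet chain:
#' [synthesize_virtual_samples()] on the lattice, [predict_scores()] through
#' the adapter, [classify()] with the calibrated thresholds, then
#' [triplet_composition()].
#'
#' @inheritParams triplet_composition
#' @param triplet a `triplet`.
#' @param adapter a classifier adapter (see [predict_scores()]).
#' @param thresholds a `task_thresholds`.
#' @param lattice a [barycentric_lattice()].
#' @return a `triplet_composition`.
#' @export
compose_triplet <- function(triplet, adapter, thresholds, schema,
                            lattice = barycentric_lattice(25L),
                            triplet_id = NA_character_) {
  virt <- synthesize_virtual_samples(triplet, lattice)
  scores <- predict_scores(adapter, virt$pixels)
  preds <- classify(scores, thresholds, schema)
  triplet_composition(preds, triplet, schema, triplet_id = triplet_id)
}

#' Composition over a charted plane grid
#'
#' Companion to [plane_chart()]: tallies class fractions over the rectangular
#' grid of a charted plane. By default only grid points inside the triplet
#' triangle count, matching the lattice-based composition's domain; with
#' `triangle_only = FALSE` the whole extended rectangle contributes. The
#' extended plane leaves the convex hull of the triplet, where virtual images
#' require clipping and the subgroup reference class is less meaningful, so
#' it is reported for exploration rather than used in subgroup aggregates.
#'
#' @param chart a [plane_chart()].
#' @param labels character vector of predicted class labels, one per chart
#'   grid point.
#' @param classes class levels to tally.
#' @param triangle_only restrict to grid points inside the triangle.
#' @return named numeric vector of fractions summing to 1.
#' @export
chart_composition <- function(chart, labels, classes,
                              triangle_only = TRUE) {
  if (length(labels) != nrow(chart$coords))
    stop_decreg("expected %d labels, got %d", nrow(chart$coords),
                length(labels))
  keep <- if (triangle_only) chart$inside else rep(TRUE, length(labels))
  if (!any(keep)) stop_decreg("no grid points selected")
  counts <- vapply(classes, function(cl) sum(labels[keep] == cl),
                   numeric(1))
  if (sum(counts) != sum(keep))
    stop_decreg("%d label(s) outside the given classes",
                sum(keep) - sum(counts))
  counts / sum(keep)
}

#' Aggregate triplet compositions over a subgroup
#'
#' Unweighted mean and sample (n - 1) standard deviation of the per-class
#' fractions over a subgroup's triplets, giving one estimate of the decision
#' space composition surrounding the subgroup. A single-triplet aggregate
#' reports standard deviation 0 and sets the `degenerate` flag.
#'
#' @param compositions non-empty list of `triplet_composition`, all from the
#'   same subgroup.
#' @param schema an [attr_schema()].
#' @return an object of class `subgroup_composition`: `subgroup`,
#'   `n_triplets`, `stats` (data frame task/class/mean/sd), `same_class`
#'   (data frame task/mean/sd), `degenerate`.
#' @export
aggregate_subgroup <- function(compositions, schema) {
  if (length(compositions) == 0)
    stop_decreg("cannot aggregate an empty set of compositions")
  sg <- compositions[[1]]$subgroup
  for (cc in compositions)
    if (!identical(cc$subgroup, sg))
      stop_decreg("compositions mix subgroups ('%s' vs '%s')",
                  subgroup_key(sg), subgroup_key(cc$subgroup))
  n <- length(compositions)
  rows <- list(); sc_rows <- list()
  for (ti in seq_along(schema$tasks)) {
    tk <- schema$tasks[ti]
    for (cl in schema$classes[[tk]]) {
      fr <- vapply(compositions, function(cc) cc$fractions[[tk]][cl],
                   numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        task = tk, class = cl, mean = mean(fr), sd = sd0(fr),
        stringsAsFactors = FALSE)
    }
    sc <- vapply(compositions, function(cc) cc$same_class[tk], numeric(1))
    sc_rows[[ti]] <- data.frame(task = tk, mean = mean(sc), sd = sd0(sc),
                                stringsAsFactors = FALSE)
  }
  structure(list(subgroup = sg, n_triplets = n,
                 stats = do.call(rbind, rows),
                 same_class = do.call(rbind, sc_rows),
                 degenerate = n < 2),
            class = "subgroup_composition")
}

#' Detect the preferred class of each task
#'
#' The assigned share of a class is the mean, over subgroups with equal
#' weights, of the subgroup-mean fraction of the decision region assigned to
#' that class. The preferred class of a task is the one holding the largest
#' assigned share; the preference gap is the margin over the runner-up. The
#' report also carries the per-class same-class summary (mean same-class
#' fraction over the subgroups whose own value for the task is that class),
#' the descriptive view from which preferred classes can be read off.
#'
#' @param subgroup_compositions list of `subgroup_composition` (one per
#'   subgroup). For the same-class summary every output class of every task
#'   must be the subgroup value of at least one contributing subgroup.
#' @param schema an [attr_schema()].
#' @return an object of class `preferred_class_report`: per task a list with
#'   `shares` (named numeric), `preferred`, `gap`, `same_class_by_class`
#'   (named numeric).
#' @export
preferred_class <- function(subgroup_compositions, schema) {
  report <- list()
  for (ti in seq_along(schema$tasks)) {
    tk <- schema$tasks[ti]
    cls <- schema$classes[[tk]]
    shares <- vapply(cls, function(cl) {
      mean(vapply(subgroup_compositions, function(sc)
        sc$stats$mean[sc$stats$task == tk & sc$stats$class == cl],
        numeric(1)))
    }, numeric(1))
    scs <- vapply(cls, function(cl) {
      contrib <- Filter(function(sc) sc$subgroup[ti] == cl,
                        subgroup_compositions)
      if (length(contrib) == 0)
        stop_decreg(paste0("task '%s': no subgroup has own value '%s'; ",
                           "the same-class summary is undefined"), tk, cl)
      mean(vapply(contrib, function(sc)
        sc$same_class$mean[sc$same_class$task == tk], numeric(1)))
    }, numeric(1))
    ord <- order(-shares)
    report[[tk]] <- list(shares = shares,
                         preferred = cls[ord[1]],
                         gap = shares[ord[1]] - shares[ord[2]],
                         same_class_by_class = scs)
  }
  structure(report, class = "preferred_class_report")
}

#' @export
print.preferred_class_report <- function(x, ...) {
  for (tk in names(x)) {
    cat(sprintf("  %s: preferred = %s (gap %.3f); shares: %s\n", tk,
                x[[tk]]$preferred, x[[tk]]$gap,
                paste(names(x[[tk]]$shares),
                      sprintf("%.3f", x[[tk]]$shares),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Sensitivity of subgroup composition to the number of triplets
#'
#' Repeatedly subsamples `T` triplets (without replacement within a
#' resample) from a pool of compositions and records the mean same-class
#' fraction of each subset, estimating how stable the subgroup aggregate is
#' at each triplet count. A flat curve beyond some `T` indicates that many
#' triplets are enough to characterize the composition; the standard
#' deviation across resamples follows the finite-population sampling law of
#' a subset mean.
#'
#' @param pool list of `triplet_composition` from one subgroup (or any pool
#'   whose same-class fraction is of interest).
#' @param task the task whose same-class fraction is tracked.
#' @param counts integer vector of triplet counts `T`; all must be at most
#'   the pool size.
#' @param n_resamples subsets drawn per count (>= 2).
#' @param seed integer seed.
#' @return an object of class `sensitivity_curve`: data frame with columns
#'   `T`, `mean`, `std`, `n_resamples`.
#' @export
triplet_count_sensitivity <- function(pool, task, counts, n_resamples = 200L,
                                      seed = 1L) {
  if (n_resamples < 2) stop_decreg("n_resamples must be >= 2")
  vals <- vapply(pool, function(cc) cc$same_class[task], numeric(1))
  N <- length(vals)
  if (any(counts > N))
    stop_decreg("requested triplet count %d exceeds pool size %d",
                max(counts), N)
  rows <- lapply(counts, function(T) {
    set.seed(stable_hash(seed, "sensitivity", T))
    means <- vapply(seq_len(n_resamples), function(r)
      mean(vals[sample(N, T)]), numeric(1))
    data.frame(T = T, mean = mean(means), std = sd0(means),
               n_resamples = n_resamples)
  })
  structure(do.call(rbind, rows), seed = seed,
            class = c("sensitivity_curve", "data.frame"))
}

#' Export compositions and aggregates as CSV
#'
#' @param compositions list of `triplet_composition`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compositions <- function(compositions, path) {
  rows <- list()
  for (cc in compositions) {
    for (tk in names(cc$fractions)) {
      fr <- cc$fractions[[tk]]
      rows[[length(rows) + 1L]] <- data.frame(
        triplet_id = cc$triplet_id, subgroup = subgroup_key(cc$subgroup),
        task = tk, class = names(fr), fraction = unname(fr),
        n_points = cc$n_points, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compositions
#' @param aggregates list of `subgroup_composition`.
#' @export
write_subgroup_compositions <- function(aggregates, path) {
  rows <- lapply(aggregates, function(sc) {
    df <- sc$stats
    df$subgroup <- subgroup_key(sc$subgroup)
    df$n_triplets <- sc$n_triplets
    df[, c("subgroup", "task", "class", "mean", "sd", "n_triplets")]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
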