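#' Run the full decision-region audit pipeline
#'
#' Executes the stages of a decision-region generalizability audit on an
#' in-memory cohort and classifier adapter, writing every report to
#' `out_dir`:
#' \enumerate{
#'   \item \strong{partition} — represented/unrepresented split and
#'     patient-stratified repeated partitions (`partition_plan.csv`);
#'   \item \strong{calibrate} — equal-error thresholds per
#'     (eval_repeat, train_repeat) pair on validation1 (`thresholds.json`
#'     holds the first pair);
#'   \item \strong{regions} — triplet sampling from validation2 and
#'     per-triplet composition (`triplet_roster.csv`, `compositions.csv`);
#'   \item \strong{aggregate} — subgroup aggregation
#'     (`subgroup_compositions.csv`);
#'   \item \strong{preferred} — preferred-class report
#'     (`preferred_class.json`);
#'   \item \strong{evaluate} — population-shift and cross-reactivity rates
#'     over all repeat pairs plus preferred-class agreement
#'     (`shift_report.csv`, `cross_reactivity.csv`, `agreement.json`);
#'   \item \strong{sensitivity} — triplet-count sensitivity on an enlarged
#'     triplet pool of the subgroup/task pair whose composition varied most
#'     across triplets (`sensitivity.csv`).
#' }
#' One master seed drives every random choice. A `run_manifest.json` records
#' the seeds, settings and a configuration hash; every CSV has a stable
#' header. With `resume = TRUE`, stages whose outputs already exist and whose
#' upstream stages did not rerun are skipped and their outputs are read back
#' from disk.
#'
#' @param samples full cohort (represented and unrepresented samples).
#' @param schema an [attr_schema()].
#' @param adapter classifier adapter (see [predict_scores()]).
#' @param out_dir output directory, created if needed.
#' @param seed master integer seed.
#' @param resolution barycentric lattice resolution R.
#' @param n_triplets triplets per subgroup.
#' @param fractions,n_eval_repeats,n_train_repeats see [make_partitions()].
#' @param region_eval_repeat,region_train_repeat the repeat pair whose
#'   validation2/validation1 sets drive region generation.
#' @param sensitivity_counts triplet counts for the sensitivity stage;
#'   the pool size is `max(sensitivity_counts)`.
#' @param n_resamples resamples per sensitivity count.
#' @param fixed_thresholds optional `task_thresholds` (e.g. from
#'   [nominal_thresholds()]): audit the model at this fixed operating point
#'   instead of re-calibrating; the calibrate stage then only reports the
#'   fixed point's FPR/FNR on validation1. With `NULL` (default) thresholds
#'   are calibrated per repeat pair at the equal-error point on validation1.
#'   Note that equal-error re-calibration absorbs any uniform score bias of
#'   the model, by design.
#' @param resume skip stages whose outputs are present (see above).
#' @param verbose print one line per stage.
#' @return invisibly, a list with the in-memory stage results (`plan`,
#'   `thresholds`, `compositions`, `aggregates`, `preferred`, `evaluation`,
#'   `sensitivity`) and `ran` (named logical of executed stages).
#' @export
run_pipeline <- function(samples, schema, adapter, out_dir, seed = 1L,
                         resolution = 25L, n_triplets = 50L,
                         fractions = c(0.5, 0.1, 0.2, 0.2),
                         n_eval_repeats = 5L, n_train_repeats = 5L,
                         region_eval_repeat = 1L, region_train_repeat = 1L,
                         sensitivity_counts = c(5L, 10L, 25L, 50L, 100L,
                                                150L),
                         n_resamples = 200L, fixed_thresholds = NULL,
                         resume = FALSE, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    partition = file.path(out_dir, "partition_plan.csv"),
    calibrate = file.path(out_dir, "thresholds.json"),
    regions = file.path(out_dir, c("compositions.csv", "triplet_roster.csv")),
    aggregate = file.path(out_dir, "subgroup_compositions.csv"),
    preferred = file.path(out_dir, "preferred_class.json"),
    evaluate = file.path(out_dir, c("shift_report.csv",
                                    "cross_reactivity.csv",
                                    "agreement.json")),
    sensitivity = file.path(out_dir, "sensitivity.csv"))
  deps <- list(partition = character(0),
               calibrate = "partition",
               regions = c("partition", "calibrate"),
               aggregate = "regions",
               preferred = "aggregate",
               evaluate = c("calibrate", "preferred"),
               sensitivity = c("partition", "calibrate", "aggregate"))
  ran <- stats::setNames(logical(length(paths)), names(paths))
  needs_run <- function(stage) {
    !resume || !all(file.exists(paths[[stage]])) || any(ran[deps[[stage]]])
  }
  say <- function(stage, action) {
    if (verbose) message(sprintf("[%s] %s", stage, action))
  }

  split <- split_represented(samples, schema)
  lattice <- barycentric_lattice(resolution)

  # -- partition ------------------------------------------------------------
  if (ran["partition"] <- needs_run("partition")) {
    say("partition", "building patient-stratified partitions")
    plan <- make_partitions(split$represented, schema, fractions,
                            n_eval_repeats, n_train_repeats, seed)
    write_partition_plan(plan, paths$partition)
  } else {
    say("partition", "reusing partition_plan.csv")
    plan <- make_partitions(split$represented, schema, fractions,
                            n_eval_repeats, n_train_repeats, seed)
  }

  # -- calibrate (all repeat pairs; thresholds.json records the region pair)
  val1_thresholds <- function(er, tr) {
    val1 <- partition_samples(plan, split$represented, "validation1", er, tr)
    scores <- predict_scores(adapter, val1)
    if (is.null(fixed_thresholds))
      calibrate_thresholds(scores, val1, schema)
    else
      report_thresholds(fixed_thresholds, scores, val1, schema)
  }
  if (ran["calibrate"] <- needs_run("calibrate")) {
    say("calibrate", if (is.null(fixed_thresholds))
      "calibrating equal-error thresholds on validation1"
      else "reporting fixed operating point on validation1")
    thresholds <- val1_thresholds(region_eval_repeat, region_train_repeat)
    write_thresholds(thresholds, paths$calibrate)
  } else {
    say("calibrate", "reusing thresholds.json")
    thresholds <- read_thresholds(paths$calibrate)
  }

  # -- regions --------------------------------------------------------------
  if (ran["regions"] <- needs_run("regions")) {
    say("regions", sprintf("composing %d triplets per subgroup at R = %d",
                           n_triplets, resolution))
    val2 <- partition_samples(plan, split$represented, "validation2",
                              region_eval_repeat, region_train_repeat)
    by_sg <- group_by_subgroup(val2, schema)
    by_sg <- by_sg[order(names(by_sg))]
    triplets <- sample_triplets(by_sg, schema, n_triplets, seed)
    compositions <- list()
    roster <- list()
    for (key in names(triplets)) {
      for (i in seq_along(triplets[[key]])) {
        tp <- triplets[[key]][[i]]
        tid <- sprintf("%s#%03d", key, i)
        compositions[[length(compositions) + 1L]] <-
          compose_triplet(tp, adapter, thresholds, schema, lattice, tid)
        roster[[length(roster) + 1L]] <- data.frame(
          subgroup = key, triplet_id = tid,
          sample_id_0 = tp$members[[1]]$sample_id,
          sample_id_1 = tp$members[[2]]$sample_id,
          sample_id_2 = tp$members[[3]]$sample_id,
          stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, roster), paths$regions[2],
                     row.names = FALSE)
    write_compositions(compositions, paths$regions[1])
  } else {
    say("regions", "reusing compositions.csv")
    compositions <- read_compositions(paths$regions[1], schema)
  }

  # -- aggregate ------------------------------------------------------------
  keys <- vapply(compositions, function(cc) subgroup_key(cc$subgroup),
                 character(1))
  by_key <- split(compositions, factor(keys, levels = unique(keys)))
  if (ran["aggregate"] <- needs_run("aggregate")) {
    say("aggregate", "aggregating subgroup compositions")
    aggregates <- lapply(by_key, aggregate_subgroup, schema = schema)
    write_subgroup_compositions(aggregates, paths$aggregate)
  } else {
    say("aggregate", "reusing subgroup_compositions.csv")
    aggregates <- lapply(by_key, aggregate_subgroup, schema = schema)
  }

  # -- preferred ------------------------------------------------------------
  if (ran["preferred"] <- needs_run("preferred")) {
    say("preferred", "detecting preferred classes")
    preferred <- preferred_class(aggregates, schema)
    jsonlite::write_json(lapply(preferred, function(x)
      list(preferred = x$preferred, gap = x$gap,
           shares = as.list(x$shares),
           same_class_by_class = as.list(x$same_class_by_class))),
      paths$preferred, auto_unbox = TRUE, digits = NA)
  } else {
    say("preferred", "reusing preferred_class.json")
    preferred <- preferred_class(aggregates, schema)
  }

  # -- evaluate -------------------------------------------------------------
  if (ran["evaluate"] <- needs_run("evaluate")) {
    say("evaluate", "evaluating population shift and cross-reactivity")
    unrep <- split$unrepresented
    shift_rows <- list(); cross_rows <- list()
    if (length(unrep) > 0) {
      scores <- predict_scores(adapter, unrep)
      for (er in seq_len(n_eval_repeats)) for (tr in seq_len(n_train_repeats)) {
        th <- if (er == region_eval_repeat && tr == region_train_repeat)
          thresholds else val1_thresholds(er, tr)
        preds <- classify(scores, th, schema)
        for (tk in schema$tasks) {
          sr <- population_shift_rates(preds[, tk], unrep, tk, schema)
          sr$eval_repeat <- er; sr$train_repeat <- tr
          shift_rows[[length(shift_rows) + 1L]] <- sr
          cr <- cross_reactivity_rates(preds[, tk], unrep, tk, schema)
          if (nrow(cr) > 0) {
            cr$eval_repeat <- er; cr$train_repeat <- tr
            cross_rows[[length(cross_rows) + 1L]] <- cr
          }
        }
      }
    }
    shift <- if (length(shift_rows)) do.call(rbind, shift_rows) else
      data.frame(task = character(0), class = character(0),
                 percent_correct = numeric(0), n_correct = integer(0),
                 count = integer(0), eval_repeat = integer(0),
                 train_repeat = integer(0))
    cross <- if (length(cross_rows)) do.call(rbind, cross_rows) else
      data.frame(task = character(0), group = character(0),
                 class = character(0), percent = numeric(0),
                 count = integer(0), eval_repeat = integer(0),
                 train_repeat = integer(0))
    utils::write.csv(shift, paths$evaluate[1], row.names = FALSE)
    utils::write.csv(cross, paths$evaluate[2], row.names = FALSE)
    agreement <- lapply(schema$tasks, function(tk) {
      sr <- pool_shift(shift, tk)
      cr <- pool_cross(cross, tk)
      preferred_class_agreement(sr, cr, preferred, tk)
    })
    names(agreement) <- schema$tasks
    jsonlite::write_json(agreement, paths$evaluate[3], auto_unbox = TRUE,
                         digits = NA)
    evaluation <- list(shift = shift, cross = cross, agreement = agreement)
  } else {
    say("evaluate", "reusing evaluation reports")
    evaluation <- list(
      shift = utils::read.csv(paths$evaluate[1]),
      cross = utils::read.csv(paths$evaluate[2]),
      agreement = jsonlite::fromJSON(paths$evaluate[3],
                                     simplifyVector = FALSE))
  }

  # -- sensitivity ----------------------------------------------------------
  if (ran["sensitivity"] <- needs_run("sensitivity")) {
    # track the (task, subgroup) pair whose same-class composition varied
    # most across triplets: the least stable estimate is the one whose
    # dependence on the triplet count is informative
    pick_task <- schema$tasks[1]; pick_key <- names(by_key)[1]; best <- -1
    for (sc in aggregates) for (ti in seq_len(nrow(sc$same_class))) {
      if (sc$same_class$sd[ti] > best) {
        best <- sc$same_class$sd[ti]
        pick_task <- sc$same_class$task[ti]
        pick_key <- subgroup_key(sc$subgroup)
      }
    }
    say("sensitivity", sprintf("triplet-count sensitivity on %s / %s",
                               pick_key, pick_task))
    val2 <- partition_samples(plan, split$represented, "validation2",
                              region_eval_repeat, region_train_repeat)
    by_sg <- group_by_subgroup(val2, schema)
    pool_n <- max(sensitivity_counts)
    pool_trips <- sample_triplets(by_sg[pick_key], schema, pool_n,
                                  stable_hash(seed, "sens-pool"))[[1]]
    pool <- lapply(seq_along(pool_trips), function(i)
      compose_triplet(pool_trips[[i]], adapter, thresholds, schema, lattice,
                      sprintf("sens#%03d", i)))
    curve <- triplet_count_sensitivity(pool, pick_task,
                                       sensitivity_counts, n_resamples,
                                       seed)
    utils::write.csv(as.data.frame(curve), paths$sensitivity,
                     row.names = FALSE)
  } else {
    say("sensitivity", "reusing sensitivity.csv")
    curve <- utils::read.csv(paths$sensitivity)
  }

  settings <- list(seed = seed, resolution = resolution,
                   n_triplets = n_triplets, fractions = fractions,
                   n_eval_repeats = n_eval_repeats,
                   n_train_repeats = n_train_repeats,
                   region_eval_repeat = region_eval_repeat,
                   region_train_repeat = region_train_repeat,
                   sensitivity_counts = sensitivity_counts,
                   n_resamples = n_resamples)
  jsonlite::write_json(
    list(settings = settings,
         config_hash = sprintf("%08x", stable_hash(settings)),
         n_samples = length(samples),
         n_represented = length(split$represented),
         tasks = schema$tasks),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(plan = plan, thresholds = thresholds,
                 compositions = compositions, aggregates = aggregates,
                 preferred = preferred, evaluation = evaluation,
                 sensitivity = curve, ran = ran))
}

# pool per-repeat shift rows to one shift_report (mean over repeats)
#' @noRd
pool_shift <- function(shift, task) {
  s <- shift[shift$task == task & !is.na(shift$percent_correct), ,
             drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  rows <- lapply(split(s, s$class), function(d)
    data.frame(task = task, class = d$class[1],
               percent_correct = mean(d$percent_correct),
               n_correct = mean(d$n_correct), count = mean(d$count),
               stringsAsFactors = FALSE))
  structure(do.call(rbind, rows),
            class = c("shift_report", "data.frame"))
}

#' @noRd
pool_cross <- function(cross, task) {
  s <- cross[cross$task == task & !is.na(cross$percent), , drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  rows <- lapply(split(s, paste(s$group, s$class, sep = "\r")), function(d)
    data.frame(task = task, group = d$group[1], class = d$class[1],
               percent = mean(d$percent), count = mean(d$count),
               stringsAsFactors = FALSE))
  structure(do.call(rbind, rows),
            class = c("cross_reactivity_report", "data.frame"))
}

#' Read back exported thresholds / compositions
#'
#' File readers for resuming a pipeline from its exported artifacts.
#'
#' @param path file path written by [write_thresholds()] or
#'   [write_compositions()].
#' @return the reconstructed `task_thresholds` or list of
#'   `triplet_composition`.
#' @export
read_thresholds <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(lapply(obj, function(th)
    list(threshold = th$threshold, fpr = th$fpr, fnr = th$fnr,
         n = th$n_calibration)),
    class = "task_thresholds")
}

#' @rdname read_thresholds
#' @param schema an [attr_schema()] (needed to recover same-class fractions
#'   from the stored subgroup key).
#' @export
read_compositions <- function(path, schema) {
  df <- utils::read.csv(path, colClasses = c(triplet_id = "character",
                                             subgroup = "character",
                                             task = "character",
                                             class = "character"))
  out <- list()
  for (tid in unique(df$triplet_id)) {
    d <- df[df$triplet_id == tid, , drop = FALSE]
    sg <- subgroup_unkey(d$subgroup[1])
    fractions <- list()
    same_class <- numeric(0)
    for (ti in seq_along(schema$tasks)) {
      tk <- schema$tasks[ti]
      dt <- d[d$task == tk, , drop = FALSE]
      fr <- stats::setNames(dt$fraction, dt$class)[schema$classes[[tk]]]
      fractions[[tk]] <- fr
      same_class[tk] <- if (sg[ti] %in% names(fr)) fr[sg[ti]] else 0
    }
    out[[length(out) + 1L]] <- structure(
      list(triplet_id = tid, subgroup = sg, fractions = fractions,
           same_class = same_class, n_points = d$n_points[1]),
      class = "triplet_composition")
  }
  out
}

#' Run the synthetic end-to-end demonstration
#'
#' Generates a synthetic cohort (all represented subgroups plus evaluation
#' cohorts carrying each unrepresented value crossed with represented values
#' of the other tasks), builds a linear scorer with a configurable
#' preferred-class bias, and runs [run_pipeline()].
#'
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @param tasks synthetic tasks (see [synthetic_config()]).
#' @param n_per_subgroup represented patients per subgroup.
#' @param n_per_unrep_subgroup patients per unrepresented evaluation
#'   subgroup.
#' @param bias_shift named raw-score shift passed to
#'   [make_linear_scorer()]; the default biases the covid task toward its
#'   negative class.
#' @param operating_point `"nominal"` (default) audits the scorer at its
#'   shipped 0.5-score operating point, so a deliberate bias shows up as a
#'   preferred class; `"calibrated"` re-calibrates at the equal-error point
#'   per repeat pair, which absorbs a uniform bias.
#' @param ... further arguments to [run_pipeline()].
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L,
                     tasks = c("sex", "race", "covid", "age_group"),
                     n_per_subgroup = 50L, n_per_unrep_subgroup = 5L,
                     bias_shift = c(covid = -0.5),
                     operating_point = c("nominal", "calibrated"), ...) {
  operating_point <- match.arg(operating_point)
  config <- synthetic_config(tasks = tasks)
  schema <- synthetic_schema(config)
  cohort <- generate_cohort(config, n_per_subgroup, seed)
  unrep_sg <- unrepresented_subgroups(config)
  if (length(unrep_sg) > 0)
    cohort <- c(cohort, generate_cohort(config, n_per_unrep_subgroup,
                                        stable_hash(seed, "unrep"),
                                        subgroups = unrep_sg,
                                        id_prefix = "unr"))
  scorer <- make_linear_scorer(config,
                               bias_shift = bias_shift[names(bias_shift)
                                                       %in% tasks])
  fixed <- if (operating_point == "nominal") nominal_thresholds(schema)
           else NULL
  run_pipeline(cohort, schema, scorer, out_dir, seed = seed,
               fixed_thresholds = fixed, ...)
}

#' Enumerate evaluation subgroups with one unrepresented value
#'
#' For every unrepresented value of every task, crosses it with the
#' represented values of the remaining tasks.
#'
#' @param config a [synthetic_config()].
#' @return list of subgroup value vectors (task order).
#' @export
unrepresented_subgroups <- function(config) {
  out <- list()
  for (ti in seq_along(config$tasks)) {
    for (v in config$spec[[ti]]$unrepresented) {
      vals <- lapply(config$spec, `[[`, "classes")
      vals[[ti]] <- v
      grid <- expand.grid(vals, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(grid)))
        out[[length(out) + 1L]] <- as.character(grid[i, ])
    }
  }
  out
}

#' Render a decision-region class map for a charted plane
#'
#' Converts per-grid-point class labels into an integer class-index raster
#' over the chart's (u, v) grid, writes it as an indexed-color PNG with the
#' triplet triangle overlaid and the vertices marked, a plain-text integer
#' array (row-major, one grid row per line), and a JSON sidecar carrying the
#' in-plane vertex coordinates and the class palette.
#'
#' @param chart a [plane_chart()].
#' @param labels character vector of predicted class labels, one per chart
#'   grid point (chart grid order).
#' @param classes class levels defining the integer coding (defaults to the
#'   sorted unique labels).
#' @param png,txt,json optional output paths.
#' @return invisibly, a list with `raster` (grid x grid integer matrix,
#'   `[u, v]` indexing), `classes`, and the file paths written.
#' @export
render_plane <- function(chart, labels, classes = sort(unique(labels)),
                         png = NULL, txt = NULL, json = NULL) {
  n <- nrow(chart$coords)
  if (length(labels) != n)
    stop_decreg("expected %d labels (one per grid point), got %d", n,
                length(labels))
  idx <- match(labels, classes)
  if (anyNA(idx)) stop_decreg("labels contain values outside 'classes'")
  raster <- matrix(idx, chart$grid, chart$grid)  # [u, v]
  if (!is.null(txt)) {
    utils::write.table(t(raster), txt, row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(vertices = chart$vertices,
                              classes = as.list(classes),
                              grid = chart$grid, margin = chart$margin),
                         json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(png)) {
    palette <- grDevices::hcl.colors(max(length(classes), 2), "Zissou 1")
    rgb <- grDevices::col2rgb(palette[raster]) / 255
    img <- array(0, c(chart$grid, chart$grid, 3))
    for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, ], chart$grid, chart$grid)
    # overlay triangle edges and vertex markers
    us <- sort(unique(chart$coords[, 1])); vs <- sort(unique(chart$coords[, 2]))
    to_px <- function(xy) c(which.min(abs(us - xy[1])),
                            which.min(abs(vs - xy[2])))
    vpx <- t(apply(chart$vertices, 1, to_px))
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      steps <- max(abs(vpx[e[2], ] - vpx[e[1], ])) + 1
      line <- cbind(round(seq(vpx[e[1], 1], vpx[e[2], 1], length.out = steps)),
                    round(seq(vpx[e[1], 2], vpx[e[2], 2], length.out = steps)))
      for (r in seq_len(nrow(line)))
        img[line[r, 1], line[r, 2], ] <- 0
    }
    for (v in seq_len(3)) {
      r <- pmin(pmax(vpx[v, 1] + (-1:1), 1), chart$grid)
      c <- pmin(pmax(vpx[v, 2] + (-1:1), 1), chart$grid)
      img[r, c, 1] <- 1; img[r, c, 2:3] <- 0
    }
    EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)),
                                       colormode = "Color"),
                        png, type = "png", bits.per.sample = 8L)
  }
  invisible(list(raster = raster, classes = classes,
                 files = c(png = png, txt = txt, json = json)))
}
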