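#' Configuration of the synthetic cohort generator
#'
#' Builds a synthetic analog of a multi-attribute chest-image cohort in which
#' every attribute modulates its own small, disjoint pixel template on a flat
#' background, with additive Gaussian pixel noise. The standard configuration
#' mirrors a four-task audit design:
#' \itemize{
#'   \item `sex` (F / M) and `covid` (negative / positive): binary, all
#'     values represented;
#'   \item `race`: black / white represented, three further values
#'     (american_indian, asian, pacific_islander) unrepresented and given
#'     intermediate template coefficients;
#'   \item `age_group`: a continuous age-like latent drawn uniformly inside
#'     the group's bin; the standardized latent is the template coefficient.
#'     Groups 40 to 49 and 60 to 69 are represented; <40, 50 to 59 and 70+
#'     are unrepresented.
#' }
#' Represented binary values map to coefficients -1 and +1. Each sample is
#' `0.5 + sum_task coef * effect * template + noise`, clipped to \[0, 1\].
#' Because templates are pairwise disjoint the tasks are statistically
#' separable, which is what permits exact oracle verification of the
#' composition estimates.
#'
#' Default magnitudes place the audit in the regime where decision boundaries
#' genuinely cross triplet planes: with a 4 x 4 template, effect 0.1 and
#' pixel noise 0.2, the per-image noise on a task's matched-filter score has
#' standard deviation `noise / (effect * 4) = 0.5` in raw-score units,
#' against class centers at -1 and +1.
#'
#' @param tasks subset of `c("sex", "race", "covid", "age_group")`; order is
#'   kept.
#' @param image_size side length of the square images (default 64).
#' @param effect per-task intensity effect size delta.
#' @param noise Gaussian pixel noise standard deviation sigma.
#' @param template_size side of the square per-task template.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(tasks = c("sex", "race", "covid", "age_group"),
                             image_size = 64L, effect = 0.1, noise = 0.2,
                             template_size = 4L) {
  catalog <- list(
    sex = list(classes = c("F", "M"), coefs = c(F = -1, M = 1),
               unrepresented = character(0)),
    race = list(classes = c("black", "white"),
                coefs = c(black = -1, white = 1, american_indian = -0.25,
                          asian = 0, pacific_islander = 0.25),
                unrepresented = c("american_indian", "asian",
                                  "pacific_islander")),
    covid = list(classes = c("negative", "positive"),
                 coefs = c(negative = -1, positive = 1),
                 unrepresented = character(0)),
    age_group = list(classes = c("40 to 49", "60 to 69"),
                     unrepresented = c("<40", "50 to 59", "70+"),
                     bins = list("<40" = c(25, 40), "40 to 49" = c(40, 50),
                                 "50 to 59" = c(50, 60),
                                 "60 to 69" = c(60, 70), "70+" = c(70, 85)),
                     latent_center = 55, latent_scale = 10))
  unknown <- setdiff(tasks, names(catalog))
  if (length(unknown))
    stop_decreg("unknown synthetic task(s): %s", paste(unknown, collapse = ", "))
  p <- image_size^2
  templates <- list()
  for (ti in seq_along(tasks)) {
    r0 <- (ti - 1L) * template_size
    if (r0 + template_size > image_size)
      stop_decreg("image_size too small for %d disjoint templates",
                  length(tasks))
    rows <- r0 + seq_len(template_size)
    cols <- seq_len(template_size)
    mask <- matrix(0, image_size, image_size)
    mask[rows, cols] <- 1
    templates[[tasks[ti]]] <- mask
  }
  for (a in seq_along(tasks)) for (b in seq_len(a - 1L)) {
    if (sum(templates[[a]] * templates[[b]]) != 0)
      stop_decreg("templates of tasks '%s' and '%s' overlap",
                  tasks[a], tasks[b])
  }
  structure(list(tasks = tasks, spec = catalog[tasks],
                 templates = templates, image_size = as.integer(image_size),
                 effect = effect, noise = noise,
                 template_size = as.integer(template_size)),
            class = "synthetic_config")
}

#' Attribute schema of a synthetic configuration
#'
#' @param config a [synthetic_config()].
#' @return an [attr_schema()] whose output and represented classes are the
#'   configuration's represented values and whose positive class is the
#'   +1-coefficient class of each task.
#' @export
synthetic_schema <- function(config) {
  classes <- lapply(config$spec, `[[`, "classes")
  unrep <- lapply(config$spec, `[[`, "unrepresented")
  values <- mapply(c, classes, unrep, SIMPLIFY = FALSE)
  attr_schema(tasks = config$tasks, classes = classes,
              represented = classes,
              positive = vapply(classes, `[`, character(1), 2),
              values = values)
}

# coefficient of one attribute value; age-like tasks draw the latent
#' @noRd
value_coef <- function(spec, value, latent = NULL) {
  if (!is.null(spec$bins)) {
    (latent - spec$latent_center) / spec$latent_scale
  } else {
    unname(spec$coefs[value])
  }
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_subgroup` patients (one image each) for every requested
#' subgroup. By default all fully represented subgroups are generated;
#' passing explicit subgroup tuples (including unrepresented values) builds
#' the cohorts used in the population-shift and cross-reactivity
#' evaluations. Generation is deterministic per (seed, subgroup).
#'
#' @param config a [synthetic_config()].
#' @param n_per_subgroup patients per subgroup (at least 3 for subgroups that
#'   will feed triplet selection).
#' @param seed integer seed.
#' @param subgroups optional list of character vectors (attribute values in
#'   task order); default: the cross-product of represented values.
#' @param id_prefix prefix for patient/sample ids.
#' @return list of `decreg_sample`.
#' @export
generate_cohort <- function(config, n_per_subgroup, seed = 1L,
                            subgroups = NULL, id_prefix = "syn") {
  if (is.null(subgroups)) {
    grid <- expand.grid(lapply(config$spec, `[[`, "classes"),
                        stringsAsFactors = FALSE)
    subgroups <- lapply(seq_len(nrow(grid)), function(i)
      as.character(grid[i, ]))
  }
  p <- config$image_size^2
  tmpl <- lapply(config$templates, as.vector)
  samples <- list()
  for (sg in subgroups) {
    key <- subgroup_key(sg)
    set.seed(stable_hash(seed, "cohort", key))
    for (i in seq_len(n_per_subgroup)) {
      px <- rep(0.5, p)
      for (ti in seq_along(config$tasks)) {
        tk <- config$tasks[ti]
        spec <- config$spec[[tk]]
        latent <- if (!is.null(spec$bins)) {
          bin <- spec$bins[[sg[ti]]]
          if (is.null(bin)) stop_decreg("no age bin for value '%s'", sg[ti])
          stats::runif(1, bin[1], bin[2])
        } else NULL
        coef <- value_coef(spec, sg[ti], latent)
        if (is.na(coef))
          stop_decreg("no coefficient for value '%s' of task '%s'",
                      sg[ti], tk)
        px <- px + coef * config$effect * tmpl[[tk]]
      }
      px <- px + stats::rnorm(p, 0, config$noise)
      px[px < 0] <- 0; px[px > 1] <- 1
      attrs <- sg
      names(attrs) <- config$tasks
      id <- sprintf("%s_%s_%02d", id_prefix, gsub("[^A-Za-z0-9]", "",
                                                  key), i)
      samples[[length(samples) + 1L]] <-
        new_sample(id, id, matrix(px, config$image_size), attrs)
    }
  }
  samples
}

#' Analytic linear scorer for synthetic cohorts
#'
#' A matched-filter classifier that is exactly affine in the pixels: the raw
#' score of task `t` on image `x` is `w_t . x + b_t + bias_shift_t`, with
#' `w_t` the task template scaled so noise-free class coefficients -1 / +1
#' map to raw scores -1 / +1 and `b_t` placing the noise-free equal-error
#' threshold at raw 0. Reported scores squash the raw score to \[0, 1\]
#' through the logistic function, which is strictly increasing, so
#' probability thresholds translate one-to-one to raw thresholds via
#' [score_to_raw()]. A positive `bias_shift` inflates a task's scores and
#' manufactures a known "preferred class", the ground truth against which
#' preferred-class detection is validated.
#'
#' @param config a [synthetic_config()].
#' @param bias_shift named numeric of per-task raw-score shifts (default 0).
#' @param squash_slope slope of the logistic squashing map.
#' @return an object of class `linear_scorer` implementing
#'   [predict_scores()].
#' @export
make_linear_scorer <- function(config, bias_shift = numeric(0),
                               squash_slope = 1) {
  p <- config$image_size^2
  W <- matrix(0, p, length(config$tasks),
              dimnames = list(NULL, config$tasks))
  b <- stats::setNames(numeric(length(config$tasks)), config$tasks)
  for (tk in config$tasks) {
    tv <- as.vector(config$templates[[tk]])
    m <- sum(tv)
    if (m == 0) stop_decreg("task '%s' has an empty template", tk)
    W[, tk] <- tv / (config$effect * m)
    b[tk] <- -0.5 / config$effect
  }
  shift <- stats::setNames(numeric(length(config$tasks)), config$tasks)
  shift[names(bias_shift)] <- bias_shift
  structure(list(W = W, b = b, bias_shift = shift,
                 squash_slope = squash_slope, tasks = config$tasks),
            class = "linear_scorer")
}

#' Raw (pre-squashing) scores of a linear scorer
#'
#' @param scorer a `linear_scorer`.
#' @param pixels as in [predict_scores()].
#' @return n x n_tasks matrix of raw affine scores.
#' @export
raw_scores <- function(scorer, pixels) {
  X <- as_pixel_matrix(pixels)
  sweep(X %*% scorer$W, 2, scorer$b + scorer$bias_shift, `+`)
}

#' @export
predict_scores.linear_scorer <- function(adapter, pixels, ...) {
  stats::plogis(adapter$squash_slope * raw_scores(adapter, pixels))
}

#' Translate between probability and raw-score thresholds
#'
#' @param scorer a `linear_scorer`.
#' @param score probability-scale threshold in (0, 1).
#' @return the equivalent raw-score threshold.
#' @export
score_to_raw <- function(scorer, score) {
  stats::qlogis(score) / scorer$squash_slope
}

#' @rdname score_to_raw
#' @param raw raw-score threshold.
#' @export
raw_to_score <- function(scorer, raw) {
  stats::plogis(scorer$squash_slope * raw)
}

#' Exact decision-region fraction for an affine scorer
#'
#' For an affine scorer, the raw score on the plane of a triplet is itself
#' affine in the barycentric coordinates: `s(a, b) = s0 (1 - a - b) + s1 a +
#' s2 b` on the reference triangle `a, b >= 0, a + b <= 1`. The fraction of
#' the triangle on which `s >= t_raw` is therefore the area of the triangle
#' clipped by one half-plane, computed exactly by polygon clipping and the
#' shoelace formula. This is the quantity the barycentric-lattice composition
#' estimates, and serves as its oracle.
#'
#' @param vertex_scores numeric length-3: raw scores at the triplet members
#'   (s0, s1, s2).
#' @param t_raw raw-score threshold.
#' @return list with `fraction` (exact area fraction with score >= t_raw)
#'   and `vertex_scores`.
#' @export
oracle_composition <- function(vertex_scores, t_raw) {
  stopifnot(length(vertex_scores) == 3)
  s <- vertex_scores
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  f <- function(ab) s[1] * (1 - ab[1] - ab[2]) + s[2] * ab[1] + s[3] * ab[2]
  poly <- clip_halfplane(tri, f, t_raw)
  area <- if (is.null(poly) || nrow(poly) < 3) 0 else shoelace(poly)
  list(fraction = area / 0.5, vertex_scores = s)
}

#' @rdname oracle_composition
#' @param scorer a `linear_scorer`.
#' @param triplet a `triplet`.
#' @param task task name.
#' @export
oracle_composition_triplet <- function(scorer, triplet, task, t_raw) {
  rs <- raw_scores(scorer, lapply(triplet$members, `[[`, "pixels"))
  oracle_composition(rs[, task], t_raw)
}

# Sutherland-Hodgman clip of polygon `poly` by the half-plane f(v) >= t
#' @noRd
clip_halfplane <- function(poly, f, t) {
  vals <- apply(poly, 1, f) - t
  n <- nrow(poly)
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- vals[i]; vj <- vals[j]
    if (vi >= 0) out[[length(out) + 1L]] <- poly[i, ]
    if ((vi >= 0) != (vj >= 0)) {
      w <- vi / (vi - vj)
      out[[length(out) + 1L]] <- poly[i, ] + w * (poly[j, ] - poly[i, ])
    }
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

#' @noRd
shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
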