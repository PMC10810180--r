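test_that("triplet composition counts class fractions exactly", {
  sch <- tiny_schema()
  tp <- fixture_triplet(sch, attrs = c(sex = "F", covid = "positive"))
  n <- 351
  preds <- matrix("F", n, 2, dimnames = list(NULL, c("sex", "covid")))
  preds[, "covid"] <- c(rep("positive", 117), rep("negative", n - 117))
  cc <- triplet_composition(preds, tp, sch)
  expect_identical(unname(cc$fractions$sex), c(1, 0))
  expect_identical(unname(cc$fractions$covid["positive"]), 117 / n)
  expect_identical(unname(cc$same_class["sex"]), 1)       # subgroup F
  expect_identical(unname(cc$same_class["covid"]), 117 / n)
  # conservation is exact, not approximate
  expect_true(all(vapply(cc$fractions, sum, numeric(1)) == 1))

  expect_error(triplet_composition(matrix("alien", n, 2,
                                          dimnames = list(NULL, sch$tasks)),
                                   tp, sch), "outside the output classes")
})

test_that("a subgroup value outside the output classes has same-class fraction 0", {
  sch <- study_schema()
  tp <- fixture_triplet(sch, attrs = c(sex = "F", race = "asian",
                                       covid = "negative",
                                       age_group = "60 to 69"))
  preds <- matrix(NA_character_, 10, 4, dimnames = list(NULL, sch$tasks))
  preds[, "sex"] <- "F"; preds[, "race"] <- "white"
  preds[, "covid"] <- "negative"; preds[, "age_group"] <- "60 to 69"
  cc <- triplet_composition(preds, tp, sch)
  expect_identical(unname(cc$same_class["race"]), 0)
  expect_identical(unname(cc$same_class["covid"]), 1)
})

test_that("subgroup aggregation reports mean and sample standard deviation", {
  sch <- tiny_schema()
  ccs <- lapply(c(0.2, 0.4, 0.6), function(f)
    fake_composition(sch, f, n_points = 10))
  agg <- aggregate_subgroup(ccs, sch)
  row <- agg$stats[agg$stats$task == "sex" & agg$stats$class == "F", ]
  expect_equal(row$mean, 0.4)
  expect_equal(row$sd, 0.2)
  expect_equal(agg$n_triplets, 3L)
  expect_false(agg$degenerate)
  # per-task means sum to 1 within 1e-12
  sums <- tapply(agg$stats$mean, agg$stats$task, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  single <- aggregate_subgroup(ccs[1], sch)
  expect_true(single$degenerate)
  expect_equal(single$stats$sd, rep(0, 4))

  other <- fake_composition(sch, 0.5)
  other$subgroup <- c("M", "positive")
  expect_error(aggregate_subgroup(c(ccs, list(other)), sch), "mix")
})

test_that("preferred class is the argmax of equally weighted subgroup shares", {
  sch <- tiny_schema()
  mk_agg <- function(attrs, sex_frac_F) {
    ccs <- lapply(sex_frac_F, function(f) {
      cc <- fake_composition(sch, f, n_points = 100)
      cc$subgroup <- unname(attrs)
      cc$same_class <- c(sex = if (attrs[1] == "F") f else 1 - f,
                         covid = 0.5)
      cc
    })
    aggregate_subgroup(ccs, sch)
  }
  # symmetric model: F-subgroup and M-subgroup mirror each other
  aggs <- list(mk_agg(c(sex = "F", covid = "negative"), c(0.5, 0.5)),
               mk_agg(c(sex = "M", covid = "negative"), c(0.5, 0.5)),
               mk_agg(c(sex = "F", covid = "positive"), c(0.5, 0.5)),
               mk_agg(c(sex = "M", covid = "positive"), c(0.5, 0.5)))
  rep_sym <- preferred_class(aggs, sch)
  expect_equal(unname(rep_sym$sex$gap), 0)
  expect_equal(sum(rep_sym$sex$shares), 1)

  # inflate the F share everywhere: F becomes preferred with the expected gap
  aggs2 <- list(mk_agg(c(sex = "F", covid = "negative"), c(0.9, 0.8)),
                mk_agg(c(sex = "M", covid = "negative"), c(0.7, 0.6)),
                mk_agg(c(sex = "F", covid = "positive"), c(0.85, 0.95)),
                mk_agg(c(sex = "M", covid = "positive"), c(0.6, 0.7)))
  rep_b <- preferred_class(aggs2, sch)
  expect_equal(rep_b$sex$preferred, "F")
  share_F <- mean(c(0.85, 0.65, 0.9, 0.65))
  expect_equal(unname(rep_b$sex$shares["F"]), share_F)
  expect_equal(unname(rep_b$sex$gap), share_F - (1 - share_F))
  # same-class summary: F subgroups report their F fraction, M theirs
  expect_equal(unname(rep_b$sex$same_class_by_class["F"]),
               mean(c(0.85, 0.9)))
  expect_equal(unname(rep_b$sex$same_class_by_class["M"]),
               mean(c(1 - 0.65, 1 - 0.65)))

  # a class no subgroup carries makes the summary undefined
  expect_error(preferred_class(aggs2[c(1, 3)], sch), "no subgroup")
})

test_that("sensitivity std follows the finite-population subset-mean law", {
  sch <- tiny_schema()
  set.seed(314)
  N <- 400
  fr <- pmin(pmax(stats::rnorm(N, 0.8, 0.1), 0), 1)
  pool <- lapply(fr, function(f) fake_composition(sch, f))
  counts <- c(10, 25, 50, 100, 200, N)
  curve <- triplet_count_sensitivity(pool, "sex", counts,
                                     n_resamples = 200, seed = 11)
  vals <- vapply(pool, function(cc) cc$same_class["sex"], numeric(1))
  S2 <- stats::var(vals)
  for (i in seq_along(counts)) {
    T <- counts[i]
    expected_sd <- sqrt(S2 / T * (N - T) / (N - 1) * (N / N))
    if (T < N) {
      expect_lt(abs(curve$std[i] - expected_sd), 0.25 * expected_sd)
    }
  }
  expect_identical(curve$std[counts == N], 0)  # exhaustive subset
  expect_lte(curve$std[counts == 100], curve$std[counts == 10])
  # the mean is stable in T (unbiasedness of the subset mean)
  expect_lt(max(abs(curve$mean - mean(vals))), 0.05 * mean(vals))

  expect_error(triplet_count_sensitivity(pool, "sex", c(10, 500), 10, 1),
               "exceeds pool size")
  expect_error(triplet_count_sensitivity(pool, "sex", 10, 1, 1), ">= 2")
})

test_that("chart composition tallies grid points inside or beyond the triangle", {
  cfg <- synthetic_config(tasks = "sex")
  sch <- synthetic_schema(cfg)
  tp <- scored_triplet(cfg, sch, c(-1, 1, 0.5))
  ch <- plane_chart(tp, grid = 30, margin = 0.3)
  scorer <- make_linear_scorer(cfg)
  labels <- ifelse(raw_scores(scorer, ch$pixels)[, "sex"] >= 0, "M", "F")
  tri <- chart_composition(ch, labels, c("F", "M"))
  expect_equal(sum(tri), 1)
  expect_equal(unname(tri["M"]),
               sum(labels[ch$inside] == "M") / sum(ch$inside))
  full <- chart_composition(ch, labels, c("F", "M"), triangle_only = FALSE)
  expect_equal(unname(full["M"]), mean(labels == "M"))
  # the triangle tally approximates the barycentric-lattice composition
  th <- nominal_thresholds(sch)
  cc <- compose_triplet(tp, scorer, th, sch, barycentric_lattice(25))
  expect_lt(abs(tri["M"] - cc$fractions$sex["M"]), 0.15)
  expect_error(chart_composition(ch, labels[-1], c("F", "M")), "labels")
})

test_that("composition is bit-identical under member relabeling through the full chain", {
  cfg <- synthetic_config(tasks = c("sex", "covid"), image_size = 16,
                          template_size = 4)
  sch <- synthetic_schema(cfg)
  scorer <- make_linear_scorer(cfg)
  th <- nominal_thresholds(sch)
  lat <- barycentric_lattice(12)
  coh <- generate_cohort(cfg, 3, seed = 6,
                         subgroups = list(c("F", "positive")))
  tp <- new_triplet(coh, sch)
  base <- compose_triplet(tp, scorer, th, sch, lat)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))) {
    pc <- compose_triplet(new_triplet(coh[perm], sch), scorer, th, sch, lat)
    expect_identical(pc$fractions, base$fractions)
    expect_identical(pc$same_class, base$same_class)
  }
})
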