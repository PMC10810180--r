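test_that("categorization distinguishes shift from cross-reactivity per task", {
  sch <- study_schema()
  # a 70+ female with otherwise represented attributes
  s <- fixture_sample("x", c(sex = "F", race = "white", covid = "negative",
                             age_group = "70+"))
  expect_equal(categorize(s, "sex", sch)$category, "population_shift")
  expect_equal(categorize(s, "age_group", sch)$category, "cross_reactivity")
  expect_equal(categorize(s, "sex", sch)$shifted_attributes, "age_group")

  rep_s <- fixture_sample("r", c(sex = "M", race = "black",
                                 covid = "positive",
                                 age_group = "40 to 49"))
  for (tk in sch$tasks)
    expect_equal(categorize(rep_s, tk, sch)$category, "represented")

  bad <- fixture_sample("b", c(sex = "F", race = "white", covid = "maybe",
                               age_group = "70+"))
  expect_error(categorize(bad, "sex", sch), "maybe")
})

test_that("the full attribute cross-product reproduces the evaluation grid", {
  sch <- study_schema()
  grid <- expand.grid(sch$values, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    attrs <- vapply(sch$tasks, function(tk) grid[i, tk], character(1))
    s <- fixture_sample("g", attrs)
    unrep <- vapply(sch$tasks, function(tk)
      !(attrs[tk] %in% sch$represented[[tk]]), logical(1))
    for (tk in sch$tasks) {
      got <- categorize(s, tk, sch)$category
      # independent reading of the taxonomy: a task whose every value is
      # represented (sex, covid) can only see population shift; race/age
      # are cross-reactive exactly when their own value is unrepresented
      expected <- if (unrep[tk]) "cross_reactivity"
                  else if (any(unrep)) "population_shift"
                  else "represented"
      if (tk %in% c("sex", "covid")) expect_false(got == "cross_reactivity")
      expect_equal(got, expected)
    }
  }
})

test_that("population shift rates are per-true-class correct percentages", {
  sch <- study_schema()
  # four covid-negative + two covid-positive patients, all shifted on race
  mk <- function(i, covid) fixture_sample(paste0("s", i),
    c(sex = "F", race = "asian", covid = covid, age_group = "60 to 69"))
  samples <- c(lapply(1:4, mk, covid = "negative"),
               lapply(5:6, mk, covid = "positive"))
  preds <- c("negative", "negative", "negative", "positive",  # 3/4 correct
             "positive", "negative")                           # 1/2 correct
  rep <- population_shift_rates(preds, samples, "covid", sch)
  expect_equal(rep$percent_correct[rep$class == "negative"], 75)
  expect_equal(rep$percent_correct[rep$class == "positive"], 50)
  expect_equal(rep$count, c(4L, 2L))
  expect_equal(nrow(rep), length(sch$classes$covid))

  # all correct -> 100 per class; represented samples are excluded
  rep2 <- population_shift_rates(
    c("negative", "negative"),
    list(mk(7, "negative"),
         fixture_sample("r", c(sex = "F", race = "white",
                               covid = "negative",
                               age_group = "60 to 69"))),
    "covid", sch)
  expect_equal(rep2$percent_correct[rep2$class == "negative"], 100)
  expect_equal(rep2$count, c(1L, 0L))
  expect_true(is.na(rep2$percent_correct[rep2$class == "positive"]))
})

test_that("cross-reactivity rates tally assignments per unrepresented group", {
  sch <- study_schema()
  mk <- function(i, age) fixture_sample(paste0("c", i),
    c(sex = "M", race = "black", covid = "negative", age_group = age))
  samples <- c(lapply(1:4, mk, age = "70+"), lapply(5:5, mk, age = "<40"))
  preds <- c("60 to 69", "60 to 69", "40 to 49", "60 to 69", "40 to 49")
  rep <- cross_reactivity_rates(preds, samples, "age_group", sch)
  g70 <- rep[rep$group == "70+", ]
  expect_equal(g70$percent[g70$class == "60 to 69"], 75)
  expect_equal(g70$percent[g70$class == "40 to 49"], 25)
  expect_equal(sum(g70$percent), 100)
  g40 <- rep[rep$group == "<40", ]  # single sample: all mass on one class
  expect_equal(g40$percent[g40$class == "40 to 49"], 100)

  # brute-force tally oracle on random predictions
  set.seed(99)
  rnd <- sample(sch$classes$age_group, 5, replace = TRUE)
  rep3 <- cross_reactivity_rates(rnd, samples, "age_group", sch)
  for (g in c("70+", "<40")) {
    truth <- vapply(samples, function(s) s$attributes[["age_group"]],
                    character(1))
    for (cl in sch$classes$age_group) {
      expect_equal(rep3$percent[rep3$group == g & rep3$class == cl],
                   100 * sum(rnd[truth == g] == cl) / sum(truth == g))
    }
  }
  # a task with no unrepresented values has an empty report
  expect_equal(nrow(cross_reactivity_rates(rep(c("F"), 5), samples, "sex",
                                           sch)), 0L)
})

test_that("preferred-class agreement compares shift and cross margins", {
  sch <- study_schema()
  preferred <- structure(list(covid = list(preferred = "negative"),
                              race = list(preferred = "white")),
                         class = "preferred_class_report")
  shift <- structure(data.frame(task = "covid",
                                class = c("negative", "positive"),
                                percent_correct = c(75.7, 57.2),
                                n_correct = c(76, 57), count = c(100, 100)),
                     class = c("shift_report", "data.frame"))
  res <- preferred_class_agreement(shift, NULL, preferred, "covid")
  expect_true(res$shift_ok)
  expect_true(res$agreement)
  expect_equal(res$shift_margin, 75.7 - 57.2)
  expect_true(is.na(res$cross_ok))

  cross <- structure(data.frame(task = "race",
                                group = rep(c("asian", "70s"), each = 2),
                                class = rep(c("black", "white"), 2),
                                percent = c(30, 70, 26, 74),
                                count = c(10, 10, 5, 5)),
                     class = c("cross_reactivity_report", "data.frame"))
  res2 <- preferred_class_agreement(NULL, cross, preferred, "race")
  expect_true(res2$cross_ok)
  expect_true(res2$agreement)
  # pooled percentage: weighted by group counts
  expect_equal(res2$cross_margin,
               (70 * 10 + 74 * 5) / 15 - (30 * 10 + 26 * 5) / 15)

  # symmetric behavior within the margin is indeterminate, not false
  shift_sym <- shift; shift_sym$percent_correct <- c(70.2, 70.0)
  res3 <- preferred_class_agreement(shift_sym, NULL, preferred, "covid")
  expect_true(is.na(res3$agreement))

  # no cohort at all: indeterminate flag rather than an error
  res4 <- preferred_class_agreement(NULL, NULL, preferred, "covid")
  expect_true(is.na(res4$agreement))
})
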