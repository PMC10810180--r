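test_that("manifest loading drops rows with missing attributes and reports them", {
  sch <- tiny_schema()
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "images"))
  for (i in 1:4)
    save_image(matrix(i / 10, 8, 8), file.path(dir, "images",
                                               paste0("im", i, ".png")))
  df <- data.frame(sample_id = paste0("s", 1:4),
                   patient_id = paste0("p", 1:4),
                   image_path = file.path("images", paste0("im", 1:4, ".png")),
                   sex = c("F", "M", "", "F"),
                   covid = c("negative", "positive", "negative", "positive"))
  utils::write.csv(df, file.path(dir, "manifest.csv"), row.names = FALSE)
  res <- load_manifest(file.path(dir, "manifest.csv"), sch)
  expect_length(res$samples, 3)
  expect_equal(res$report$dropped, 1)
  expect_setequal(vapply(res$samples, `[[`, character(1), "sample_id"),
                  c("s1", "s2", "s4"))

  # header-only manifest
  utils::write.csv(df[0, ], file.path(dir, "empty.csv"), row.names = FALSE)
  res0 <- load_manifest(file.path(dir, "empty.csv"), sch)
  expect_length(res0$samples, 0)
  expect_equal(res0$report$dropped, 0)
})

test_that("8-bit images are rescaled to [0, 1] and load errors are collected", {
  sch <- tiny_schema()
  dir <- withr::local_tempdir()
  px <- matrix(0, 8, 8); px[1, 1] <- 1  # full-scale 8-bit pixel
  save_image(px, file.path(dir, "a.png"))
  df <- data.frame(sample_id = c("a", "b"), patient_id = c("pa", "pb"),
                   image_path = c("a.png", "missing.png"),
                   sex = "F", covid = "negative")
  utils::write.csv(df, file.path(dir, "m.csv"), row.names = FALSE)
  res <- load_manifest(file.path(dir, "m.csv"), sch)
  expect_equal(max(res$samples[[1]]$pixels), 1.0)
  expect_gte(min(res$samples[[1]]$pixels), 0)
  expect_length(res$samples, 1)
  expect_named(res$report$failed, "b")
})

test_that("manifest schema violations are hard errors", {
  sch <- tiny_schema()
  dir <- withr::local_tempdir()
  save_image(matrix(0.5, 8, 8), file.path(dir, "a.png"))
  base <- data.frame(sample_id = c("a", "a"), patient_id = c("p1", "p2"),
                     image_path = "a.png", sex = "F", covid = "negative")
  utils::write.csv(base, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(dir, "dup.csv"), sch),
               "duplicate sample_id")
  utils::write.csv(base[1, c("sample_id", "patient_id", "sex", "covid")],
                   file.path(dir, "nocol.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(dir, "nocol.csv"), sch),
               "image_path")
  two <- base; two$sample_id <- c("a", "b"); two$patient_id <- "p1"
  utils::write.csv(two, file.path(dir, "dup2.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(dir, "dup2.csv"), sch),
               "duplicate patient_id")
  expect_length(load_manifest(file.path(dir, "dup2.csv"), sch,
                              allow_multiple_per_patient = TRUE)$samples, 2)
})

test_that("preprocessing resizes to the short side and center-crops square", {
  out <- preprocess_image(matrix(stats::runif(480 * 640), 480, 640))
  expect_equal(dim(out), c(320L, 320L))
  expect_true(all(out >= 0 & out <= 1))

  id <- matrix(stats::runif(320 * 320), 320, 320)
  expect_identical(preprocess_image(id), id)

  # bilinear resampling preserves constant images
  expect_equal(preprocess_image(matrix(0.37, 640, 640)),
               matrix(0.37, 320, 320), tolerance = 1e-12)

  # portrait orientation takes the same path
  expect_equal(dim(preprocess_image(matrix(0.1, 800, 400))), c(320L, 320L))

  expect_error(preprocess_image(array(0, c(4, 4, 3))), "2-D")
  expect_error(preprocess_image(matrix(0, 400, 400), short_side = 100,
                                crop = 200), "exceeds")
})

test_that("subgroup assignment follows schema task order", {
  sch <- study_schema()
  s <- fixture_sample("x", c(sex = "F", race = "black", covid = "negative",
                             age_group = "40 to 49"))
  expect_equal(assign_subgroup(s, sch),
               c("F", "black", "negative", "40 to 49"))

  one <- attr_schema("sex", list(sex = c("F", "M")), list(sex = c("F", "M")),
                     c(sex = "M"))
  expect_equal(assign_subgroup(s, one), "F")

  # permuting schema task order permutes the tuple identically
  set.seed(42)
  for (i in 1:10) {
    ord <- sample(4)
    perm <- attr_schema(sch$tasks[ord], sch$classes[ord],
                        sch$represented[ord], sch$positive[ord],
                        sch$values[ord])
    expect_equal(assign_subgroup(s, perm), assign_subgroup(s, sch)[ord])
  }
})

test_that("represented split requires every attribute value to be represented", {
  sch <- study_schema()
  rep1 <- fixture_sample("r1", c(sex = "F", race = "white",
                                 covid = "negative", age_group = "60 to 69"))
  unr1 <- fixture_sample("u1", c(sex = "F", race = "asian",
                                 covid = "negative", age_group = "60 to 69"))
  unr2 <- fixture_sample("u2", c(sex = "M", race = "black",
                                 covid = "positive", age_group = "70+"))
  res <- split_represented(list(rep1, unr1, unr2), sch)
  expect_equal(vapply(res$represented, `[[`, character(1), "sample_id"), "r1")
  expect_equal(vapply(res$unrepresented, `[[`, character(1), "sample_id"),
               c("u1", "u2"))

  # partition property: union preserves input, disjoint, order-preserving
  set.seed(7)
  cohort <- c(represented_cohort(sch, 2),
              list(unr1, unr2))[sample(34)]
  res <- split_represented(cohort, sch)
  expect_equal(length(res$represented) + length(res$unrepresented),
               length(cohort))
  ids <- vapply(cohort, `[[`, character(1), "sample_id")
  got <- c(vapply(res$represented, `[[`, character(1), "sample_id"),
           vapply(res$unrepresented, `[[`, character(1), "sample_id"))
  expect_setequal(got, ids)
  # order preserved within each half
  rep_ids <- vapply(res$represented, `[[`, character(1), "sample_id")
  expect_equal(rep_ids, ids[ids %in% rep_ids])

  bad <- fixture_sample("z", c(sex = "F", race = "martian",
                               covid = "negative", age_group = "60 to 69"))
  expect_error(split_represented(list(bad), sch), "martian")
})

test_that("partitioning hits 50/10/20/20 and yields 25 distinct training sets", {
  sch <- tiny_schema()
  cohort <- subgroup_samples(100, c(sex = "F", covid = "negative"), sch,
                             prefix = "p")
  plan <- make_partitions(cohort, sch, seed = 5)
  one <- plan[plan$eval_repeat == 1 & plan$train_repeat == 1, ]
  expect_equal(as.vector(table(one$partition)[c("training", "validation1",
                                                "validation2", "test")]),
               c(50L, 10L, 20L, 20L))

  train_sets <- vapply(1:5, function(er) vapply(1:5, function(tr) {
    sel <- plan$eval_repeat == er & plan$train_repeat == tr &
      plan$partition == "training"
    paste(sort(plan$patient_id[sel]), collapse = ",")
  }, character(1)), character(5))
  expect_equal(length(unique(as.vector(train_sets))), 25L)

  # determinism: identical plan on reseed
  expect_identical(as.data.frame(plan),
                   as.data.frame(make_partitions(cohort, sch, seed = 5)))
})

test_that("partitions are patient-disjoint and stratified within one patient", {
  sch <- tiny_schema()
  cohort <- c(subgroup_samples(25, c(sex = "F", covid = "negative"), sch,
                               prefix = "a"),
              subgroup_samples(25, c(sex = "M", covid = "positive"), sch,
                               prefix = "b"))
  plan <- make_partitions(cohort, sch, seed = 2)
  for (er in 1:5) for (tr in 1:5) {
    sel <- plan[plan$eval_repeat == er & plan$train_repeat == tr, ]
    expect_false(anyDuplicated(sel$patient_id) > 0)
    expect_equal(nrow(sel), 50L)
    for (sg in unique(sel$subgroup)) {
      counts <- table(factor(sel$partition[sel$subgroup == sg],
                             levels = c("training", "validation1",
                                        "validation2", "test")))
      expect_true(all(abs(counts - 25 * c(0.5, 0.1, 0.2, 0.2)) <= 1))
    }
  }
  # validation2/test depend only on the eval repeat
  v2 <- function(er, tr) sort(plan$patient_id[plan$eval_repeat == er &
    plan$train_repeat == tr & plan$partition == "validation2"])
  expect_identical(v2(2, 1), v2(2, 5))

  small <- subgroup_samples(9, c(sex = "F", covid = "positive"), sch,
                            prefix = "t")
  expect_error(make_partitions(small, sch, seed = 1), "at least 3")
})
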