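#' Patient-stratified repeated data partitions
#'
#' Splits the represented cohort into training / validation1 / validation2 /
#' test partitions, stratified by subgroup so that every subgroup is equally
#' represented in every partition (within the rounding limit of one patient).
#' The split is repeated at two levels, mirroring a nested
#' development/evaluation design:
#' \itemize{
#'   \item per evaluation repeat, each subgroup's patients are shuffled and
#'     divided into a development pool (training + validation1), validation2
#'     (decision-region generation and shift evaluation) and test;
#'   \item per training repeat, the development pool alone is re-divided into
#'     training and validation1 (threshold calibration / model selection).
#' }
#' With the default five repeats at each level this yields 25 distinct
#' (training, validation1) assignments sharing 5 validation2/test splits.
#' Counts are apportioned by largest remainder, and every shuffle uses an RNG
#' seed derived by a stable hash of (seed, repeat indices, subgroup), so
#' adding a subgroup never changes another subgroup's split.
#'
#' @param represented list of `decreg_sample` (use [split_represented()]
#'   first).
#' @param schema an [attr_schema()].
#' @param fractions length-4 numeric: target fractions for training,
#'   validation1, validation2 and test; defaults to 50/10/20/20.
#' @param n_eval_repeats,n_train_repeats repeat counts at the two levels.
#' @param seed master integer seed.
#' @return a `partition_plan`: data frame with columns `eval_repeat`,
#'   `train_repeat`, `patient_id`, `subgroup`, `partition`, carrying the
#'   fractions and seed as attributes.
#' @export
make_partitions <- function(represented, schema,
                            fractions = c(0.5, 0.1, 0.2, 0.2),
                            n_eval_repeats = 5L, n_train_repeats = 5L,
                            seed = 1L) {
  stopifnot(length(fractions) == 4, all(fractions > 0))
  fractions <- fractions / sum(fractions)
  by_sg <- group_by_subgroup(represented, schema)
  patients <- lapply(by_sg, function(ss)
    sort(unique(vapply(ss, function(s) s$patient_id, character(1)))))

  rows <- list()
  for (er in seq_len(n_eval_repeats)) {
    for (key in names(patients)) {
      pts <- patients[[key]]
      n <- length(pts)
      # development pool (training + validation1) vs validation2 vs test
      counts <- largest_remainder(n, c(fractions[1] + fractions[2],
                                       fractions[3], fractions[4]))
      if (counts[2] < 3)
        stop_decreg(paste0("subgroup '%s' would receive %d validation2 ",
                           "patient(s); at least 3 are required to form ",
                           "triplets"), key, counts[2])
      rng <- stable_hash(seed, "eval", er, key)
      set.seed(rng)
      shuffled <- sample(pts)
      dev  <- shuffled[seq_len(counts[1])]
      val2 <- shuffled[counts[1] + seq_len(counts[2])]
      test <- shuffled[counts[1] + counts[2] + seq_len(counts[3])]
      for (tr in seq_len(n_train_repeats)) {
        set.seed(stable_hash(seed, "train", er, tr, key))
        dshuf <- sample(dev)
        dcounts <- largest_remainder(length(dev), fractions[1:2])
        train <- dshuf[seq_len(dcounts[1])]
        val1  <- dshuf[dcounts[1] + seq_len(dcounts[2])]
        rows[[length(rows) + 1L]] <- data.frame(
          eval_repeat = er, train_repeat = tr,
          patient_id = c(train, val1, val2, test),
          subgroup = key,
          partition = rep(c("training", "validation1", "validation2", "test"),
                          c(length(train), length(val1), length(val2),
                            length(test))),
          stringsAsFactors = FALSE)
      }
    }
  }
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  structure(plan, fractions = fractions, seed = seed,
            class = c("partition_plan", "data.frame"))
}

#' Extract the samples of one partition
#'
#' @param plan a `partition_plan` from [make_partitions()].
#' @param samples list of `decreg_sample`.
#' @param partition one of `"training"`, `"validation1"`, `"validation2"`,
#'   `"test"`.
#' @param eval_repeat,train_repeat repeat indices. `validation2` and `test`
#'   membership depends only on `eval_repeat`.
#' @return list of samples whose patient falls in the requested partition.
#' @export
partition_samples <- function(plan, samples, partition, eval_repeat = 1L,
                              train_repeat = 1L) {
  sel <- plan$eval_repeat == eval_repeat & plan$train_repeat == train_repeat &
    plan$partition == partition
  ids <- plan$patient_id[sel]
  samples[vapply(samples, function(s) s$patient_id %in% ids, logical(1))]
}

#' Export a partition plan as CSV
#'
#' @param plan a `partition_plan`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan)[, c("eval_repeat", "train_repeat",
                                           "patient_id", "partition")],
                   path, row.names = FALSE)
  invisible(path)
}
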