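#' Load a sample manifest
#'
#' Reads a cohort manifest CSV (columns `sample_id`, `patient_id`,
#' `image_path`, plus one column per schema task) and loads every referenced
#' image. Rows with any missing attribute value are dropped — patients with
#' incomplete label information cannot be evaluated on all tasks — and counted
#' in the load report. Unreadable images are collected as per-row errors
#' without aborting the run; a duplicate `sample_id` (or, by default, a
#' duplicate `patient_id`) aborts, because the patient is the unit of
#' partitioning and each patient is expected to contribute exactly one image.
#'
#' @param path manifest CSV path (UTF-8, header required).
#' @param schema an [attr_schema()]; one manifest column per task.
#' @param image_root directory against which relative `image_path` entries
#'   are resolved.
#' @param preprocess if `TRUE`, apply [preprocess_image()] with `short_side`
#'   and `crop`.
#' @param short_side,crop passed to [preprocess_image()].
#' @param allow_multiple_per_patient allow several samples per patient
#'   (partitioning still operates on patients).
#' @return list with `samples` (list of `decreg_sample`) and `report`
#'   (`dropped` = rows with missing attributes, `failed` = named image-load
#'   error messages, `loaded` = number of samples returned).
#' @export
load_manifest <- function(path, schema, image_root = dirname(path),
                          preprocess = FALSE, short_side = 320L, crop = 320L,
                          allow_multiple_per_patient = FALSE) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "patient_id", "image_path", schema$tasks)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_decreg("manifest is missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_decreg("duplicate sample_id in manifest: %s",
                df$sample_id[duplicated(df$sample_id)][1])
  if (!allow_multiple_per_patient && anyDuplicated(df$patient_id))
    stop_decreg(paste0("duplicate patient_id '%s' in manifest; pass ",
                       "allow_multiple_per_patient = TRUE to keep several ",
                       "images per patient"),
                df$patient_id[duplicated(df$patient_id)][1])

  attr_cols <- df[, schema$tasks, drop = FALSE]
  complete <- !Reduce(`|`, lapply(attr_cols, function(x) is.na(x) | !nzchar(x)))
  dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]

  samples <- list()
  failed <- character(0)
  for (i in seq_len(nrow(df))) {
    p <- df$image_path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(image_root, p)
    px <- tryCatch(load_image(p), error = function(e) e)
    if (inherits(px, "error")) {
      failed[df$sample_id[i]] <- conditionMessage(px)
      next
    }
    if (preprocess) px <- preprocess_image(px, short_side, crop)
    attrs <- vapply(schema$tasks, function(tk) df[[tk]][i], character(1))
    samples[[length(samples) + 1L]] <-
      new_sample(df$sample_id[i], df$patient_id[i], px, attrs)
  }
  shapes <- unique(t(vapply(samples, function(s) dim(s$pixels), integer(2))))
  if (nrow(shapes) > 1)
    warning("samples do not share one image shape; run preprocess_image() ",
            "before triplet analysis", call. = FALSE)
  list(samples = samples,
       report = list(dropped = dropped, failed = failed,
                     loaded = length(samples)))
}

#' Write a cohort manifest and its images to disk
#'
#' Inverse of [load_manifest()]: writes one 8-bit PNG per sample under
#' `dir/images/` and a manifest CSV referencing them. Used by the synthetic
#' `simulate` entry point to materialize a cohort for the file-based pipeline.
#'
#' @param samples list of `decreg_sample`.
#' @param schema an [attr_schema()].
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_manifest <- function(samples, schema, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    rel <- file.path("images", paste0(s$sample_id, ".png"))
    save_image(s$pixels, file.path(dir, rel))
    c(sample_id = s$sample_id, patient_id = s$patient_id, image_path = rel,
      s$attributes[schema$tasks])
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  out <- file.path(dir, "manifest.csv")
  utils::write.csv(df, out, row.names = FALSE)
  invisible(out)
}
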