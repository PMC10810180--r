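# Shared fixtures: small schemas, samples and triplets built in code.

# two binary tasks, everything represented
tiny_schema <- function() {
  attr_schema(
    tasks = c("sex", "covid"),
    classes = list(sex = c("F", "M"), covid = c("negative", "positive")),
    represented = list(sex = c("F", "M"),
                       covid = c("negative", "positive")),
    positive = c(sex = "M", covid = "positive"))
}

# the four-task audit schema with unrepresented race and age values
study_schema <- function() synthetic_schema(synthetic_config())

fixture_sample <- function(id, attrs, pixels = matrix(0.5, 6, 6),
                           patient = id) {
  new_sample(id, patient, pixels, attrs)
}

# n same-subgroup samples with random pixels, one patient each
subgroup_samples <- function(n, attrs, schema, npix = 6, seed = 1,
                             prefix = "s") {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    fixture_sample(sprintf("%s%02d", prefix, i), attrs,
                   matrix(runif(npix * npix), npix, npix)))
}

fixture_triplet <- function(schema, attrs = NULL, npix = 6, seed = 1) {
  if (is.null(attrs)) {
    attrs <- vapply(schema$tasks, function(tk) schema$classes[[tk]][1],
                    character(1))
  }
  new_triplet(subgroup_samples(3, attrs, schema, npix, seed), schema)
}

# a cohort covering every represented subgroup of a schema
represented_cohort <- function(schema, n_per_subgroup, npix = 6, seed = 1) {
  grid <- expand.grid(schema$represented, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    attrs <- vapply(schema$tasks, function(tk) grid[i, tk], character(1))
    out <- c(out, subgroup_samples(n_per_subgroup, attrs, schema, npix,
                                   seed = seed + i,
                                   prefix = sprintf("g%02d_", i)))
  }
  out
}

# triplet whose member pixels put prescribed raw scores on a linear scorer:
# masked pixels at 0.5 + effect * s_i give raw score s_i exactly
scored_triplet <- function(config, schema, vertex_scores,
                           attrs = NULL) {
  if (is.null(attrs))
    attrs <- vapply(schema$tasks, function(tk) schema$classes[[tk]][1],
                    character(1))
  tmpl <- as.vector(config$templates[[1]])
  p <- config$image_size^2
  members <- lapply(1:3, function(i) {
    px <- rep(0.5, p)
    px <- px + vertex_scores[i] * config$effect * tmpl
    # member-specific off-template structure keeps the spanned plane
    # non-degenerate without touching the template (and thus the scores)
    if (i > 1) px[p - i] <- px[p - i] + 0.2
    fixture_sample(sprintf("v%d", i), attrs,
                   matrix(px, config$image_size))
  })
  new_triplet(members, schema)
}

# fabricate a triplet_composition with a prescribed same-class fraction on
# the first task (granularity 1/n_points)
fake_composition <- function(schema, same_frac, n_points = 351,
                             id = NA_character_) {
  tk <- schema$tasks[1]
  cls <- schema$classes[[tk]]
  k <- round(same_frac * n_points)
  preds <- matrix(NA_character_, n_points, length(schema$tasks),
                  dimnames = list(NULL, schema$tasks))
  for (t2 in schema$tasks) preds[, t2] <- schema$classes[[t2]][2]
  preds[seq_len(k), tk] <- cls[1]
  attrs <- vapply(schema$tasks, function(t2) schema$classes[[t2]][1],
                  character(1))
  trip <- list(subgroup = unname(attrs))
  triplet_composition(preds, trip, schema, triplet_id = id)
}
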