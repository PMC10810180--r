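#' Construct a triplet of same-subgroup samples
#'
#' Three images from three distinct patients sharing one subgroup span a
#' two-dimensional plane in pixel space; virtual images are synthesized on
#' that plane. Keeping all three members in one subgroup gives every
#' classification task a well-defined reference class for the whole plane.
#'
#' @param members list of three `decreg_sample`s with distinct patients, equal
#'   image shapes and identical attributes.
#' @param schema an [attr_schema()].
#' @return an object of class `triplet` with fields `members` and `subgroup`.
#' @export
new_triplet <- function(members, schema) {
  if (length(members) != 3) stop_decreg("a triplet needs exactly 3 members")
  pids <- vapply(members, function(s) s$patient_id, character(1))
  if (anyDuplicated(pids))
    stop_decreg("triplet members must come from distinct patients")
  sgs <- lapply(members, assign_subgroup, schema = schema)
  if (!all(vapply(sgs[-1], identical, logical(1), y = sgs[[1]])))
    stop_decreg("triplet members do not share one subgroup")
  shapes <- vapply(members, function(s) dim(s$pixels), integer(2))
  if (any(shapes != shapes[, 1]))
    stop_decreg("triplet member images do not share one shape")
  structure(list(members = members, subgroup = sgs[[1]]), class = "triplet")
}

#' Randomly sample triplets per subgroup
#'
#' Draws `n_triplets` triplets from every subgroup by uniform sampling of
#' three distinct patients per draw. Draws are independent, so with small
#' patient pools the same patient combination can recur across triplets;
#' within one triplet the patients are always distinct. Each subgroup uses an
#' RNG seed derived from (seed, subgroup), so results per subgroup are stable
#' under changes to the rest of the cohort.
#'
#' @param samples_by_subgroup named list (subgroup key -> list of samples),
#'   e.g. from [group_by_subgroup()]. Every subgroup needs at least three
#'   patients.
#' @param schema an [attr_schema()].
#' @param n_triplets triplets per subgroup (default 50).
#' @param seed master integer seed.
#' @return named list (subgroup key -> list of `triplet`).
#' @export
sample_triplets <- function(samples_by_subgroup, schema, n_triplets = 50L,
                            seed = 1L) {
  out <- list()
  for (key in names(samples_by_subgroup)) {
    ss <- samples_by_subgroup[[key]]
    pids <- vapply(ss, function(s) s$patient_id, character(1))
    pool <- sort(unique(pids))
    if (length(pool) < 3)
      stop_decreg("subgroup '%s' has %d patient(s); triplet selection needs >= 3",
                  key, length(pool))
    first_idx <- match(pool, pids)  # one image per patient: first occurrence
    set.seed(stable_hash(seed, "triplets", key))
    out[[key]] <- lapply(seq_len(n_triplets), function(i) {
      pick <- sample(length(pool), 3L)
      new_triplet(ss[first_idx[pick]], schema)
    })
  }
  out
}

#' Barycentric lattice on the triangle spanned by a triplet
#'
#' Evenly spaced interpolation weights (a, b, c) = (i/R, j/R, (R-i-j)/R) for
#' all non-negative integers i + j <= R. The lattice has (R+1)(R+2)/2 points,
#' is closed under permutation of the three barycentric roles, and the
#' integer construction makes every weight triple sum to one exactly as a
#' rational number. `index` stores the integer coordinates; `weights` the
#' floating-point matrix used for interpolation.
#'
#' @param R lattice resolution (points per edge minus one); default 25, i.e.
#'   351 virtual images per triplet.
#' @return an object of class `bary_lattice` with fields `R`, `index`
#'   (n x 3 integer) and `weights` (n x 3 double).
#' @export
barycentric_lattice <- function(R = 25L) {
  R <- as.integer(R)
  if (is.na(R) || R < 1) stop_decreg("lattice resolution R must be >= 1")
  ij <- expand.grid(i = 0:R, j = 0:R)
  ij <- ij[ij$i + ij$j <= R, ]
  ij <- ij[order(ij$i, ij$j), ]
  idx <- cbind(i = ij$i, j = ij$j, k = R - ij$i - ij$j)
  structure(list(R = R, index = idx, weights = idx / R),
            class = "bary_lattice")
}

#' @export
print.bary_lattice <- function(x, ...) {
  cat(sprintf("barycentric lattice: R = %d, %d points\n", x$R,
              nrow(x$weights)))
  invisible(x)
}

#' Synthesize the vicinal distribution of virtual images for a triplet
#'
#' Linearly interpolates the three member images at every lattice weight:
#' p = a x0 + b x1 + c x2 on the flattened pixel vectors. Every virtual pixel
#' lies in the convex hull of the member pixels, so no clipping is needed.
#' The weighted sum is accumulated with the members ordered by `sample_id`,
#' which makes the synthesized images (and hence any downstream composition)
#' bit-identical under relabeling of the triplet members.
#'
#' @param triplet a `triplet`.
#' @param lattice a [barycentric_lattice()].
#' @return list with `pixels` (n_points x n_pixels matrix, rows in lattice
#'   order), `weights` (the lattice weights), and `shape` of the member
#'   images.
#' @export
synthesize_virtual_samples <- function(triplet, lattice) {
  shape <- dim(triplet$members[[1]]$pixels)
  X <- vapply(triplet$members, function(s) {
    if (!identical(dim(s$pixels), shape))
      stop_decreg("triplet member images do not share one shape")
    as.vector(s$pixels)
  }, numeric(prod(shape)))
  # canonical accumulation order: permutation-invariant at the bit level
  ord <- order(vapply(triplet$members, function(s) s$sample_id, character(1)))
  W <- lattice$weights[, ord, drop = FALSE]
  X <- X[, ord, drop = FALSE]
  P <- W %*% t(X)
  list(pixels = P, weights = lattice$weights, shape = shape)
}

#' Chart the plane spanned by a triplet
#'
#' Builds an orthonormal in-plane frame by Gram-Schmidt on (x1 - x0, x2 - x0)
#' and a rectangular grid covering the triangle's bounding box (expanded by a
#' margin), each grid point mapped back to pixel space. The extended plane is
#' intended for decision-region visualization; composition uses the closed
#' triangle (the barycentric lattice) by default because only there is the
#' subgroup reference class meaningful.
#'
#' @param triplet a `triplet` whose member differences are linearly
#'   independent.
#' @param grid number of grid points per axis.
#' @param margin fractional expansion of the bounding box on each side.
#' @return an object of class `plane_chart`: origin pixels `x0`, orthonormal
#'   directions `e1`, `e2`, 3 x 2 matrix `vertices` of in-plane vertex
#'   coordinates, grid coordinates `coords` (n x 2), `pixels` (n x n_pixels,
#'   clipped to \[0, 1\]), logical `inside` flags, and `shape`.
#' @export
plane_chart <- function(triplet, grid = 50L, margin = 0.1) {
  shape <- dim(triplet$members[[1]]$pixels)
  x0 <- as.vector(triplet$members[[1]]$pixels)
  d1 <- as.vector(triplet$members[[2]]$pixels) - x0
  d2 <- as.vector(triplet$members[[3]]$pixels) - x0
  n1 <- sqrt(sum(d1^2))
  if (n1 == 0) stop_decreg("degenerate plane: first two members identical")
  e1 <- d1 / n1
  r <- d2 - sum(d2 * e1) * e1
  n2 <- sqrt(sum(r^2))
  if (n2 <= 1e-8 * sqrt(sum(d2^2)))
    stop_decreg("degenerate plane: triplet members are collinear")
  e2 <- r / n2
  vertices <- rbind(c(0, 0), c(n1, 0), c(sum(d2 * e1), n2))

  lo <- apply(vertices, 2, min); hi <- apply(vertices, 2, max)
  pad <- margin * (hi - lo)
  us <- seq(lo[1] - pad[1], hi[1] + pad[1], length.out = grid)
  vs <- seq(lo[2] - pad[2], hi[2] + pad[2], length.out = grid)
  coords <- as.matrix(expand.grid(u = us, v = vs))
  P <- coords[, 1] %o% e1 + coords[, 2] %o% e2
  P <- sweep(P, 2, x0, `+`)
  P[P < 0] <- 0; P[P > 1] <- 1
  inside <- point_in_triangle(coords, vertices)
  structure(list(x0 = x0, e1 = e1, e2 = e2, vertices = vertices,
                 coords = coords, pixels = P, inside = inside,
                 grid = as.integer(grid), margin = margin, shape = shape),
            class = "plane_chart")
}

# barycentric point-in-triangle test with a small tolerance for edge points
#' @noRd
point_in_triangle <- function(coords, vertices, tol = 1e-9) {
  A <- cbind(vertices[2, ] - vertices[1, ], vertices[3, ] - vertices[1, ])
  rel <- sweep(coords, 2, vertices[1, ])
  ab <- t(solve(A, t(rel)))
  ab[, 1] >= -tol & ab[, 2] >= -tol & rowSums(ab) <= 1 + tol
}
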