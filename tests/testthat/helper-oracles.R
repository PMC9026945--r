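## Independent oracles used across the test suite. These deliberately take
## different computational routes from the package code they check.

## Connected component of {v > t} (plus the seed voxel) containing the seed,
## computed via igraph's component labelling rather than the package's
## wavefront expansion.
oracle_component <- function(v, dims, seed_lin, t, offsets) {
  cand <- which(v > t)
  cand <- union(cand, seed_lin)
  in_cand <- logical(length(v)); in_cand[cand] <- TRUE
  ni <- dims[1]; nj <- dims[2]
  i0 <- ((cand - 1L) %% ni) + 1L
  j0 <- (((cand - 1L) %/% ni) %% nj) + 1L
  k0 <- ((cand - 1L) %/% (ni * nj)) + 1L
  edges <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    i <- i0 + offsets[r, 1]; j <- j0 + offsets[r, 2]; k <- k0 + offsets[r, 3]
    ok <- i >= 1L & i <= ni & j >= 1L & j <= nj & k >= 1L & k <= dims[3]
    nb <- i[ok] + (j[ok] - 1L) * ni + (k[ok] - 1L) * ni * nj
    keep <- in_cand[nb]
    edges <- c(edges, rbind(cand[ok][keep], nb[keep]))
  }
  g <- igraph::make_empty_graph(n = length(v), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  members <- which(comp == comp[seed_lin])
  intersect(members, cand)
}

## Per-threshold flood-fill reference for the whole growing schedule: at each
## threshold in the decrement sequence the region is the seeded connected
## component of the thresholded volume, and the same stop rules are applied:
## revert-and-stop on more-than-doubling (once the region has min_voxels),
## stop when a saturated region cannot grow at any admissible threshold, stop
## below the floor.
oracle_grow <- function(vol, seed, params) {
  v <- as.vector(vol$data); dims <- dim(vol$data)
  offsets <- hspseg:::connectivity_offsets(params$connectivity)
  seed_lin <- seed$i + (seed$j - 1L) * dims[1] + (seed$k - 1L) * dims[1] * dims[2]
  t0 <- initial_threshold(vol, seed, params$window_radius)
  floor_t <- params$threshold_floor %||% min(v)
  t <- t0
  region <- seed_lin
  stop_reason <- NA_character_
  repeat {
    new_region <- oracle_component(v, dims, seed_lin, t, offsets)
    stopifnot(all(region %in% new_region))   # nesting sanity
    added <- length(new_region) - length(region)
    if (added > 0L &&
        length(region) >= params$doubling_min_voxels &&
        length(new_region) > params$doubling_factor * length(region)) {
      stop_reason <- "volume_doubled"
      break                                  # keep pre-doubling region
    }
    region <- new_region
    if (added == 0L && length(region) > 1L) {
      nb <- hspseg:::neighbor_indices(region, dims, offsets)
      nb <- setdiff(nb, region)
      if (!length(nb) || max(v[nb]) <= floor_t) {
        stop_reason <- "no_new_voxels"
        break
      }
    }
    t <- t - params$threshold_step
    if (t < floor_t) { stop_reason <- "floor_reached"; break }
  }
  mask <- logical(length(v)); mask[region] <- TRUE
  list(mask = array(mask, dims), stop_reason = stop_reason)
}

## Dense 3D Gaussian kernel built explicitly (outer product of 1D samples),
## for checking the separable implementation against direct convolution.
oracle_gaussian_kernel3 <- function(sigma, radius) {
  x <- (-radius):radius
  w1 <- exp(-x^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  k3 <- outer(outer(w1, w1), w1)
  array(k3, dim = c(length(x), length(x), length(x)))
}

## ICC(2,1) mean squares obtained through aov() rather than closed-form sums.
oracle_icc21_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

## Small random integer test volume wrapped as volume3d.
random_volume <- function(dims, lo = 0L, hi = 50L) {
  volume3d(array(sample(lo:hi, prod(dims), replace = TRUE), dim = dims))
}

## Deterministic in-bounds random seed point for a volume.
random_seed_point <- function(dims) {
  seed_point(sample.int(dims[1], 1), sample.int(dims[2], 1),
             sample.int(dims[3], 1))
}
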