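## Neighbourhood machinery for region growing. Offsets are rows of a
## n x 3 integer matrix; 6 = face neighbours, 18 = faces + edges,
## 26 = the full 3 x 3 x 3 cube minus the centre.
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop_contract("connectivity must be 6, 18 or 26"))
}

## In-bounds neighbours (linear indices, may contain duplicates) of the
## voxels in `lin` under the offset set. Vectorized over all offsets.
neighbor_indices <- function(lin, dims, offsets) {
  if (!length(lin)) return(integer(0))
  ni <- dims[1]; nj <- dims[2]
  i0 <- ((lin - 1L) %% ni) + 1L
  j0 <- (((lin - 1L) %/% ni) %% nj) + 1L
  k0 <- ((lin - 1L) %/% (ni * nj)) + 1L
  n <- length(lin); m <- nrow(offsets)
  i <- rep(i0, times = m) + rep(offsets[, 1], each = n)
  j <- rep(j0, times = m) + rep(offsets[, 2], each = n)
  k <- rep(k0, times = m) + rep(offsets[, 3], each = n)
  ok <- i >= 1L & i <= ni & j >= 1L & j <= nj & k >= 1L & k <= dims[3]
  (i[ok] + (j[ok] - 1L) * ni + (k[ok] - 1L) * ni * nj)
}

## Expand `region` (logical vector) into `cand` (logical vector) until no
## connected candidate remains; breadth-first by wavefront.
expand_region <- function(region, cand, frontier, dims, offsets) {
  while (length(frontier)) {
    nb <- neighbor_indices(frontier, dims, offsets)
    newly <- unique(nb[cand[nb] & !region[nb]])
    region[newly] <- TRUE
    frontier <- newly
  }
  region
}

#' Extract the plaque region by threshold-decrementing region growing
#'
#' Starting from the corrected seed, the region is grown on the smoothed
#' volume: at each pass, connected voxels with intensity *strictly greater*
#' than the current threshold are added; the threshold starts at the window
#' maximum around the seed ([initial_threshold()]) and is reduced by
#' `threshold_step` between passes. Growing stops when
#'
#' * `no_new_voxels`: the region (beyond the bare seed) can no longer gain
#'   any voxel at any admissible threshold — every voxel adjacent to it sits
#'   at or below the threshold floor;
#' * `volume_doubled`: a pass multiplies the region size by more than
#'   `doubling_factor` (once the region holds at least
#'   `doubling_min_voxels`), the signature of flooding into surrounding
#'   tissue — the region from the pass *before* the flood is returned;
#' * `floor_reached`: the threshold would drop below the threshold floor
#'   (default: the smoothed volume minimum), which guarantees termination.
#'
#' The returned mask is a single connected component under the configured
#' connectivity and always contains the corrected seed; each pass's region
#' is a superset of the previous pass's.
#'
#' @param smoothed The smoothed [volume3d()].
#' @param corrected_seed A [seed_point()] inside the volume.
#' @param params A [region_grow_params()].
#' @return A list with `mask` (the plaque [mask3d()]), `trace` (a
#'   `region_grow_trace` data frame with one row per pass: `threshold`,
#'   `count`, `added`, and attributes `stop_reason`, `initial_threshold`,
#'   `final_threshold`), `initial_threshold` and `final_threshold` (the
#'   threshold of the pass that produced the returned mask).
#' @export
grow_plaque_region <- function(smoothed, corrected_seed,
                               params = region_grow_params()) {
  dims <- dim(smoothed$data)
  check_seed_bounds(corrected_seed, dims, "corrected seed")
  v <- as.vector(smoothed$data)
  offsets <- connectivity_offsets(params$connectivity)
  t0 <- initial_threshold(smoothed, corrected_seed, params$window_radius)
  floor_t <- params$threshold_floor %||% min(v)
  step <- params$threshold_step

  seed_lin <- corrected_seed$i + (corrected_seed$j - 1L) * dims[1] +
    (corrected_seed$k - 1L) * dims[1] * dims[2]
  region <- logical(length(v))
  region[seed_lin] <- TRUE
  count <- 1L

  thresholds <- numeric(0); counts <- integer(0); addeds <- integer(0)
  stop_reason <- NA_character_
  final_t <- t0
  t <- t0
  ## once a zero-growth pass proves the region saturated, remember it
  repeat {
    cand <- v > t
    prev_region <- region
    region <- expand_region(region, cand, which(prev_region), dims, offsets)
    new_count <- sum(region)
    added <- new_count - count
    thresholds <- c(thresholds, t)
    counts <- c(counts, new_count)
    addeds <- c(addeds, added)

    if (added > 0L && count >= params$doubling_min_voxels &&
        new_count > params$doubling_factor * count) {
      region <- prev_region            # keep the pre-flood region
      stop_reason <- "volume_doubled"
      break
    }
    count <- new_count
    final_t <- t
    if (added == 0L && count > 1L) {
      ## terminal only if nothing adjacent can ever clear the floor
      nb <- neighbor_indices(which(region), dims, offsets)
      nb <- nb[!region[nb]]
      if (!length(nb) || max(v[nb]) <= floor_t) {
        stop_reason <- "no_new_voxels"
        break
      }
    }
    t <- t - step
    if (t < floor_t) {
      stop_reason <- "floor_reached"
      break
    }
  }

  trace <- data.frame(threshold = thresholds, count = counts, added = addeds)
  attr(trace, "stop_reason") <- stop_reason
  attr(trace, "initial_threshold") <- t0
  attr(trace, "final_threshold") <- final_t
  class(trace) <- c("region_grow_trace", "data.frame")
  list(mask = mask3d(array(region, dims), smoothed$spacing),
       trace = trace,
       initial_threshold = t0,
       final_threshold = final_t)
}

#' @export
print.region_grow_trace <- function(x, ...) {
  cat(sprintf("region_grow_trace: %d passes, threshold %.6g -> %.6g, stop: %s\n",
              nrow(x), attr(x, "initial_threshold"),
              attr(x, "final_threshold"), attr(x, "stop_reason")))
  NextMethod()
}
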