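#' Canonical resting-state network names used for synthetic templates
#'
#' Standard large-scale network abbreviations (medial/lateral visual,
#' precuneus, sensorimotor, auditory, executive control, default mode,
#' frontal, language, ventral attention, salience, task-positive,
#' cerebellar).
#' @export
RSN_NAMES <- c("MVN", "LVN", "PN", "PNsup", "SMNm1", "SMNs2", "AN", "ECN",
               "DMN", "DMNa", "FCN", "LNa", "LNp", "RVAN", "LVAN", "SN",
               "TPN", "CBLN")

#' Generate synthetic resting-state network spatial templates
#'
#' Places `n_networks` smooth Gaussian blobs at well-separated centers on a
#' 3D grid. Each template is normalized so its maximum weight is exactly 1;
#' the suprathreshold (> 0.5) extents of distinct templates are disjoint by
#' construction. Deterministic given `seed`.
#'
#' @param grid_dims integer triple of grid dimensions (each >= 8).
#' @param n_networks number of templates (>= 2).
#' @param seed integer RNG seed.
#' @param sigma_vox Gaussian width in voxels.
#' @param names template names; defaults to the first `n_networks` entries
#'   of [RSN_NAMES].
#' @return a list of `rsn_template` objects with fields `name`, `map`
#'   (3D array, values in `[0,1]`, max 1) and `peak_coords` (voxel triple).
#' @export
make_rsn_templates <- function(grid_dims, n_networks, seed,
                               sigma_vox = 1.6,
                               names = NULL) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, n_networks >= 2)
  small <- which(grid_dims < 8)
  if (length(small))
    stop(sprintf("grid dimension %d (= %d) too small to place blobs",
                 small[1], grid_dims[small[1]]))
  if (is.null(names)) names <- RSN_NAMES[seq_len(n_networks)]
  stopifnot(length(names) == n_networks)

  # >0.5 iso-surface radius of a peak-1 Gaussian
  r_half <- sigma_vox * sqrt(2 * log(2))
  min_dist <- 2 * r_half + 1
  margin <- ceiling(r_half)
  lo <- pmin(1 + margin, grid_dims)
  hi <- pmax(grid_dims - margin, lo)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  # best-candidate (maximin) placement with restarts: each center is the
  # candidate farthest from those already placed, which avoids the
  # dead-end configurations plain sequential rejection can jam into
  centers <- NULL
  for (restart in seq_len(100L)) {
    cur <- matrix(NA_real_, n_networks, 3)
    placed <- 0
    repeat {
      cand <- cbind(runif(64, lo[1], hi[1]), runif(64, lo[2], hi[2]),
                    runif(64, lo[3], hi[3]))
      if (placed == 0) {
        best <- cand[1, ]
        d_best <- Inf
      } else {
        dmin <- apply(cand, 1, function(p)
          min(sqrt(rowSums(sweep(cur[seq_len(placed), , drop = FALSE],
                                 2, p)^2))))
        best <- cand[which.max(dmin), ]
        d_best <- max(dmin)
      }
      if (d_best < min_dist) break        # jammed; restart
      placed <- placed + 1
      cur[placed, ] <- best
      if (placed == n_networks) break
    }
    if (placed == n_networks) {
      centers <- cur
      break
    }
  }
  if (is.null(centers)) {
    worst <- which.min(grid_dims)
    stop(sprintf(
      "could not place %d non-overlapping networks; grid dimension %d (= %d) is the limiting one",
      n_networks, worst, grid_dims[worst]))
  }

  ax <- seq_len(grid_dims[1]); ay <- seq_len(grid_dims[2]); az <- seq_len(grid_dims[3])
  lapply(seq_len(n_networks), function(k) {
    cx <- centers[k, ]
    gx <- exp(-((ax - cx[1])^2) / (2 * sigma_vox^2))
    gy <- exp(-((ay - cx[2])^2) / (2 * sigma_vox^2))
    gz <- exp(-((az - cx[3])^2) / (2 * sigma_vox^2))
    map <- outer(outer(gx, gy), gz)
    map <- map / max(map)
    structure(list(name = names[k], map = map,
                   peak_coords = round(cx)),
              class = "rsn_template")
  })
}

#' Suprathreshold mask of a template
#' @param tpl an `rsn_template`.
#' @param thr weight threshold (default 0.5).
#' @return logical 3D array.
#' @export
template_mask <- function(tpl, thr = 0.5) tpl$map > thr

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
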