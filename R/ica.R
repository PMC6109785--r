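#' Seeded randomized SVD
#'
#' Top-`k` singular triplets of a wide matrix by random range finding with
#' power iterations; deterministic given the RNG state.
#' @param X matrix.
#' @param k number of components.
#' @param oversample extra probe vectors.
#' @param power number of power iterations.
#' @return list `u`, `d`, `v` as in [svd()].
#' @keywords internal
rsvd <- function(X, k, oversample = 10, power = 2) {
  p <- min(k + oversample, min(dim(X)))
  Om <- matrix(rnorm(ncol(X) * p), ncol(X), p)
  Y <- X %*% Om
  for (i in seq_len(power)) {
    Y <- qr.Q(qr(Y))
    Y <- X %*% crossprod(X, Y)
  }
  Q <- qr.Q(qr(Y))
  B <- crossprod(Q, X)
  s <- svd(B, nu = k, nv = k)
  list(u = Q %*% s$u[, seq_len(k), drop = FALSE],
       d = s$d[seq_len(k)],
       v = s$v[, seq_len(k), drop = FALSE])
}

# fixed-point (logcosh negentropy) iteration with symmetric decorrelation;
# Z is k x V whitened data (rows orthonormal up to sqrt(V) scaling)
.fastica_core <- function(Z, tol = 1e-6, max_iter = 500) {
  k <- nrow(Z); V <- ncol(Z)
  W <- matrix(rnorm(k * k), k, k)
  sym <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gprime <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / V - diag(gprime, k) %*% W
    W1 <- sym(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) return(list(W = W, converged = TRUE, iter = it))
  }
  list(W = W, converged = FALSE, iter = max_iter)
}

#' Group spatial ICA by temporal concatenation
#'
#' Concatenates subjects along time, whitens to `order` dimensions
#' (randomized SVD over the temporal dimension), and extracts spatially
#' independent components with a fixed-point negentropy-maximization
#' iteration under symmetric decorrelation (convergence when successive
#' unmixing matrices differ by < `tol`, up to `max_iter` iterations, with
#' up to 5 seeded restarts). Component maps are Z-scaled (zero mean, unit
#' variance over the mask) with the sign fixed so the largest-magnitude
#' voxel is positive.
#'
#' @param subjects list of [volume4d]s sharing grid and mask.
#' @param order number of components (>= 2).
#' @param seed integer seed.
#' @param tol,max_iter convergence controls of the fixed-point iteration.
#' @return a `group_ica` object: `spatial_maps` (order x in-mask voxels),
#'   `timecourses` (concatenated time x order), `order`, `labels`
#'   (initially `NA`), `power_low_ratio`, plus grid bookkeeping.
#' @export
group_decompose <- function(subjects, order, seed = 1,
                            tol = 1e-6, max_iter = 500) {
  stopifnot(order >= 2, length(subjects) >= 1)
  d0 <- dim(subjects[[1]]$data)[1:3]
  mask <- subjects[[1]]$mask
  for (s in subjects) {
    if (!all(dim(s$data)[1:3] == d0) || !all(s$mask == mask))
      stop("all subjects must share grid and mask")
  }
  lens <- vapply(subjects, function(s) dim(s$data)[4], integer(1))
  X <- do.call(rbind, lapply(subjects, vol_matrix))
  X <- X - rowMeans(X)                     # demean each timepoint over voxels
  V <- ncol(X)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sv <- rsvd(X, order)
  Z <- t(sv$v) * sqrt(V)                   # order x V, rows: mean 0, var 1

  fit <- NULL
  for (attempt in 0:5) {
    if (attempt > 0) set.seed(seed + 1000L * attempt)
    fit <- .fastica_core(Z, tol = tol, max_iter = max_iter)
    if (fit$converged) break
  }
  if (!fit$converged)
    stop("fixed-point iteration failed to converge after 5 restarts")

  S <- fit$W %*% Z                         # order x V spatial sources
  S <- S / apply(S, 1, stats::sd)
  flip <- apply(S, 1, function(r) sign(r[which.max(abs(r))]))
  S <- S * flip
  # deterministic component ordering: by explained variance of projection
  tc <- X %*% t(S) %*% solve(tcrossprod(S))
  ord <- order(colSums(tc^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  tc <- tc[, ord, drop = FALSE]

  tr <- subjects[[1]]$tr
  plr <- vapply(seq_len(order), function(k) {
    segs <- split(tc[, k], rep(seq_along(lens), lens))
    mean(vapply(segs, band_power_ratio, numeric(1), tr = tr))
  }, numeric(1))

  structure(list(spatial_maps = S, timecourses = tc, order = order,
                 labels = rep(NA_character_, order),
                 power_low_ratio = plr,
                 mask = mask, dims = d0, tr = tr,
                 subject_lengths = lens),
            class = "group_ica")
}

#' @export
print.group_ica <- function(x, ...) {
  cat(sprintf("<group_ica> %d components over %d in-mask voxels\n",
              x$order, sum(x$mask)))
  if (!all(is.na(x$labels))) {
    n_rsn <- sum(x$labels != "artifact", na.rm = TRUE)
    cat(sprintf("  %d labeled as RSNs, %d as artifacts\n",
                n_rsn, sum(x$labels == "artifact", na.rm = TRUE)))
  }
  invisible(x)
}

#' Spatial map of one component as a 3D array
#' @param ica a `group_ica`.
#' @param k component index.
#' @return 3D array (zero outside the mask).
#' @export
component_map <- function(ica, k) unmask(ica$spatial_maps[k, ], ica$mask)

#' Classify components as resting-state networks or artifacts
#'
#' A component receives the best-matching template's name iff its maximum
#' absolute spatial correlation with any unassigned template is at least
#' `r_min` *and* the low-frequency (0.01-0.1 Hz) fraction of its time
#' course power is at least `p_min`; otherwise it is labeled `"artifact"`.
#' Templates are assigned greedily by decreasing correlation, ties broken
#' by lower component index.
#'
#' @param ica a `group_ica`.
#' @param templates list of `rsn_template`s.
#' @param r_min spatial correlation threshold.
#' @param p_min low-frequency power-ratio threshold.
#' @return the `group_ica` with `labels` filled in.
#' @export
classify_components <- function(ica, templates, r_min = 0.4, p_min = 0.5) {
  stopifnot(length(templates) >= 1)
  nt <- length(templates); nc <- ica$order
  tmpl_v <- vapply(templates, function(tp) as.vector(tp$map)[ica$mask],
                   numeric(sum(ica$mask)))
  cors <- abs(stats::cor(t(ica$spatial_maps), tmpl_v))  # nc x nt
  labels <- rep("artifact", nc)
  eligible <- ica$power_low_ratio >= p_min
  cand <- cors
  cand[!eligible, ] <- -Inf
  repeat {
    best <- max(cand)
    if (!is.finite(best) || best < r_min) break
    hit <- which(cand == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1]), , drop = FALSE][1, ]
    labels[hit[1]] <- templates[[hit[2]]]$name
    cand[hit[1], ] <- -Inf
    cand[, hit[2]] <- -Inf
  }
  ica$labels <- labels
  ica$template_correlations <- cors
  ica
}

#' Greedy matching of estimated maps to reference templates
#'
#' Pairs each template with its best-correlated map (absolute correlation,
#' greedy without replacement) — the standard recovery metric for planted
#' decompositions.
#'
#' @param maps k x voxels matrix (or `group_ica`).
#' @param templates list of `rsn_template`s.
#' @param mask logical 3D array selecting the voxels of `maps` columns.
#' @return data.frame with `template`, `component`, `abs_cor`.
#' @export
match_maps_to_templates <- function(maps, templates, mask = NULL) {
  if (inherits(maps, "group_ica")) {
    mask <- maps$mask
    maps <- maps$spatial_maps
  }
  tmpl_v <- vapply(templates, function(tp) {
    v <- as.vector(tp$map)
    if (!is.null(mask)) v[as.vector(mask)] else v
  }, numeric(ncol(maps)))
  cors <- abs(stats::cor(t(maps), tmpl_v))
  out <- data.frame(template = vapply(templates, `[[`, "", "name"),
                    component = NA_integer_, abs_cor = NA_real_)
  cand <- cors
  for (rep_i in seq_len(min(nrow(maps), length(templates)))) {
    best <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    out$component[best[2]] <- best[1]
    out$abs_cor[best[2]] <- cors[best[1], best[2]]
    cand[best[1], ] <- -Inf
    cand[, best[2]] <- -Inf
  }
  out
}
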