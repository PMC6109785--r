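#' Dual regression stage 1: subject-specific time courses
#'
#' For each timepoint, ordinary least squares of the subject's in-mask
#' voxel values on *all* group spatial maps simultaneously; the coefficient
#' series of each map is that subject's network time course.
#'
#' @param vol a [volume4d].
#' @param group_maps components x in-mask-voxels matrix (e.g.
#'   `spatial_maps` of a `group_ica`).
#' @param mask logical 3D array the map columns refer to; defaults to
#'   `vol$mask`.
#' @return T x components matrix of time courses.
#' @export
stage1_timecourses <- function(vol, group_maps, mask = NULL) {
  if (is.null(mask)) mask <- vol$mask
  Y <- t(vol_matrix(vol))                      # voxels x T (under vol mask)
  stopifnot(ncol(group_maps) == nrow(Y))
  G <- t(group_maps)                           # voxels x k
  qrG <- qr(G)
  if (qrG$rank < ncol(G)) {
    dep <- setdiff(seq_len(ncol(G)), qrG$pivot[seq_len(qrG$rank)])
    stop(sprintf("group maps are rank deficient; collinear components: %s",
                 paste(dep, collapse = ", ")))
  }
  t(qr.coef(qrG, Y))                           # T x k
}

#' Dual regression stage 2: subject spatial maps
#'
#' Per voxel, ordinary least squares of its time series on all stage-1
#' time courses simultaneously. Parameter-estimate (`pe`) maps are the
#' coefficients; `z` maps are coefficient / standard error converted from
#' the t distribution (`T - k` degrees of freedom) to standard normal
#' deviates.
#'
#' @param vol a [volume4d].
#' @param timecourses T x components matrix.
#' @param variance_normalize_tc scale each time course to unit variance
#'   before the fit (default `TRUE`), making `pe` maps carry amplitude as
#'   well as shape information.
#' @return a `subject_maps` object: `pe_maps` and `z_maps` (components x
#'   in-mask voxels), `timecourses`, `mask`, `dims`.
#' @export
stage2_subject_maps <- function(vol, timecourses, variance_normalize_tc = TRUE) {
  Y <- vol_matrix(vol)                         # T x voxels
  Tn <- nrow(Y); k <- ncol(timecourses)
  if (Tn <= k) stop("need more timepoints than components")
  stopifnot(nrow(timecourses) == Tn)
  tc <- timecourses
  if (variance_normalize_tc) {
    s <- apply(tc, 2, stats::sd)
    if (any(s == 0)) stop("constant time course cannot be variance-normalized")
    tc <- sweep(tc, 2, s, "/")
  }
  qrT <- qr(tc)
  if (qrT$rank < k) {
    dep <- setdiff(seq_len(k), qrT$pivot[seq_len(qrT$rank)])
    stop(sprintf("time courses are rank deficient; collinear columns: %s",
                 paste(dep, collapse = ", ")))
  }
  B <- qr.coef(qrT, Y)                         # k x voxels
  res <- Y - tc %*% B
  df <- Tn - k
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrT))
  se <- sqrt(outer(diag(XtXinv), sigma2))      # k x voxels
  tstat <- B / se
  tstat[se == 0] <- 0
  z <- .t_to_z(tstat, df)
  structure(list(pe_maps = B, z_maps = z, timecourses = tc,
                 mask = vol$mask, dims = dim(vol$data)[1:3]),
            class = "subject_maps")
}

# numerically stable t -> standard normal deviate conversion
.t_to_z <- function(tstat, df) {
  lp <- stats::pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE)
  z <- -sign(tstat) * stats::qnorm(lp, log.p = TRUE)
  dim(z) <- dim(tstat)
  z
}

#' Run both dual-regression stages for every subject
#'
#' @param volumes list of [volume4d]s.
#' @param ica a `group_ica` (or a components x voxels matrix plus `mask`).
#' @param components indices of components to retain (default: all; for a
#'   labeled `group_ica`, all non-artifact components).
#' @param variance_normalize_tc see [stage2_subject_maps].
#' @return list of `subject_maps`, with the retained component indices as
#'   attribute `"components"`.
#' @export
dual_regression <- function(volumes, ica, components = NULL,
                            variance_normalize_tc = TRUE) {
  maps <- if (inherits(ica, "group_ica")) ica$spatial_maps else ica
  if (is.null(components)) {
    components <- if (inherits(ica, "group_ica") && !all(is.na(ica$labels)))
      which(ica$labels != "artifact") else seq_len(nrow(maps))
  }
  maps <- maps[components, , drop = FALSE]
  out <- lapply(volumes, function(v) {
    tc <- stage1_timecourses(v, maps)
    stage2_subject_maps(v, tc, variance_normalize_tc = variance_normalize_tc)
  })
  attr(out, "components") <- components
  out
}

#' Stack one component's subject maps into a subjects x voxels matrix
#'
#' @param subject_maps list of `subject_maps`.
#' @param k component row index within the subject maps.
#' @param what `"pe"` (default) or `"z"`.
#' @return subjects x in-mask-voxels matrix.
#' @export
stack_component <- function(subject_maps, k, what = c("pe", "z")) {
  what <- match.arg(what)
  field <- if (what == "pe") "pe_maps" else "z_maps"
  do.call(rbind, lapply(subject_maps, function(s) s[[field]][k, ]))
}
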