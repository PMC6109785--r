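#' Significance mask of a stat map
#'
#' @param stat a `stat_map`.
#' @param alpha FWE threshold.
#' @return logical 3D array: `p_fwe <= alpha` (FALSE outside the mask).
#' @export
build_stage_mask <- function(stat, alpha = 0.05) {
  out <- !is.na(stat$p_fwe) & stat$p_fwe <= alpha
  array(out, dim(stat$mask))
}

#' Masked covariate permutation inference (both signs)
#'
#' Within `stage_mask` only, runs [permutation_fwe] with the design
#' `[covariate, intercept, nuisance...]` and the contrast on the covariate
#' column, once per sign. The significant set of each sign is
#' `p_fwe <= alpha`; the combined per-voxel sign map is +1 / -1 where the
#' positive / negative association is significant, 0 elsewhere.
#'
#' @param subject_maps subjects x voxels matrix over the *analysis* mask
#'   (the function restricts the columns to `stage_mask` itself).
#' @param analysis_mask logical 3D array the columns refer to.
#' @param design_df design rows of the included subjects (MS only).
#' @param covariate covariate column name (`"t2ll"` or `"msss"`).
#' @param stage_mask logical 3D array (nonempty, within `analysis_mask`).
#' @param stage stage tag stored in the stat maps.
#' @param n_perm,params,seed,alpha,keep_nuisance inference controls.
#' @param component,contrast_name labels stored in the stat maps.
#' @return a `cov_stat`: `pos` and `neg` `stat_map`s, `sig_sign` (integer
#'   3D array), `sig_mask`, `stage`, `alpha`.
#' @export
masked_covariate_inference <- function(subject_maps, analysis_mask,
                                       design_df, covariate, stage_mask,
                                       stage = "tstatFC_T2LL",
                                       n_perm = 5000,
                                       params = tfce_params(), seed = 1,
                                       alpha = 0.05, keep_nuisance = TRUE,
                                       component = NA_character_,
                                       contrast_name = NA_character_) {
  if (sum(stage_mask) == 0) stop("empty stage mask")
  if (any(stage_mask & !analysis_mask))
    stop("stage_mask extends outside the analysis mask")
  keep <- as.vector(stage_mask)[as.vector(analysis_mask)]
  Y <- subject_maps[, keep, drop = FALSE]
  fits <- lapply(c(pos = 1, neg = -1), function(sg) {
    spec <- make_covariate_spec(design_df, covariate, contrast_sign = sg,
                                keep_nuisance = keep_nuisance)
    permutation_fwe(Y, spec, params = params, n_perm = n_perm,
                    mask = stage_mask, seed = seed, stage = stage,
                    component = component,
                    contrast_name = sprintf("%s%s", covariate,
                                            if (sg > 0) "+" else "-"))
  })
  sig_pos <- build_stage_mask(fits$pos, alpha)
  sig_neg <- build_stage_mask(fits$neg, alpha)
  sig_sign <- array(0L, dim(stage_mask))
  sig_sign[sig_pos] <- 1L
  sig_sign[sig_neg & !sig_pos] <- -1L
  structure(list(pos = fits$pos, neg = fits$neg, sig_sign = sig_sign,
                 sig_mask = sig_pos | sig_neg, stage = stage,
                 alpha = alpha),
            class = "cov_stat")
}

#' Mean Z value over a mask, per subject
#'
#' @param subject_z_maps subjects x voxels matrix over `analysis_mask`
#'   (e.g. stacked dual-regression z maps).
#' @param mask logical 3D array (nonempty).
#' @param analysis_mask logical 3D array the columns refer to.
#' @return numeric vector, one mean per subject.
#' @export
extract_mean_z <- function(subject_z_maps, mask, analysis_mask) {
  if (sum(mask) == 0) stop("empty mask")
  keep <- as.vector(mask)[as.vector(analysis_mask)]
  rowMeans(subject_z_maps[, keep, drop = FALSE])
}

#' Pearson correlation with Bonferroni correction
#'
#' Sample Pearson r, two-sided p from the t transform with `n - 2` degrees
#' of freedom, and `p_bonferroni = min(1, m_tests * p)`.
#'
#' @param x,y numeric vectors (length >= 3, non-constant).
#' @param m_tests number of tests in the family.
#' @return list with `r`, `p_two_sided`, `p_bonferroni`, `n`.
#' @export
pearson_with_bonferroni <- function(x, y, m_tests = 1) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input series")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, p_two_sided = p, p_bonferroni = min(1, m_tests * p), n = n)
}

#' Sequential masked covariate cascade for one (component, contrast)
#'
#' Stage 1 input: the FC group-difference `stat_map`. Voxels surviving
#' FWE `alpha` form the mask for the T2LL permutation stage; its
#' significant voxels form the mask for the MSSS stage. Masks are strictly
#' nested by construction. Per-subject mean Z values over the T2LL- and
#' MSSS-significant sets give the Pearson statistics against the
#' covariates.
#'
#' @param fc_stat the originating `stat_map` (stage `tstatFC`).
#' @param ms_pe,ms_z MS-subject pe/z map matrices over `analysis_mask`.
#' @param analysis_mask logical 3D array the map columns refer to.
#' @param ms_design design rows of the MS subjects.
#' @param alpha FWE threshold per stage.
#' @param within optional logical 3D array restricting the stage-1 mask to
#'   a network's extent (alterations are interpreted within their RSN).
#' @param n_perm,params,seed,keep_nuisance inference controls.
#' @return a `cascade_result`: nested `masks`, per-stage statistics
#'   (`fc`, `t2ll`, `msss`), and a `pearson` data.frame. Stages after an
#'   empty mask are `NULL`.
#' @export
run_cascade <- function(fc_stat, ms_pe, ms_z, analysis_mask, ms_design,
                        alpha = 0.05, within = NULL, n_perm = 5000,
                        params = tfce_params(), seed = 1,
                        keep_nuisance = TRUE) {
  comp <- fc_stat$component
  ctr <- fc_stat$contrast_name
  sig_fc <- build_stage_mask(fc_stat, alpha)
  if (!is.null(within)) sig_fc <- sig_fc & within
  masks <- list(sig_fc = sig_fc,
                sig_t2ll = NULL, sig_msss = NULL)
  out <- structure(list(masks = masks, fc = fc_stat, t2ll = NULL,
                        msss = NULL, pearson = NULL, alpha = alpha),
                   class = "cascade_result")
  if (sum(masks$sig_fc) == 0) return(out)

  t2 <- masked_covariate_inference(ms_pe, analysis_mask, ms_design, "t2ll",
                                   masks$sig_fc, stage = "tstatFC_T2LL",
                                   n_perm = n_perm, params = params,
                                   seed = fanout_seed(seed, 1L),
                                   alpha = alpha,
                                   keep_nuisance = keep_nuisance,
                                   component = comp, contrast_name = ctr)
  out$t2ll <- t2
  out$masks$sig_t2ll <- t2$sig_mask
  pearson <- list()
  if (sum(t2$sig_mask) > 0) {
    mz <- extract_mean_z(ms_z, t2$sig_mask, analysis_mask)
    pearson$t2ll <- c(list(region = sprintf("%s:%s:T2LL-correlated", comp, ctr),
                           covariate = "t2ll"),
                      pearson_with_bonferroni(mz, ms_design$t2ll))
    ms <- masked_covariate_inference(ms_pe, analysis_mask, ms_design, "msss",
                                     t2$sig_mask,
                                     stage = "tstatFC_T2LL_MSSS",
                                     n_perm = n_perm, params = params,
                                     seed = fanout_seed(seed, 2L),
                                     alpha = alpha,
                                     keep_nuisance = keep_nuisance,
                                     component = comp, contrast_name = ctr)
    out$msss <- ms
    out$masks$sig_msss <- ms$sig_mask
    if (sum(ms$sig_mask) > 0) {
      mz3 <- extract_mean_z(ms_z, ms$sig_mask, analysis_mask)
      pearson$msss <- c(list(region = sprintf("%s:%s:MSSS-correlated", comp, ctr),
                             covariate = "msss"),
                        pearson_with_bonferroni(mz3, ms_design$msss))
    }
  }
  if (length(pearson)) {
    tb <- do.call(rbind, lapply(pearson, as.data.frame))
    # the Bonferroni family is the set of Pearson tests actually run
    m <- nrow(tb)
    tb$p_bonferroni <- pmin(1, tb$p_two_sided * m)
    tb$m_tests <- m
    rownames(tb) <- NULL
    out$pearson <- tb
  }
  out
}

#' Scenario sign inputs from a cascade result
#'
#' Converts one cascade into the three per-voxel sign maps consumed by
#' [classify_scenarios]: the FC contrast direction on the FC-significant
#' mask, and the significant association signs of the T2LL and MSSS
#' stages.
#'
#' @param cascade a `cascade_result`.
#' @param fc_direction `+1` if the originating contrast tested an FC
#'   increase (e.g. MS > HC), `-1` for a decrease.
#' @return list `fc_dir`, `t2ll_sign`, `msss_sign` (integer 3D arrays).
#' @export
cascade_sign_maps <- function(cascade, fc_direction) {
  stopifnot(fc_direction %in% c(-1, 1))
  d <- dim(cascade$masks$sig_fc)
  fc_dir <- array(0L, d); t2s <- array(0L, d); mss <- array(0L, d)
  fc_dir[cascade$masks$sig_fc] <- as.integer(fc_direction)
  if (!is.null(cascade$t2ll)) t2s <- cascade$t2ll$sig_sign
  if (!is.null(cascade$msss)) mss <- cascade$msss$sig_sign
  list(fc_dir = fc_dir, t2ll_sign = t2s, msss_sign = mss)
}
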