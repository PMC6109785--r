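#' Global functional connectivity alteration index (gFC)
#'
#' Scores a network's alteration under one contrast as the sum of |t| over
#' the FWE-significant voxels inside the network's extent — cluster
#' extension enters through the voxel count, magnitude through |t|. The
#' scoring function is pluggable via `score_fun`.
#'
#' @param stat a `stat_map`.
#' @param rsn_mask logical 3D array (network extent, within `stat$mask`).
#' @param alpha FWE significance threshold.
#' @param score_fun function of the significant |t| values; default `sum`.
#' @return list with `gfc` (non-negative score) and `n_sig_voxels`.
#' @export
compute_gfc <- function(stat, rsn_mask, alpha = 0.05, score_fun = sum) {
  stopifnot(all(dim(rsn_mask) == dim(stat$mask)))
  if (any(rsn_mask & !stat$mask))
    stop("rsn_mask extends outside the analysis mask")
  sig <- rsn_mask & !is.na(stat$p_fwe) & stat$p_fwe <= alpha
  n <- sum(sig)
  list(gfc = if (n == 0) 0 else score_fun(abs(stat$t[sig])),
       n_sig_voxels = n)
}

#' Rank networks by their gFC alteration
#'
#' One row per (network, contrast), sorted within each contrast by
#' decreasing gFC; ties broken alphabetically by network name.
#'
#' @param stats list of `stat_map`s, one per (component, contrast).
#' @param atlas named list mapping network name to its logical 3D extent.
#' @param alpha FWE threshold.
#' @param score_fun see [compute_gfc].
#' @return data.frame with `network`, `contrast`, `gfc`, `n_sig_voxels`.
#' @export
rank_networks <- function(stats, atlas, alpha = 0.05, score_fun = sum) {
  keys <- vapply(stats, function(s)
    paste(s$component, s$contrast_name, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop(sprintf("duplicate (component, contrast) pairs: %s",
                 paste(unique(keys[duplicated(keys)]), collapse = "; ")))
  rows <- lapply(stats, function(s) {
    if (!s$component %in% names(atlas))
      stop(sprintf("no atlas mask for component %s", s$component))
    g <- compute_gfc(s, atlas[[s$component]], alpha, score_fun)
    data.frame(network = s$component, contrast = s$contrast_name,
               gfc = g$gfc, n_sig_voxels = g$n_sig_voxels,
               stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  tb <- tb[order(tb$contrast, -tb$gfc, tb$network), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}
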