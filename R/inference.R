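#' GLM specification for voxelwise group inference
#'
#' A subjects x regressors design with a single-EV contrast: the contrast
#' vector is nonzero only on the explanatory variable of interest; the
#' remaining columns (intercept, demographic covariates) are nuisance.
#'
#' @param design subjects x regressors numeric matrix (full column rank).
#' @param ev_of_interest column index of the explanatory variable tested.
#' @param contrast optional contrast vector; defaults to `+1` on
#'   `ev_of_interest` (use `-1` for the opposite one-sided contrast).
#' @param nuisance_idx indices of nuisance columns; defaults to all columns
#'   except `ev_of_interest`.
#' @return a `glm_spec` object.
#' @export
glm_spec <- function(design, ev_of_interest, contrast = NULL,
                     nuisance_idx = NULL) {
  design <- as.matrix(design)
  p <- ncol(design)
  stopifnot(ev_of_interest >= 1, ev_of_interest <= p)
  if (is.null(contrast)) {
    contrast <- rep(0, p)
    contrast[ev_of_interest] <- 1
  }
  if (any(contrast[-ev_of_interest] != 0) || contrast[ev_of_interest] == 0)
    stop("contrast must be nonzero exactly on ev_of_interest")
  if (is.null(nuisance_idx)) nuisance_idx <- setdiff(seq_len(p), ev_of_interest)
  qrd <- qr(design)
  if (qrd$rank < p) {
    dep <- setdiff(seq_len(p), qrd$pivot[seq_len(qrd$rank)])
    stop(sprintf("singular design; dependent columns: %s",
                 paste(dep, collapse = ", ")))
  }
  structure(list(design = design, contrast = contrast,
                 ev_of_interest = ev_of_interest,
                 nuisance_idx = nuisance_idx),
            class = "glm_spec")
}

#' Voxelwise GLM t map
#'
#' Per voxel, ordinary least squares of the subject maps on the full
#' design; returns `t = (contrast' beta) / SE(contrast' beta)`.
#'
#' @param subject_maps subjects x voxels matrix.
#' @param spec a [glm_spec].
#' @return numeric vector of t statistics, one per voxel.
#' @export
fit_glm_tmap <- function(subject_maps, spec) {
  X <- spec$design
  n <- nrow(X); p <- ncol(X)
  if (nrow(subject_maps) != n) stop("subject_maps rows must match the design")
  if (n < p + 2) stop("need at least regressors + 2 subjects")
  qrX <- qr(X)
  beta <- qr.coef(qrX, subject_maps)             # p x V
  res <- subject_maps - X %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  cvec <- spec$contrast
  se <- sqrt(drop(t(cvec) %*% XtXinv %*% cvec) * sigma2)
  tt <- drop(crossprod(cvec, beta)) / se
  tt[se == 0] <- 0
  tt
}

#' TFCE parameters
#'
#' Standard parameterization: extent exponent `E = 0.5`, height exponent
#' `H = 2`, 26-connectivity, integration step `dh` = (max statistic)/100
#' when `dh = 0`.
#'
#' @param E,H extent and height exponents (> 0).
#' @param dh threshold step; 0 selects max/`n_steps` automatically.
#' @param connectivity 6, 18 or 26.
#' @param n_steps number of threshold steps used when `dh = 0`.
#' @return a `tfce_params` object.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = 0, connectivity = 26,
                        n_steps = 100) {
  stopifnot(E > 0, H > 0, dh >= 0, connectivity %in% c(6, 18, 26))
  structure(list(E = E, H = H, dh = dh, connectivity = connectivity,
                 n_steps = n_steps),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel `p`, `TFCE(p) = sum_h e(h,p)^E * h^H * dh` over the
#' threshold ladder `h = dh, 2dh, ...`, where `e(h,p)` is the voxel count
#' of the connected suprathreshold cluster containing `p` at height `h`.
#' Negative values are enhanced on the negated map separately and returned
#' with negative sign.
#'
#' @param t_map numeric 3D array (finite).
#' @param params a [tfce_params].
#' @return 3D array of signed enhanced values.
#' @export
tfce_enhance <- function(t_map, params = tfce_params()) {
  stopifnot(is.array(t_map), length(dim(t_map)) == 3L,
            all(is.finite(t_map)))
  d <- dim(t_map)
  pos <- .cpp_tfce_pos(pmax(as.vector(t_map), 0), d[1], d[2], d[3],
                       params$E, params$H, params$dh, params$connectivity,
                       params$n_steps)
  neg <- .cpp_tfce_pos(pmax(-as.vector(t_map), 0), d[1], d[2], d[3],
                       params$E, params$H, params$dh, params$connectivity,
                       params$n_steps)
  array(pos - neg, d)
}

# all permutations of 1..n (n small), as a list
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in .all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# permuted EV columns: observed first; exhaustive when the number of
# distinct permutations/relabelings does not exceed n_perm
.build_ev_perms <- function(x, n_perm) {
  n <- length(x)
  ux <- unique(x)
  if (length(ux) == 2L) {
    n1 <- sum(x == ux[1])
    n_distinct <- choose(n, n1)
    if (n_distinct <= n_perm) {
      sets <- combn(n, n1)
      evs <- apply(sets, 2, function(s) {
        v <- rep(ux[2], n); v[s] <- ux[1]; v
      })
      obs <- which(colSums(abs(evs - x)) == 0)[1]
      evs <- cbind(x, evs[, -obs, drop = FALSE])
      return(list(evs = evs, exhaustive = TRUE))
    }
  } else if (factorial(n) <= n_perm) {
    perms <- .all_perms(n)
    evs <- vapply(perms, function(p) x[p], numeric(n))
    obs <- which(colSums(abs(evs - x)) == 0)[1]
    evs <- cbind(x, evs[, -obs, drop = FALSE])
    return(list(evs = evs, exhaustive = TRUE))
  }
  evs <- cbind(x, vapply(seq_len(n_perm), function(i) x[sample.int(n)],
                         numeric(n)))
  list(evs = evs, exhaustive = FALSE)
}

#' Permutation inference with TFCE and FWE correction
#'
#' Freedman-Lane scheme: the data are residualized against the nuisance
#' regressors, the explanatory variable of interest is permuted (for a
#' binary EV, group relabelings), and the full model is refit; the null
#' distribution is the image-wide maximum TFCE value per permutation, and
#' `p_fwe(v) = (1 + #{perm maxima >= TFCE(v)}) / (1 + n_perm)`. When the
#' number of distinct permutations does not exceed `n_perm` the set is
#' enumerated exhaustively and the p-value is the exact fraction.
#'
#' @param subject_maps subjects x voxels matrix (columns = in-mask voxels).
#' @param spec a [glm_spec]; the contrast sign selects the tested
#'   direction.
#' @param params a [tfce_params].
#' @param n_perm number of permutations (>= 1).
#' @param mask logical 3D array with `sum(mask) == ncol(subject_maps)`.
#' @param seed integer seed for permutation sampling.
#' @param stage stage tag (`"tstatFC"`, `"tstatFC_T2LL"`,
#'   `"tstatFC_T2LL_MSSS"`).
#' @param component,contrast_name labels stored in the result.
#' @return a `stat_map`: 3D arrays `t`, `tfce`, `p_fwe` (`NA` outside the
#'   mask), the mask, and permutation metadata.
#' @export
permutation_fwe <- function(subject_maps, spec, params = tfce_params(),
                            n_perm = 5000, mask, seed = 1,
                            stage = "tstatFC", component = NA_character_,
                            contrast_name = NA_character_) {
  stopifnot(n_perm >= 1)
  if (sum(mask) == 0) stop("empty analysis mask")
  if (ncol(subject_maps) != sum(mask))
    stop("subject_maps columns must match the mask voxel count")
  X <- spec$design
  ev <- spec$ev_of_interest
  sgn <- sign(spec$contrast[ev])
  x <- sgn * X[, ev]
  Z <- X[, -ev, drop = FALSE]
  if (ncol(Z) == 0 || !any(apply(Z, 2, function(col) all(col == col[1]))))
    Z <- cbind(Z, 1)                     # ensure an intercept in the nuisance
  if (stats::sd(x) == 0) stop("constant explanatory variable")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ep <- .build_ev_perms(x, n_perm)
  d <- dim(mask)
  mask_idx <- which(as.vector(mask)) - 1L
  fit <- .cpp_perm_engine(subject_maps, Z, ep$evs, mask_idx,
                          d[1], d[2], d[3],
                          params$E, params$H, params$dh,
                          params$connectivity, params$n_steps)
  n_total <- ncol(ep$evs)
  p_fwe <- vapply(fit$tfce, function(o) mean(fit$null_max >= o), numeric(1))
  structure(list(stage = stage, component = component,
                 contrast_name = contrast_name,
                 t = unmask(fit$t, mask),
                 tfce = unmask(fit$tfce, mask),
                 p_fwe = unmask(p_fwe, mask, fill = NA_real_),
                 mask = mask,
                 n_perm = n_total - 1L,
                 exhaustive = ep$exhaustive,
                 null_max = fit$null_max,
                 params = params, seed = seed),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  nsig <- sum(x$p_fwe <= 0.05, na.rm = TRUE)
  cat(sprintf("<stat_map> stage=%s component=%s contrast=%s: %d/%d voxels FWE p<=0.05 (%s, %d perms)\n",
              x$stage, x$component, x$contrast_name, nsig, sum(x$mask),
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}

#' Build the two-group design and contrast used by the pipeline
#'
#' EV of interest: group indicator (1 for `group_pos`, 0 otherwise);
#' nuisance: intercept plus mean-centered age, gender indicator, education
#' and GM ratio.
#'
#' @param design_df cohort design data.frame.
#' @param group_pos group coded 1 in the indicator.
#' @param contrast_sign `+1` tests `group_pos` > other, `-1` the reverse.
#' @param rows optional row subset.
#' @param group_col column holding the group label.
#' @param covariates nuisance covariate columns.
#' @return a [glm_spec].
#' @export
make_group_spec <- function(design_df, group_pos = "MS", contrast_sign = 1,
                            rows = NULL, group_col = "group",
                            covariates = c("age", "gender", "education",
                                           "gm_ratio")) {
  if (!is.null(rows)) design_df <- design_df[rows, , drop = FALSE]
  g <- as.numeric(design_df[[group_col]] == group_pos)
  nuis <- .nuisance_matrix(design_df, covariates)
  X <- cbind(group = g, intercept = 1, nuis)
  spec <- glm_spec(X, ev_of_interest = 1)
  spec$contrast[1] <- contrast_sign
  spec
}

#' Build the covariate design used by the cascade stages
#'
#' EV of interest: the mean-centered covariate; nuisance: intercept plus
#' (optionally) the demographic covariates.
#'
#' @param design_df design rows of the included subjects.
#' @param covariate column name of the EV (e.g. `"t2ll"`).
#' @param contrast_sign `+1` or `-1`.
#' @param keep_nuisance retain the demographic nuisance covariates
#'   (default `TRUE`).
#' @param covariates nuisance covariate columns.
#' @return a [glm_spec].
#' @export
make_covariate_spec <- function(design_df, covariate, contrast_sign = 1,
                                keep_nuisance = TRUE,
                                covariates = c("age", "gender", "education",
                                               "gm_ratio")) {
  x <- design_df[[covariate]]
  if (any(is.na(x))) stop(sprintf("covariate %s undefined for %d subjects",
                                  covariate, sum(is.na(x))))
  if (stats::sd(x) == 0) stop("constant covariate")
  X <- cbind(ev = x - mean(x), intercept = 1)
  if (keep_nuisance) X <- cbind(X, .nuisance_matrix(design_df, covariates))
  spec <- glm_spec(X, ev_of_interest = 1)
  spec$contrast[1] <- contrast_sign
  spec
}

.nuisance_matrix <- function(design_df, covariates) {
  cols <- lapply(covariates, function(cv) {
    v <- design_df[[cv]]
    if (cv == "gender") v <- as.numeric(v == "F")
    v - mean(v)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- covariates
  out
}
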