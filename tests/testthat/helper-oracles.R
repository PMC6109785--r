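# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: TFCE by per-threshold relabeling,
# group statistics by textbook formulas, permutation p-values by explicit
# enumeration.

# brute-force TFCE: explicit threshold sweep with BFS cluster labeling
bf_tfce <- function(img, E = 0.5, H = 2, dh, conn = 26) {
  d <- dim(img)
  out <- array(0, d)
  mx <- max(img)
  if (mx <= 0) return(out)
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- nb[rowSums(abs(nb)) > 0, ]
  if (conn == 6) nb <- nb[rowSums(abs(nb)) == 1, ]
  if (conn == 18) nb <- nb[rowSums(abs(nb)) <= 2, ]
  for (h in seq(dh, mx, by = dh)) {
    supra <- img >= h
    lab <- array(0L, d)
    cur <- 0L
    for (i in which(supra)) {
      if (lab[i]) next
      cur <- cur + 1L
      queue <- i
      lab[i] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        z <- (v - 1) %/% (d[1] * d[2]); r <- (v - 1) %% (d[1] * d[2])
        y <- r %/% d[1]; x <- r %% d[1]
        for (k in seq_len(nrow(nb))) {
          xx <- x + nb$dx[k]; yy <- y + nb$dy[k]; zz <- z + nb$dz[k]
          if (xx < 0 || yy < 0 || zz < 0 ||
              xx >= d[1] || yy >= d[2] || zz >= d[3]) next
          w <- 1 + xx + d[1] * (yy + d[2] * zz)
          if (supra[w] && !lab[w]) { lab[w] <- cur; queue <- c(queue, w) }
        }
      }
    }
    for (cl in seq_len(cur)) {
      mem <- lab == cl
      out[mem] <- out[mem] + sum(mem)^E * h^H * dh
    }
  }
  out
}

# signed brute-force TFCE (positive and negated parts separately)
bf_tfce_signed <- function(img, E = 0.5, H = 2, dh, conn = 26) {
  bf_tfce(pmax(img, 0), E, H, dh, conn) -
    bf_tfce(pmax(-img, 0), E, H, dh, conn)
}

# classic pooled-variance two-sample t (group a minus group b)
two_sample_t <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# exhaustive relabeling oracle for one-sided max-TFCE FWE p-values:
# enumerates every assignment of n1 subjects to group 1, computes the
# voxelwise t map with plain OLS, enhances with brute-force TFCE, and
# takes the fraction of relabelings whose image-wide maximum reaches each
# observed voxel value
enum_fwe_oracle <- function(Y, group, mask, E = 0.5, H = 2, conn = 26,
                            n_steps = 100) {
  n <- length(group)
  n1 <- sum(group == 1)
  d <- dim(mask)
  tmap_of <- function(g) {
    X <- cbind(g, 1)
    beta <- qr.coef(qr(X), Y)
    res <- Y - X %*% beta
    sigma2 <- colSums(res^2) / (n - 2)
    XtXinv <- chol2inv(qr.R(qr(X)))
    tt <- beta[1, ] / sqrt(XtXinv[1, 1] * sigma2)
    tt[sigma2 == 0] <- 0
    tt
  }
  embed <- function(v) { a <- array(0, d); a[mask] <- v; a }
  t_obs <- tmap_of(group)
  dh <- max(c(pmax(t_obs, 0), 0)) / n_steps
  if (dh <= 0) dh <- 1e-3
  tfce_obs <- bf_tfce(pmax(embed(t_obs), 0), E, H, dh, conn)[mask]
  sets <- combn(n, n1)
  maxima <- apply(sets, 2, function(s) {
    g <- rep(0, n); g[s] <- 1
    enh <- bf_tfce(pmax(embed(tmap_of(g)), 0), E, H, dh, conn)
    max(enh[mask])
  })
  p <- vapply(tfce_obs, function(o) mean(maxima >= o), numeric(1))
  list(p = p, t = t_obs, tfce = tfce_obs, n_relabelings = ncol(sets))
}

# literal transcription of the Laplace evidence for probabilistic PCA,
# kept scalar and loop-based, independent of the package's vectorized path
minka_evidence_literal <- function(lambda, N, k) {
  d <- length(lambda)
  sigma2 <- sum(lambda[(k + 1):d]) / (d - k)
  m <- d * k - k * (k + 1) / 2
  log_pU <- 0
  for (i in 1:k) {
    log_pU <- log_pU + lgamma((d - i + 1) / 2) -
      ((d - i + 1) / 2) * log(pi)
  }
  log_pU <- log_pU - k * log(2)
  lam_hat <- ifelse(seq_len(d) <= k, lambda, sigma2)
  log_Az <- 0
  for (i in 1:k) {
    for (j in (i + 1):d) {
      term <- (1 / lam_hat[j] - 1 / lam_hat[i]) * (lambda[i] - lambda[j]) * N
      log_Az <- log_Az + log(max(term, .Machine$double.eps))
    }
  }
  prod_lam <- 0
  for (i in 1:k) prod_lam <- prod_lam + log(lambda[i])
  log_pU - (N / 2) * prod_lam - (N * (d - k) / 2) * log(sigma2) +
    ((m + k) / 2) * log(2 * pi) - log_Az / 2 - (k / 2) * log(N)
}

# a small planted cohort whose group maps are the templates themselves
# (skips ICA where the property under test does not involve it)
dualreg_with_templates <- function(cohort, preprocessed = NULL,
                                   varnorm = FALSE) {
  vols <- if (is.null(preprocessed)) cohort$volumes else preprocessed
  maps <- do.call(rbind, lapply(cohort$templates,
                                function(tp) as.vector(tp$map)))
  dual_regression(vols, maps)
}

# benchmark cohort for map-recovery checks
recovery_cohort <- function(noise_sd, seed, n = 12, grid = c(14, 14, 10),
                            n_networks = 4, n_timepoints = 120) {
  cfg <- cohort_config(n_hc = ceiling(n / 2), n_ms = floor(n / 2),
                       n_ms_short = floor(n / 4), grid_dims = grid,
                       n_networks = n_networks, noise_sd = noise_sd,
                       scenarios = NULL, n_timepoints = n_timepoints)
  simulate_cohort(cfg, seed = seed)
}
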