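test_that("stage masks threshold the FWE p map exactly", {
  dims <- c(4, 4, 3)
  mask <- array(TRUE, dims)
  p <- array(1, dims)
  sig <- sample(prod(dims), 7)
  p[sig] <- 0.04
  st <- structure(list(p_fwe = p, mask = mask), class = "stat_map")
  expect_equal(sum(build_stage_mask(st, 0.05)), 7)
  expect_true(all(which(build_stage_mask(st, 0.05)) %in% sig))
  st$p_fwe[] <- 1
  expect_equal(sum(build_stage_mask(st, 0.05)), 0)
  expect_true(all(build_stage_mask(st, 1)))
})

test_that("mean Z extraction is the plain arithmetic mean over the mask", {
  dims <- c(4, 4, 3)
  amask <- array(TRUE, dims)
  Z <- matrix(rnorm(6 * prod(dims)), 6)
  m <- array(FALSE, dims); m[sample(prod(dims), 10)] <- TRUE
  out <- extract_mean_z(Z, m, amask)
  expect_equal(out, rowMeans(Z[, as.vector(m)]), tolerance = 1e-12)
  # constant map and singleton mask
  Zc <- matrix(2.5, 3, prod(dims))
  expect_equal(extract_mean_z(Zc, m, amask), rep(2.5, 3))
  m1 <- array(FALSE, dims); m1[2, 3, 1] <- TRUE
  expect_equal(extract_mean_z(Z, m1, amask), Z[, which(as.vector(m1))])
  expect_error(extract_mean_z(Z, array(FALSE, dims), amask), "empty")
})

test_that("Pearson statistics match the closed-form covariance formula", {
  out <- pearson_with_bonferroni(1:10, 2 * (1:10) + 1)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_lt(out$p_two_sided, 1e-12)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  out <- pearson_with_bonferroni(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(out$p_two_sided, 2 * pt(abs(t_hand), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # Bonferroni multiplies and caps
  p <- pearson_with_bonferroni(rnorm(20), rnorm(20), m_tests = 20)
  expect_equal(p$p_bonferroni, min(1, 20 * p$p_two_sided))
  expect_error(pearson_with_bonferroni(rep(1, 5), rnorm(5)), "constant")
})

make_covariate_bench <- function(seed, n = 62, dims = c(10, 10, 6),
                                 slope = 0.08, noise = 0.3,
                                 region_frac = 0.1) {
  set.seed(seed)
  nvox <- prod(dims)
  region <- array(FALSE, dims)
  region[3:5, 3:5, 2:4] <- TRUE
  t2ll <- rlnorm(n, log(16.63) - 0.5, 1)
  msss <- runif(n, 0, 6)
  Y <- matrix(rnorm(n * nvox, 0, noise), n, nvox)
  Y[, as.vector(region)] <- Y[, as.vector(region)] + slope * t2ll
  design <- data.frame(t2ll = t2ll, msss = msss, age = rnorm(n, 38, 8),
                       gender = sample(c("F", "M"), n, TRUE),
                       education = rnorm(n, 13, 2),
                       gm_ratio = rnorm(n, 0.45, 0.03))
  list(Y = Y, design = design, region = region, dims = dims)
}

test_that("a planted covariate slope is detected inside the stage mask", {
  b <- make_covariate_bench(1)
  amask <- array(TRUE, b$dims)
  cv <- masked_covariate_inference(b$Y, amask, b$design, "t2ll",
                                   stage_mask = amask, n_perm = 300,
                                   seed = 5)
  hit <- cv$sig_sign[b$region]
  expect_gte(mean(hit == 1), 0.5)
  # masking contract: excluding the planted region removes it entirely
  excl <- amask & !b$region
  cv2 <- masked_covariate_inference(b$Y, amask, b$design, "t2ll",
                                    stage_mask = excl, n_perm = 100,
                                    seed = 5)
  expect_true(all(cv2$sig_sign[b$region] == 0))
  expect_true(all(build_stage_mask(cv2$pos, 0.05)[!excl] == FALSE))
})

test_that("covariate inference is calibrated under the null", {
  hits <- 0
  n_rep <- 100
  amask <- array(TRUE, c(8, 8, 4))
  for (i in seq_len(n_rep)) {
    set.seed(i)
    n <- 30
    Y <- matrix(rnorm(n * 256), n, 256)
    design <- data.frame(t2ll = rlnorm(n, 2.3, 1),
                         msss = runif(n, 0, 6),
                         age = rnorm(n, 38, 8),
                         gender = sample(c("F", "M"), n, TRUE),
                         education = rnorm(n, 13, 2),
                         gm_ratio = rnorm(n, 0.45, 0.03))
    cv <- masked_covariate_inference(Y, amask, design, "t2ll",
                                     stage_mask = amask, n_perm = 250,
                                     seed = 1000 + i)
    hits <- hits + (sum(cv$sig_sign == 1) > 0)
  }
  expect_lte(hits / n_rep, 0.09)
  expect_error(masked_covariate_inference(matrix(rnorm(30 * 256), 30), amask,
                                          data.frame(t2ll = rep(2, 30)),
                                          "t2ll", amask, n_perm = 10),
               "constant")
})

test_that("cascade masks are strictly nested with sign-consistent summaries", {
  b <- make_covariate_bench(3, slope = 0.08)
  dims <- b$dims
  amask <- array(TRUE, dims)
  # plant a matching msss association inside the same region
  b$Y[, as.vector(b$region)] <- b$Y[, as.vector(b$region)] +
    0.4 * b$design$msss
  # an upstream FC stat that is significant over a superset of the region
  fc_sig <- array(FALSE, dims); fc_sig[2:6, 2:6, 1:5] <- TRUE
  p <- array(1, dims); p[fc_sig] <- 0.01
  tmap <- array(0, dims); tmap[fc_sig] <- 4
  fc_stat <- structure(list(stage = "tstatFC", component = "MVN",
                            contrast_name = "MS>HC", t = tmap,
                            tfce = tmap, p_fwe = p, mask = amask,
                            n_perm = 100L, exhaustive = FALSE,
                            params = tfce_params(), seed = 1L),
                       class = "stat_map")
  casc <- run_cascade(fc_stat, b$Y, b$Y, amask, b$design,
                      n_perm = 300, seed = 9)
  expect_true(all(casc$masks$sig_t2ll <= casc$masks$sig_fc))
  expect_true(all(casc$masks$sig_msss <= casc$masks$sig_t2ll))
  expect_gt(sum(casc$masks$sig_t2ll), 0)
  expect_gt(sum(casc$masks$sig_msss), 0)
  # pearson summary signs agree with the planted positive associations
  expect_true(all(casc$pearson$r > 0))
  expect_equal(casc$pearson$m_tests, rep(2, 2))
  expect_equal(casc$pearson$p_bonferroni,
               pmin(1, casc$pearson$p_two_sided * 2))
  # stage tags
  expect_equal(casc$t2ll$pos$stage, "tstatFC_T2LL")
  expect_equal(casc$msss$pos$stage, "tstatFC_T2LL_MSSS")
})
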