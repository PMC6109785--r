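test_that("the voxelwise GLM t map matches textbook oracles", {
  # identical groups give t = 0
  y0 <- matrix(rep(c(1, 2, 3, 4, 5), 2), ncol = 1)
  spec0 <- glm_spec(cbind(g = rep(0:1, each = 5), icpt = 1), 1)
  expect_equal(fit_glm_tmap(y0, spec0), 0)
  # 4 vs 4 against the pooled-variance two-sample formula
  y <- matrix(c(10, 11, 12, 13, 0, 1, 2, 3), ncol = 1)
  g <- rep(1:0, each = 4)
  spec <- glm_spec(cbind(g = g, icpt = 1), 1)
  expect_equal(fit_glm_tmap(y, spec),
               two_sample_t(y[g == 1], y[g == 0]), tolerance = 1e-10)
  # a nuisance regressor orthogonal to contrast and data leaves the
  # contrast estimate and residual untouched; t rescales only through the
  # lost degree of freedom
  nuis <- c(1, -1, 1, -1, -1, 1, -1, 1)
  expect_lt(abs(crossprod(nuis, y)), 1e-12)
  spec2 <- glm_spec(cbind(g = g, icpt = 1, n = nuis), 1)
  expect_equal(fit_glm_tmap(y, spec2),
               fit_glm_tmap(y, spec) * sqrt(5 / 6), tolerance = 1e-8)
  # singular designs are rejected naming the dependent columns
  expect_error(glm_spec(cbind(g, 1, 2 * g), 1), "dependent columns: 3")
})

test_that("TFCE matches its closed form and a brute-force threshold sweep", {
  # all-zero map
  z <- array(0, c(5, 5, 4))
  expect_true(all(tfce_enhance(z) == 0))
  # single voxel of height 3: integral of h^2 dh from 0 to 3 = 9
  img <- array(0, c(5, 5, 5)); img[3, 3, 3] <- 3
  val <- tfce_enhance(img, tfce_params(E = 0.5, H = 2, dh = 0.03))[3, 3, 3]
  expect_lt(abs(val - 9) / 9, 0.02)
  # 1D ridge against the explicit sweep oracle
  ridge <- array(0, c(7, 3, 3))
  ridge[2:6, 2, 2] <- c(1, 2, 3, 2, 1)
  e1 <- tfce_enhance(ridge, tfce_params(dh = 0.01))
  e2 <- bf_tfce(ridge, dh = 0.01)
  expect_lt(max(abs(e1 - e2)) / max(e2), 0.01)
  # random signed 3D maps, all three connectivities
  set.seed(31)
  for (conn in c(6, 18, 26)) {
    img <- array(rnorm(6 * 6 * 5), c(6, 6, 5)) * 2
    e1 <- tfce_enhance(img, tfce_params(dh = 0.05, connectivity = conn))
    e2 <- bf_tfce_signed(img, dh = 0.05, conn = conn)
    expect_lt(max(abs(e1 - e2)) / max(abs(e2)), 0.01)
  }
})

test_that("TFCE is monotone in voxel height", {
  set.seed(7)
  for (rep in 1:5) {
    img <- array(pmax(rnorm(6 * 6 * 5), 0), c(6, 6, 5))
    p <- tfce_params(dh = 0.02)
    base <- tfce_enhance(img, p)
    img2 <- img
    v <- sample(length(img), 1)
    img2[v] <- img2[v] + runif(1, 0.1, 1)
    bumped <- tfce_enhance(img2, p)
    expect_true(all(bumped >= base - 1e-10))
  }
})

test_that("small two-group instances are enumerated exactly", {
  set.seed(12)
  mask <- array(TRUE, c(4, 4, 3))
  Y <- matrix(rnorm(8 * 48), 8, 48)
  Y[1:4, 10:14] <- Y[1:4, 10:14] + 2          # a planted cluster
  g <- rep(1:0, each = 4)
  spec <- glm_spec(cbind(g = g, icpt = 1), 1)
  st <- permutation_fwe(Y, spec, n_perm = 100, mask = mask, seed = 1)
  expect_true(st$exhaustive)
  expect_equal(st$n_perm, choose(8, 4) - 1)
  oracle <- enum_fwe_oracle(Y, g, mask)
  expect_equal(st$p_fwe[mask], oracle$p, tolerance = 1e-12)
  expect_equal(st$t[mask], oracle$t, tolerance = 1e-10)
  # p floor is 1/(number of relabelings)
  expect_gte(min(st$p_fwe, na.rm = TRUE), 1 / 70)
})

test_that("sampled and enumerated p agree whenever enumeration is possible", {
  set.seed(4)
  mask <- array(TRUE, c(3, 3, 2))
  for (n1 in c(3, 4)) {
    n <- n1 + 4
    Y <- matrix(rnorm(n * 18), n, 18)
    g <- c(rep(1, n1), rep(0, 4))
    spec <- glm_spec(cbind(g = g, icpt = 1), 1)
    st <- permutation_fwe(Y, spec, n_perm = 5000, mask = mask, seed = 2)
    expect_true(st$exhaustive)
    oracle <- enum_fwe_oracle(Y, g, mask)
    expect_equal(st$p_fwe[mask], oracle$p, tolerance = 1e-12)
  }
})

test_that("a unit alpha makes every in-mask voxel significant", {
  set.seed(5)
  mask <- array(TRUE, c(3, 3, 2))
  Y <- matrix(rnorm(10 * 18), 10, 18)
  spec <- glm_spec(cbind(g = rep(0:1, 5), icpt = 1), 1)
  st <- permutation_fwe(Y, spec, n_perm = 50, mask = mask, seed = 3)
  expect_true(all(build_stage_mask(st, alpha = 1) == mask))
  expect_error(permutation_fwe(Y, spec, n_perm = 50,
                               mask = array(FALSE, c(3, 3, 2)), seed = 3),
               "empty")
})

test_that("the Freedman-Lane observed statistic equals the raw full-model t", {
  set.seed(6)
  mask <- array(TRUE, c(4, 3, 2))
  n <- 14
  Y <- matrix(rnorm(n * 24), n, 24)
  X <- cbind(g = rep(0:1, 7), icpt = 1, age = rnorm(n), gm = rnorm(n))
  spec <- glm_spec(X, 1)
  st <- permutation_fwe(Y, spec, n_perm = 200, mask = mask, seed = 9)
  expect_equal(st$t[mask], fit_glm_tmap(Y, spec), tolerance = 1e-8)
})

test_that("negating the contrast tests the opposite direction", {
  set.seed(16)
  mask <- array(TRUE, c(3, 3, 2))
  Y <- matrix(rnorm(12 * 18), 12, 18)
  Y[1:6, 5] <- Y[1:6, 5] + 3
  g <- rep(1:0, each = 6)
  pos <- glm_spec(cbind(g = g, icpt = 1), 1)
  neg <- glm_spec(cbind(g = g, icpt = 1), 1, contrast = c(-1, 0))
  st_pos <- permutation_fwe(Y, pos, n_perm = 500, mask = mask, seed = 2)
  st_neg <- permutation_fwe(Y, neg, n_perm = 500, mask = mask, seed = 2)
  expect_equal(st_pos$t[mask], -st_neg$t[mask], tolerance = 1e-10)
  expect_lt(st_pos$p_fwe[2, 2, 1], 0.05)   # voxel 5 -> index (2,2,1)
  expect_gt(st_neg$p_fwe[2, 2, 1], 0.5)
})
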