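test_that("network templates are normalized, separated and reproducible", {
  tp <- make_rsn_templates(c(12, 12, 12), 4, seed = 3)
  expect_length(tp, 4)
  for (t in tp) {
    expect_equal(max(t$map), 1)
    expect_true(all(t$map >= 0 & t$map <= 1))
  }
  # suprathreshold extents pairwise disjoint
  masks <- lapply(tp, template_mask)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(any(masks[[i]] & masks[[j]]))
  # bit-identical under the same seed
  expect_identical(make_rsn_templates(c(10, 10, 10), 2, seed = 7),
                   make_rsn_templates(c(10, 10, 10), 2, seed = 7))
})

test_that("template placement fails loudly on an undersized grid", {
  expect_error(make_rsn_templates(c(6, 12, 12), 2, seed = 1), "dimension 1")
  expect_error(make_rsn_templates(c(20, 20, 8), 40, seed = 1),
               "limiting")
})

test_that("a noiseless single-network subject is rank one over time", {
  tp <- make_rsn_templates(c(10, 10, 8), 2, seed = 2)[1]
  row <- data.frame(subject_id = "s1", group = "HC", subgroup = "none",
                    age = 30, gender = "F", education = 12,
                    gm_ratio = 0.45, t2ll = NA, msss = NA,
                    disease_duration = NA)
  s <- simulate_subject(tp, row, list(), n_timepoints = 60, noise_sd = 0,
                        seed = 4)
  supra <- as.vector(template_mask(tp[[1]]))
  m <- vol_matrix(s$vol)[, supra]
  sv <- svd(m)$d
  expect_gt(sv[1], 1e-6)
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("group labels with zero effects leave the generative model unchanged", {
  tp <- make_rsn_templates(c(10, 10, 8), 2, seed = 2)
  sc <- list(scenario_region_spec("1", template_mask(tp[[1]]), tp[[1]]$name,
                                  fc_effect = 0, t2ll_slope = 0,
                                  msss_slope = 0))
  base <- data.frame(subject_id = "s1", group = "HC", subgroup = "none",
                     age = 30, gender = "F", education = 12,
                     gm_ratio = 0.45, t2ll = NA, msss = NA,
                     disease_duration = NA)
  ms <- base
  ms$group <- "MS"; ms$subgroup <- "MS_long"
  ms$t2ll <- 20; ms$msss <- 3; ms$disease_duration <- 8
  cfg <- cohort_config(subgroup_shift = 0)
  a <- simulate_subject(tp, base, sc, n_timepoints = 60, seed = 11,
                        config = cfg)
  b <- simulate_subject(tp, ms, sc, n_timepoints = 60, seed = 11,
                        config = cfg)
  expect_identical(a$vol$data, b$vol$data)
})

test_that("coupling is linear in the lesion-load covariate", {
  tp <- make_rsn_templates(c(10, 10, 8), 2, seed = 2)
  sc <- list(scenario_region_spec("3b", template_mask(tp[[1]]),
                                  tp[[1]]$name, fc_effect = 0,
                                  t2ll_slope = 0.05, msss_slope = 0))
  row <- data.frame(subject_id = "s1", group = "MS", subgroup = "MS_long",
                    age = 30, gender = "F", education = 12,
                    gm_ratio = 0.45, t2ll = 20, msss = 3,
                    disease_duration = 8)
  row0 <- row; row0$t2ll <- 0
  a <- simulate_subject(tp, row, sc, seed = 5)
  b <- simulate_subject(tp, row0, sc, seed = 5)
  expect_equal(a$coupling[tp[[1]]$name] - b$coupling[tp[[1]]$name],
               c(MVN = 1.0))
})

test_that("MS subjects without covariate metadata are rejected", {
  tp <- make_rsn_templates(c(10, 10, 8), 2, seed = 2)
  sc <- list(scenario_region_spec("1", template_mask(tp[[1]]),
                                  tp[[1]]$name, -0.5, -0.02))
  row <- data.frame(subject_id = "s1", group = "MS", subgroup = "MS_long",
                    age = 30, gender = "F", education = 12,
                    gm_ratio = 0.45, t2ll = NA, msss = NA,
                    disease_duration = 8)
  expect_error(simulate_subject(tp, row, sc, seed = 1), "t2ll/msss")
})

test_that("cohort simulation is reproducible and carries full ground truth", {
  cfg <- cohort_config(n_hc = 4, n_ms = 6, n_ms_short = 3,
                       grid_dims = c(12, 12, 10), n_networks = 6,
                       n_timepoints = 40)
  co <- simulate_cohort(cfg, seed = 9)
  expect_equal(nrow(co$design), 10)
  # one distinct nonzero label per planted scenario
  expect_setequal(setdiff(unique(as.vector(co$ground_truth$scenario_map)), 0L),
                  c(1L, 2L, 31L, 32L, 41L, 42L))
  # scenario map nonzero exactly on the union of region masks
  union_mask <- Reduce(`|`, lapply(co$scenarios, `[[`, "region_mask"))
  expect_identical(co$ground_truth$scenario_map != 0L, union_mask)
  co2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(co$volumes[[3]]$data, co2$volumes[[3]]$data)
  expect_identical(co$design, co2$design)
  # subgroup duration invariants
  expect_true(all(co$design$disease_duration[co$design$subgroup ==
                                               "MS_short"] <= 5))
  dd_long <- co$design$disease_duration[co$design$subgroup == "MS_long"]
  expect_true(all(dd_long > 5 & dd_long <= 15))
  # HC covariates stay missing
  hc <- co$design$group == "HC"
  expect_true(all(is.na(co$design$t2ll[hc])))
  expect_true(all(is.na(co$design$msss[hc])))
})

test_that("a scenario region spanning two templates is rejected", {
  tp <- make_rsn_templates(c(14, 14, 10), 2, seed = 2)
  bad <- template_mask(tp[[1]]) | template_mask(tp[[2]])
  sc <- list(scenario_region_spec("1", bad, tp[[1]]$name, -0.5, -0.02))
  expect_error(validate_scenarios(sc, tp), "overlaps 2 template")
})

test_that("planted coupling-covariate correlation is recovered from the truth", {
  # slope and jitter chosen for a population coupling~T2LL correlation of 0.6
  sd_pop <- sqrt((exp(1) - 1) * exp(2 * (log(16.63) - 0.5) + 1))
  slope <- 0.02
  jitter <- slope * sd_pop * sqrt(1 / 0.6^2 - 1)
  cfg <- cohort_config(n_hc = 0, n_ms = 62, n_ms_short = 31,
                       grid_dims = c(12, 12, 10), n_networks = 2,
                       coupling_jitter_sd = jitter,
                       scenarios = "3b", fc_shift = 0,
                       t2ll_slope_mag = slope, msss_slope_mag = 0)
  rs <- vapply(1:100, function(s) {
    tr <- simulate_truth(cfg, seed = s)
    ms <- tr$design$group == "MS"
    cor(tr$coupling[ms, tr$scenarios[[1]]$network], tr$design$t2ll[ms])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.15)
})

test_that("null cohorts give t-distributed voxelwise group statistics", {
  # pe maps of a zero-effect cohort, pooled over seeds: two-group t must
  # follow the t distribution with n - p degrees of freedom
  tvals <- c()
  for (s in 1:3) {
    cfg <- cohort_config(n_hc = 8, n_ms = 8, n_ms_short = 4,
                         grid_dims = c(14, 14, 9), n_networks = 2,
                         scenarios = NULL, coupling_jitter_sd = 0,
                         n_timepoints = 60)
    co <- simulate_cohort(cfg, seed = 100 + s)
    sm <- dualreg_with_templates(co)
    pe <- stack_component(sm, 1, "pe")
    g <- as.numeric(co$design$group == "MS")
    spec <- glm_spec(cbind(g, 1), 1)
    tvals <- c(tvals, fit_glm_tmap(pe, spec))
  }
  expect_gte(length(tvals), 5000)
  ks <- stats::ks.test(tvals, stats::pt, df = 14)
  expect_gt(ks$p.value, 0.01)
})

test_that("regression of true coupling on T2LL recovers the planted slope", {
  cfg <- cohort_config(grid_dims = c(12, 12, 10), n_networks = 6,
                       scenarios = c("3b"))
  tr <- simulate_truth(cfg, seed = 21)
  ms <- tr$design$group == "MS"
  sc <- tr$scenarios[[1]]
  fit <- stats::lm(tr$coupling[ms, sc$network] ~ tr$design$t2ll[ms] +
                     tr$design$msss[ms])
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - sc$t2ll_slope), 2 * est["Std. Error"])
})

test_that("cohorts round-trip through NIfTI/TSV/JSON on disk", {
  cfg <- cohort_config(n_hc = 2, n_ms = 2, n_ms_short = 1,
                       grid_dims = c(10, 10, 8), n_networks = 2,
                       scenarios = c("1", "2"), n_timepoints = 40)
  co <- simulate_cohort(cfg, seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "sub-001.nii.gz")))
  v <- read_volume(file.path(dir, "sub-001.nii.gz"),
                   mask = co$volumes[[1]]$mask)
  expect_equal(v$data, co$volumes[[1]]$data, tolerance = 1e-6)
  expect_equal(v$tr, 2.5, tolerance = 1e-6)
  des <- read.delim(file.path(dir, "design.tsv"))
  expect_equal(des$subject_id, co$design$subject_id)
  leg <- jsonlite::read_json(file.path(dir, "scenario_legend.json"))
  expect_equal(leg[["32"]], "false functional compensation")
})

test_that("the truth-only generator matches the full cohort generator", {
  cfg <- cohort_config(n_hc = 3, n_ms = 5, n_ms_short = 3,
                       grid_dims = c(12, 12, 10), n_networks = 6,
                       n_timepoints = 40)
  co <- simulate_cohort(cfg, seed = 13)
  tr <- simulate_truth(cfg, seed = 13)
  expect_identical(tr$design, co$design)
  expect_identical(tr$coupling, co$ground_truth$coupling)
  expect_identical(tr$scenario_map, co$ground_truth$scenario_map)
})
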