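sign_maps <- function(fc, t2, ms, dims = c(2, 2, 1)) {
  list(fc = array(fc, dims), t2 = array(t2, dims), ms = array(ms, dims))
}

test_that("the decision table reproduces the mechanism assignments", {
  d <- c(2, 2, 1)
  # increased FC negatively tied to lesion load = true compensation,
  # whatever the MSSS stage says
  for (ms in c(-1L, 0L, 1L)) {
    s <- sign_maps(1L, -1L, ms, d)
    out <- classify_scenarios(s$fc, s$t2, array(0L, d))
    expect_true(all(out$labels == 2L))
  }
  # increased FC, positive T2LL and MSSS associations = false compensation
  out <- classify_scenarios(array(1L, d), array(1L, d), array(1L, d))
  expect_true(all(out$labels == 32L))
  expect_equal(out$legend[["32"]], "false functional compensation")
  # reduced FC with negative T2LL association = lesion-driven reduction
  out <- classify_scenarios(array(-1L, d), array(-1L, d), array(0L, d))
  expect_true(all(out$labels == 1L))
  # the remaining sign patterns
  out <- classify_scenarios(array(1L, d), array(1L, d), array(-1L, d))
  expect_true(all(out$labels == 31L))
  out <- classify_scenarios(array(-1L, d), array(1L, d), array(-1L, d))
  expect_true(all(out$labels == 41L))
  out <- classify_scenarios(array(-1L, d), array(1L, d), array(1L, d))
  expect_true(all(out$labels == 42L))
  # all-zero input, no T2LL significance, and an unresolved MSSS stage
  out <- classify_scenarios(array(0L, d), array(0L, d), array(0L, d))
  expect_true(all(out$labels == 0L))
  out <- classify_scenarios(array(1L, d), array(0L, d), array(0L, d))
  expect_true(all(out$labels == 0L))
  out <- classify_scenarios(array(1L, d), array(1L, d), array(0L, d))
  expect_true(all(out$labels == 0L))
})

test_that("the alternative 4a/4b convention swaps only the MSSS signs", {
  d <- c(2, 2, 1)
  out <- classify_scenarios(array(-1L, d), array(1L, d), array(1L, d),
                            convention = "methods")
  expect_true(all(out$labels == 41L))
  out <- classify_scenarios(array(-1L, d), array(1L, d), array(-1L, d),
                            convention = "methods")
  expect_true(all(out$labels == 42L))
  # 3a/3b unchanged
  out <- classify_scenarios(array(1L, d), array(1L, d), array(1L, d),
                            convention = "methods")
  expect_true(all(out$labels == 32L))
})

test_that("precondition violations report the offending voxel count", {
  d <- c(2, 2, 1)
  expect_error(classify_scenarios(array(0L, d), array(1L, d), array(0L, d)),
               "4 voxels.*T2LL")
  expect_error(classify_scenarios(array(1L, d), array(0L, d), array(1L, d)),
               "4 voxels.*MSSS")
})

test_that("overlap percentages follow containment arithmetic", {
  d <- c(4, 4, 2)
  labels <- array(0L, d)
  labels[1:2, 1:2, 1] <- 2L
  sm <- structure(list(labels = labels, legend = scenario_legend(),
                       convention = "results"),
                  class = "scenario_label_map")
  full <- labels == 2L
  expect_equal(overlap_percent(full, sm, 2L), 100)
  expect_equal(overlap_percent(full, sm, "2"), 100)
  disjoint <- array(FALSE, d); disjoint[3:4, 3:4, 2] <- TRUE
  expect_equal(overlap_percent(disjoint, sm, 2L), 0)
  q <- array(FALSE, d); q[1:2, 1:4, 1] <- TRUE      # 8 voxels, 2 labeled...
  q[1:2, 1:2, 1] <- FALSE; q[1:2, 1, 1] <- TRUE; q[1, 2, 1] <- TRUE
  q <- array(FALSE, d); q[1:4, 1:2, 1] <- TRUE      # 8 voxels, 4 labeled
  expect_equal(overlap_percent(q, sm, 2L), 50)
  q2 <- array(FALSE, d); q2[1:4, 1, 1] <- TRUE; q2[1:4, 3, 1] <- TRUE
  expect_equal(overlap_percent(q2, sm, 2L), 25)     # 8 voxels, 2 labeled
  expect_warning(p0 <- overlap_percent(array(FALSE, d), sm, 2L), "empty")
  expect_equal(p0, 0)
  expect_error(overlap_percent(full, sm, 99L), "unknown")
})

test_that("scenario maps merge disjointly and conflicts are caught", {
  d <- c(3, 3, 1)
  a <- array(0L, d); a[1, 1, 1] <- 1L
  b <- array(0L, d); b[2, 2, 1] <- 32L
  mk <- function(l) structure(list(labels = l, legend = scenario_legend(),
                                   convention = "results"),
                              class = "scenario_label_map")
  m <- merge_scenario_maps(list(mk(a), mk(b)))
  expect_equal(sum(m$labels == 1L), 1)
  expect_equal(sum(m$labels == 32L), 1)
  b2 <- b; b2[1, 1, 1] <- 2L
  expect_error(merge_scenario_maps(list(mk(a), mk(b2))), "conflicting")
  expect_warning(m2 <- merge_scenario_maps(list(mk(a), mk(b2)),
                                           on_conflict = "first"),
                 "keeping the first")
  expect_equal(m2$labels[1, 1, 1], 1L)
})

test_that("the scenario report lists present scenarios and overlaps", {
  d <- c(4, 4, 2)
  labels <- array(0L, d)
  labels[1:2, 1, 1] <- 1L
  labels[3:4, 1, 1] <- 42L
  sm <- structure(list(labels = labels, legend = scenario_legend(),
                       convention = "results"),
                  class = "scenario_label_map")
  q <- array(FALSE, d); q[1:4, 1, 1] <- TRUE
  rep <- scenario_report(sm, network_masks = list(N1 = array(TRUE, d)),
                         query_masks = list(sub = q))
  expect_setequal(rep$present, c("1", "4b"))
  expect_equal(rep$counts$total_voxels[rep$counts$scenario == "1"], 2L)
  ov <- rep$overlaps
  expect_equal(ov$percent[ov$scenario == "1"], 50)
  expect_equal(ov$percent[ov$scenario == "4b"], 50)
  expect_equal(ov$percent[ov$scenario == "2"], 0)
  # a null map reports nothing present
  rep0 <- scenario_report(structure(list(labels = array(0L, d),
                                         legend = scenario_legend(),
                                         convention = "results"),
                                    class = "scenario_label_map"))
  expect_length(rep0$present, 0)
})

test_that("negating the severity covariate swaps 3a/3b and 4a/4b exactly", {
  d <- c(3, 3, 2)
  set.seed(2)
  t2 <- array(sample(c(-1L, 0L, 1L), prod(d), TRUE), d)
  fc <- array(sample(c(-1L, 1L), prod(d), TRUE), d)
  fc[t2 == 0L] <- fc[t2 == 0L]            # fc may be nonzero anywhere
  ms <- array(0L, d)
  ms[t2 != 0L] <- sample(c(-1L, 0L, 1L), sum(t2 != 0L), TRUE)
  a <- classify_scenarios(fc, t2, ms)
  b <- classify_scenarios(fc, t2, -ms)
  swap <- a$labels
  swap[a$labels == 31L] <- 32L
  swap[a$labels == 32L] <- 31L
  swap[a$labels == 41L] <- 42L
  swap[a$labels == 42L] <- 41L
  # patterns whose MSSS stage was required but null stay 'none' either way
  expect_identical(b$labels, swap)
})
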