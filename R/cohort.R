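#' Specification of a planted mechanism-scenario region
#'
#' Defines a compact region inside one network template where MS subjects'
#' network coupling is shifted relative to controls and tied linearly to the
#' lesion-load (T2LL) and severity (MSSS) covariates. The sign pattern of
#' `(fc_effect + slopes at the covariate means, t2ll_slope, msss_slope)`
#' determines which mechanism scenario the region instantiates (see
#' [scenario_sign_table]).
#'
#' @param scenario_id one of `"1","2","3a","3b","4a","4b"`.
#' @param region_mask logical 3D array; must lie inside exactly one
#'   template's suprathreshold extent.
#' @param network name of the owning network template.
#' @param fc_effect signed baseline coupling shift for MS vs HC.
#' @param t2ll_slope signed coupling change per mL of T2LL.
#' @param msss_slope signed coupling change per MSSS unit.
#' @return a `scenario_region_spec` object.
#' @export
scenario_region_spec <- function(scenario_id, region_mask, network,
                                 fc_effect, t2ll_slope, msss_slope = 0) {
  scenario_id <- match.arg(as.character(scenario_id),
                           c("1", "2", "3a", "3b", "4a", "4b"))
  structure(list(scenario_id = scenario_id,
                 region_mask = region_mask,
                 network = network,
                 fc_effect = fc_effect,
                 t2ll_slope = t2ll_slope,
                 msss_slope = msss_slope),
            class = "scenario_region_spec")
}

#' Build the default set of planted scenario regions
#'
#' One region per requested scenario, each occupying the suprathreshold
#' extent of a distinct network template. The baseline shift is solved so
#' the *net* mean MS-vs-HC coupling difference equals `fc_shift` with the
#' scenario's FC sign after accounting for the covariate slopes at the
#' population covariate means; the slope signs encode the scenario's
#' T2LL/MSSS correlation directions.
#'
#' @param templates list of `rsn_template`s (at least one per scenario).
#' @param which character vector of scenario ids to plant.
#' @param fc_shift magnitude of the net mean coupling difference.
#' @param t2ll_slope_mag magnitude of the coupling-per-mL slope.
#' @param msss_slope_mag magnitude of the coupling-per-MSSS-unit slope.
#' @param mu_t2ll,mu_msss population means used to solve for the baseline
#'   shift (defaults: 16.63 mL and mid-range severity 3).
#' @return list of [scenario_region_spec]s.
#' @export
default_scenarios <- function(templates,
                              which = c("1", "2", "3a", "3b", "4a", "4b"),
                              fc_shift = 0.5,
                              t2ll_slope_mag = 0.015,
                              msss_slope_mag = 0.15,
                              mu_t2ll = 16.63, mu_msss = 3) {
  which <- match.arg(which, c("1", "2", "3a", "3b", "4a", "4b"),
                     several.ok = TRUE)
  if (length(templates) < length(which))
    stop("need at least one template per planted scenario")
  signs <- scenario_sign_table()
  lapply(seq_along(which), function(i) {
    sid <- which[i]
    row <- signs[signs$scenario == sid, ]
    t2 <- row$t2ll_sign * t2ll_slope_mag
    ms <- if (is.na(row$msss_sign)) 0 else row$msss_sign * msss_slope_mag
    fc <- row$fc_sign * fc_shift - t2 * mu_t2ll - ms * mu_msss
    scenario_region_spec(sid,
                         region_mask = template_mask(templates[[i]]),
                         network = templates[[i]]$name,
                         fc_effect = fc, t2ll_slope = t2, msss_slope = ms)
  })
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the reference study conditions: 29 healthy controls
#' and 62 MS subjects (36 short disease duration, 26 long), TR 2.5 s, T2LL
#' lognormal with mean 16.63 mL, MSSS uniform on 0-6; a desk-scale
#' 20x20x12 grid with 120 timepoints.
#'
#' @param n_hc,n_ms,n_ms_short group sizes (`n_ms_short <= n_ms`).
#' @param grid_dims voxel grid.
#' @param n_networks number of planted network templates.
#' @param n_timepoints,tr series length and repetition time (seconds).
#' @param noise_sd Gaussian measurement noise amplitude.
#' @param baseline_coupling mean network coupling shared by all subjects.
#' @param coupling_jitter_sd between-subject SD of per-network coupling.
#' @param scenarios scenario ids to plant (passed to [default_scenarios]),
#'   or a list of [scenario_region_spec]s, or `NULL` for a null cohort.
#' @param fc_shift,t2ll_slope_mag,msss_slope_mag effect magnitudes for
#'   [default_scenarios].
#' @param subgroup_shift extra coupling for MS_short subjects in the
#'   true-compensation (scenario 2) region when planted, otherwise in the
#'   first region (emulates duration-dependent FC differences); 0 disables
#'   it.
#' @param t2ll_meanlog,t2ll_sdlog lognormal parameters of T2LL (defaults
#'   give mean 16.63 mL, SD approx 22 mL).
#' @param templates optional list of `rsn_template`s to use verbatim
#'   instead of generating `n_networks` fresh ones (required when
#'   `scenarios` is a list referencing specific templates).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_hc = 29, n_ms = 62, n_ms_short = 36,
                          grid_dims = c(20, 20, 12),
                          n_networks = 6,
                          n_timepoints = 120, tr = 2.5,
                          noise_sd = 1,
                          baseline_coupling = 1,
                          coupling_jitter_sd = 0.15,
                          scenarios = c("1", "2", "3a", "3b", "4a", "4b"),
                          fc_shift = 0.5,
                          t2ll_slope_mag = 0.015,
                          msss_slope_mag = 0.15,
                          subgroup_shift = 0.6,
                          t2ll_meanlog = log(16.63) - 0.5,
                          t2ll_sdlog = 1,
                          templates = NULL) {
  stopifnot(n_ms_short <= n_ms, n_timepoints >= 40, tr > 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Draw the cohort design table
#'
#' Covariates follow the reference cohort's demographics: age and education
#' normal around the group means, gender drawn at the observed
#' female fractions, GM ratio narrow-normal, T2LL lognormal, MSSS uniform
#' 0-6, disease duration uniform within the subgroup definition (MS_short
#' <= 5 years, MS_long 5-15 years). HC rows carry `NA` for T2LL, MSSS and
#' disease duration; they are never imputed.
#'
#' @param config a [cohort_config].
#' @param seed integer seed.
#' @return a `data.frame`, one row per subject.
#' @export
simulate_design <- function(config, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_hc <- config$n_hc; n_ms <- config$n_ms
  n_short <- config$n_ms_short; n_long <- n_ms - n_short
  n <- n_hc + n_ms
  group <- c(rep("HC", n_hc), rep("MS", n_ms))
  subgroup <- c(rep("none", n_hc), rep("MS_short", n_short),
                rep("MS_long", n_long))
  age <- numeric(n)
  age[group == "HC"] <- rnorm(n_hc, 34.45, 10.17)
  age[subgroup == "MS_short"] <- rnorm(n_short, 37.34, 8.82)
  age[subgroup == "MS_long"] <- rnorm(n_long, 40.62, 7.26)
  age <- pmax(age, 18)
  p_f <- c(HC = 21 / 29, MS_short = 30 / 36, MS_long = 17 / 26)
  key <- ifelse(group == "HC", "HC", subgroup)
  gender <- ifelse(rbinom(n, 1, p_f[key]) == 1, "F", "M")
  education <- pmax(rnorm(n, 13.3, 2.4), 8)
  gm_ratio <- pmin(pmax(rnorm(n, 0.45, 0.03), 0.3), 0.6)
  t2ll <- rep(NA_real_, n)
  t2ll[group == "MS"] <- rlnorm(n_ms, config$t2ll_meanlog, config$t2ll_sdlog)
  msss <- rep(NA_real_, n)
  msss[group == "MS"] <- runif(n_ms, 0, 6)
  dd <- rep(NA_real_, n)
  dd[subgroup == "MS_short"] <- runif(n_short, 0.3, 5)
  dd[subgroup == "MS_long"] <- runif(n_long, 5.1, 15)
  data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
             group = group, subgroup = subgroup,
             age = age, gender = gender, education = education,
             gm_ratio = gm_ratio, t2ll = t2ll, msss = msss,
             disease_duration = dd,
             stringsAsFactors = FALSE)
}

#' True per-subject coupling for each network
#'
#' The coupling a subject expresses inside a network's scenario region:
#' baseline + between-subject jitter, plus for MS subjects the planted
#' `fc_effect + t2ll_slope * t2ll + msss_slope * msss`, plus the subgroup
#' shift where configured. The jitter is drawn from the subject's own seed
#' stream, so this function reproduces exactly the couplings used by
#' [simulate_subject].
#' @keywords internal
subject_couplings <- function(config, design_row, scenarios, networks,
                              jitter) {
  cc <- rep(config$baseline_coupling, length(networks)) + jitter
  names(cc) <- networks
  region_cc <- cc
  if (design_row$group == "MS") {
    if (is.na(design_row$t2ll) || is.na(design_row$msss))
      stop(sprintf("MS subject %s lacks t2ll/msss metadata",
                   design_row$subject_id))
    for (i in seq_along(scenarios)) {
      sc <- scenarios[[i]]
      k <- match(sc$network, networks)
      shift <- sc$fc_effect + sc$t2ll_slope * design_row$t2ll +
        sc$msss_slope * design_row$msss
      if (i == .subgroup_region(scenarios) &&
          identical(design_row$subgroup, "MS_short"))
        shift <- shift + config$subgroup_shift
      region_cc[k] <- cc[k] + shift
    }
  }
  list(baseline = cc, region = region_cc)
}

# the subgroup (disease-duration) shift lands in the true-compensation
# (scenario 2) region when planted, mirroring the reported overlap of the
# MS_short > MS_long map with compensation areas; otherwise the first region
.subgroup_region <- function(scenarios) {
  ids <- vapply(scenarios, `[[`, "", "scenario_id")
  i <- match("2", ids)
  if (is.na(i)) i <- 1L
  i
}

#' Band-limited random time courses
#'
#' White Gaussian noise restricted to a frequency band by Fourier masking,
#' rescaled to unit SD — the generator's model of low-frequency BOLD
#' network fluctuations.
#'
#' @param n_timepoints series length.
#' @param tr sampling interval (seconds).
#' @param n number of independent series.
#' @param f_lo,f_hi passband in Hz (default 0.01-0.1).
#' @return `n_timepoints` x `n` matrix.
#' @export
bandlimited_series <- function(n_timepoints, tr, n, f_lo = 0.01, f_hi = 0.1) {
  freq <- (seq_len(n_timepoints) - 1) / (n_timepoints * tr)
  freq <- pmin(freq, 1 / tr - freq)           # fold to two-sided spectrum
  keep <- freq >= f_lo & freq <= f_hi
  out <- matrix(0, n_timepoints, n)
  for (j in seq_len(n)) {
    sp <- stats::fft(rnorm(n_timepoints))
    sp[!keep] <- 0
    x <- Re(stats::fft(sp, inverse = TRUE)) / n_timepoints
    s <- stats::sd(x)
    out[, j] <- if (s > 0) x / s else x
  }
  out
}

#' Simulate one subject's 4D time series
#'
#' Each voxel's signal is the sum over networks of
#' `coupling * template_weight * timecourse(t)` plus white Gaussian noise.
#' Inside a scenario region, MS subjects' coupling additionally carries the
#' planted group shift and the covariate-linked terms.
#'
#' @param templates list of `rsn_template`s.
#' @param design_row one row of the design table.
#' @param scenarios list of [scenario_region_spec]s (possibly empty).
#' @param n_timepoints,tr series length and repetition time.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed for this subject.
#' @param config a [cohort_config] (supplies baseline coupling and jitter).
#' @return a list with `vol` (a [volume4d]) and `coupling` (the true
#'   per-network region couplings).
#' @export
simulate_subject <- function(templates, design_row, scenarios,
                             n_timepoints = 120, tr = 2.5, noise_sd = 1,
                             seed = 1, config = cohort_config()) {
  stopifnot(n_timepoints >= 40, tr > 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  networks <- vapply(templates, `[[`, "", "name")
  jitter <- rnorm(length(networks), 0, config$coupling_jitter_sd)
  cc <- subject_couplings(config, design_row, scenarios, networks, jitter)
  dims <- dim(templates[[1]]$map)
  nvox <- prod(dims)
  tcs <- bandlimited_series(n_timepoints, tr, length(networks))
  sig <- matrix(0, nvox, n_timepoints)
  for (k in seq_along(templates)) {
    w <- as.vector(templates[[k]]$map)
    cvox <- rep(cc$baseline[k], nvox)
    sc_k <- Filter(function(s) s$network == networks[k], scenarios)
    for (sc in sc_k) cvox[as.vector(sc$region_mask)] <- cc$region[k]
    sig <- sig + (w * cvox) %o% tcs[, k]
  }
  if (noise_sd > 0)
    sig <- sig + matrix(rnorm(nvox * n_timepoints, 0, noise_sd),
                        nvox, n_timepoints)
  vol <- volume4d(array(sig, c(dims, n_timepoints)), tr = tr)
  list(vol = vol, coupling = cc$region, baseline = cc$baseline)
}

#' Simulate a full cohort with planted ground truth
#'
#' Generates network templates, the design table, scenario regions and one
#' 4D volume per subject; returns everything plus a `ground_truth` record
#' (scenario label map, true per-subject couplings, templates). Fully
#' reproducible from `(config, seed)`.
#'
#' @param config a [cohort_config].
#' @param seed integer master seed.
#' @return a list of class `cohort` with `volumes`, `design`, `templates`,
#'   `scenarios` and `ground_truth`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  templates <- config$templates
  if (is.null(templates))
    templates <- make_rsn_templates(config$grid_dims, config$n_networks,
                                    seed = fanout_seed(seed, 1L))
  design <- simulate_design(config, seed = fanout_seed(seed, 2L))
  scenarios <- config$scenarios
  if (is.character(scenarios)) {
    scenarios <- default_scenarios(templates, which = scenarios,
                                   fc_shift = config$fc_shift,
                                   t2ll_slope_mag = config$t2ll_slope_mag,
                                   msss_slope_mag = config$msss_slope_mag)
  }
  if (is.null(scenarios)) scenarios <- list()
  validate_scenarios(scenarios, templates)

  networks <- vapply(templates, `[[`, "", "name")
  n <- nrow(design)
  volumes <- vector("list", n)
  coup <- matrix(NA_real_, n, length(networks),
                 dimnames = list(design$subject_id, networks))
  for (i in seq_len(n)) {
    s <- simulate_subject(templates, design[i, ], scenarios,
                          n_timepoints = config$n_timepoints,
                          tr = config$tr, noise_sd = config$noise_sd,
                          seed = fanout_seed(seed, 100L + i),
                          config = config)
    volumes[[i]] <- s$vol
    coup[i, ] <- s$coupling
  }
  smap <- array(0L, config$grid_dims)
  for (sc in scenarios) smap[sc$region_mask] <- scenario_code(sc$scenario_id)
  structure(list(volumes = volumes, design = design,
                 templates = templates, scenarios = scenarios,
                 ground_truth = list(scenario_map = smap,
                                     coupling = coup,
                                     templates = templates)),
            class = "cohort")
}

#' Ground truth of a cohort without generating the volumes
#'
#' Reproduces exactly the design table, scenario regions and per-subject
#' true couplings that [simulate_cohort] would produce for the same
#' `(config, seed)` — the couplings are drawn from the identical
#' per-subject seed streams — but skips the expensive 4D signal synthesis.
#'
#' @inheritParams simulate_cohort
#' @return list with `design`, `templates`, `scenarios`, `coupling`
#'   (subjects x networks matrix of region couplings) and `scenario_map`.
#' @export
simulate_truth <- function(config = cohort_config(), seed = 1) {
  templates <- config$templates
  if (is.null(templates))
    templates <- make_rsn_templates(config$grid_dims, config$n_networks,
                                    seed = fanout_seed(seed, 1L))
  design <- simulate_design(config, seed = fanout_seed(seed, 2L))
  scenarios <- config$scenarios
  if (is.character(scenarios)) {
    scenarios <- default_scenarios(templates, which = scenarios,
                                   fc_shift = config$fc_shift,
                                   t2ll_slope_mag = config$t2ll_slope_mag,
                                   msss_slope_mag = config$msss_slope_mag)
  }
  if (is.null(scenarios)) scenarios <- list()
  validate_scenarios(scenarios, templates)
  networks <- vapply(templates, `[[`, "", "name")
  n <- nrow(design)
  coup <- matrix(NA_real_, n, length(networks),
                 dimnames = list(design$subject_id, networks))
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (i in seq_len(n)) {
    set.seed(fanout_seed(seed, 100L + i))
    jitter <- rnorm(length(networks), 0, config$coupling_jitter_sd)
    coup[i, ] <- subject_couplings(config, design[i, ], scenarios,
                                   networks, jitter)$region
  }
  smap <- array(0L, config$grid_dims)
  for (sc in scenarios) smap[sc$region_mask] <- scenario_code(sc$scenario_id)
  list(design = design, templates = templates, scenarios = scenarios,
       coupling = coup, scenario_map = smap)
}

#' Validate planted scenario regions against the templates
#'
#' Each region must lie inside exactly one template's suprathreshold
#' extent.
#' @param scenarios list of [scenario_region_spec]s.
#' @param templates list of `rsn_template`s.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_scenarios <- function(scenarios, templates) {
  masks <- lapply(templates, template_mask)
  names(masks) <- vapply(templates, `[[`, "", "name")
  for (sc in scenarios) {
    hits <- vapply(masks, function(m) any(sc$region_mask & m), logical(1))
    if (sum(hits) != 1L)
      stop(sprintf("scenario %s region overlaps %d template extents (must be exactly 1)",
                   sc$scenario_id, sum(hits)))
    if (!names(masks)[hits] == sc$network)
      stop(sprintf("scenario %s region lies in template %s, not its declared network %s",
                   sc$scenario_id, names(masks)[hits], sc$network))
    own <- masks[[sc$network]]
    if (any(sc$region_mask & !own))
      stop(sprintf("scenario %s region extends outside its template's suprathreshold extent",
                   sc$scenario_id))
  }
  invisible(TRUE)
}

#' Write a cohort to disk
#'
#' Subjects as 4D NIfTI-1 files, the design as TSV, the ground-truth
#' scenario map as an integer-coded NIfTI-1 with a JSON legend.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$volumes)) {
    write_volume(cohort$volumes[[i]],
                 file.path(dir, paste0(cohort$design$subject_id[i], ".nii.gz")))
  }
  utils::write.table(cohort$design, file.path(dir, "design.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sm <- RNifti::asNifti(cohort$ground_truth$scenario_map * 1L)
  RNifti::writeNifti(sm, file.path(dir, "scenario_map.nii.gz"))
  jsonlite::write_json(scenario_legend(),
                       file.path(dir, "scenario_legend.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
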