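#' Scenario code/name legend
#'
#' Integer codes used in scenario label maps: 0 = none, 1, 2, 31 = 3a,
#' 32 = 3b, 41 = 4a, 42 = 4b.
#' @return named list mapping code (as character) to mechanism name.
#' @export
scenario_legend <- function() {
  list("0"  = "none",
       "1"  = "FC reduction driven by MS lesions",
       "2"  = "true functional compensation",
       "31" = "functional compensation attempt",
       "32" = "false functional compensation",
       "41" = "neurodegeneration",
       "42" = "pre-symptomatic condition")
}

#' @rdname scenario_legend
#' @param scenario_id scenario identifier (`"1"`, `"2"`, `"3a"`, `"3b"`,
#'   `"4a"`, `"4b"`).
#' @export
scenario_code <- function(scenario_id) {
  c("1" = 1L, "2" = 2L, "3a" = 31L, "3b" = 32L,
    "4a" = 41L, "4b" = 42L)[[as.character(scenario_id)]]
}

#' @rdname scenario_legend
#' @param code integer scenario code.
#' @export
scenario_id_from_code <- function(code) {
  ids <- c("1", "2", "3a", "3b", "4a", "4b")
  ids[match(code, c(1L, 2L, 31L, 32L, 41L, 42L))]
}

#' Sign table of the six mechanism scenarios
#'
#' Correlation-sign semantics: `fc_sign` is the direction of the MS-vs-HC
#' FC difference; `t2ll_sign`/`msss_sign` are the signs of the voxel's
#' FC-covariate association t statistic (positive = FC increases with the
#' covariate). Scenarios 1 and 2 do not consult the MSSS stage
#' (`msss_sign = NA`).
#'
#' The default `"results"` convention assigns 4a = neurodegeneration to
#' (FC down, T2LL +, MSSS −) and 4b = pre-symptomatic to (FC down, T2LL +,
#' MSSS +); `"methods"` swaps the MSSS signs of 4a/4b.
#'
#' @param convention `"results"` (default) or `"methods"`.
#' @return data.frame with columns `scenario`, `code`, `name`, `fc_sign`,
#'   `t2ll_sign`, `msss_sign`.
#' @export
scenario_sign_table <- function(convention = c("results", "methods")) {
  convention <- match.arg(convention)
  tb <- data.frame(
    scenario = c("1", "2", "3a", "3b", "4a", "4b"),
    code = c(1L, 2L, 31L, 32L, 41L, 42L),
    name = unlist(scenario_legend()[c("1", "2", "31", "32", "41", "42")]),
    fc_sign   = c(-1,  1,  1,  1, -1, -1),
    t2ll_sign = c(-1, -1,  1,  1,  1,  1),
    msss_sign = c(NA, NA, -1,  1, -1,  1),
    stringsAsFactors = FALSE)
  if (convention == "methods") {
    tb$msss_sign[tb$scenario == "4a"] <- 1
    tb$msss_sign[tb$scenario == "4b"] <- -1
  }
  rownames(tb) <- NULL
  tb
}

#' Classify voxels into mechanism scenarios
#'
#' Applies the scenario decision table to three per-voxel sign maps: the
#' direction of the originating FC contrast (`fc_dir`), the sign of the
#' significant FC-T2LL association (`t2ll_sig_sign`, 0 = not significant),
#' and the sign of the significant FC-MSSS association (`msss_sig_sign`).
#' Voxels without a significant T2LL association — and voxels whose
#' T2LL association is positive but whose MSSS stage did not reach
#' significance — are labeled `none`.
#'
#' @param fc_dir integer 3D array in `{-1, 0, +1}`.
#' @param t2ll_sig_sign integer 3D array in `{-1, 0, +1}`; nonzero only
#'   where `fc_dir` is nonzero.
#' @param msss_sig_sign integer 3D array in `{-1, 0, +1}`; nonzero only
#'   where `t2ll_sig_sign` is nonzero.
#' @param convention see [scenario_sign_table].
#' @return a `scenario_label_map`: list with `labels` (integer 3D array of
#'   codes) and `legend`.
#' @export
classify_scenarios <- function(fc_dir, t2ll_sig_sign, msss_sig_sign,
                               convention = c("results", "methods")) {
  convention <- match.arg(convention)
  stopifnot(all(dim(fc_dir) == dim(t2ll_sig_sign)),
            all(dim(fc_dir) == dim(msss_sig_sign)))
  bad_t2 <- sum(t2ll_sig_sign != 0 & fc_dir == 0)
  if (bad_t2 > 0)
    stop(sprintf("%d voxels have a T2LL sign outside the FC-significant mask",
                 bad_t2))
  bad_ms <- sum(msss_sig_sign != 0 & t2ll_sig_sign == 0)
  if (bad_ms > 0)
    stop(sprintf("%d voxels have an MSSS sign outside the T2LL-significant mask",
                 bad_ms))
  tb <- scenario_sign_table(convention)
  labels <- array(0L, dim(fc_dir))
  for (i in seq_len(nrow(tb))) {
    hit <- fc_dir == tb$fc_sign[i] & t2ll_sig_sign == tb$t2ll_sign[i]
    if (!is.na(tb$msss_sign[i])) hit <- hit & msss_sig_sign == tb$msss_sign[i]
    labels[hit] <- tb$code[i]
  }
  structure(list(labels = labels, legend = scenario_legend(),
                 convention = convention),
            class = "scenario_label_map")
}

#' Percentage of a query mask carrying a given scenario label
#'
#' @param query_mask logical 3D array.
#' @param scenario_map a `scenario_label_map` (or integer label array).
#' @param code scenario code (integer) or id (`"3b"` etc.).
#' @return percentage in `[0, 100]`; an empty query mask yields 0 with a
#'   warning.
#' @export
overlap_percent <- function(query_mask, scenario_map, code) {
  labels <- if (inherits(scenario_map, "scenario_label_map"))
    scenario_map$labels else scenario_map
  stopifnot(all(dim(query_mask) == dim(labels)))
  if (is.character(code)) code <- scenario_code(code)
  if (!code %in% c(1L, 2L, 31L, 32L, 41L, 42L))
    stop(sprintf("unknown scenario code %s", code))
  nq <- sum(query_mask)
  if (nq == 0) {
    warning("empty query mask; overlap defined as 0")
    return(0)
  }
  100 * sum(labels[query_mask] == code) / nq
}

#' Merge per-network scenario label maps
#'
#' Scenario supports from different networks/contrasts are disjoint by
#' construction; overlapping conflicting labels raise an error by default
#' (`on_conflict = "first"` keeps the earlier map's label with a warning).
#' @param maps list of `scenario_label_map`s.
#' @param on_conflict `"error"` or `"first"`.
#' @return a single `scenario_label_map`.
#' @export
merge_scenario_maps <- function(maps, on_conflict = c("error", "first")) {
  on_conflict <- match.arg(on_conflict)
  stopifnot(length(maps) >= 1)
  out <- maps[[1]]$labels
  for (m in maps[-1]) {
    clash <- out != 0L & m$labels != 0L & out != m$labels
    if (any(clash)) {
      if (on_conflict == "error")
        stop(sprintf("%d voxels carry conflicting scenario labels", sum(clash)))
      warning(sprintf("%d voxels carry conflicting scenario labels; keeping the first",
                      sum(clash)))
    }
    add <- m$labels != 0L & out == 0L
    out[add] <- m$labels[add]
  }
  structure(list(labels = out, legend = scenario_legend(),
                 convention = maps[[1]]$convention),
            class = "scenario_label_map")
}

#' Summarize scenario support and query-mask overlaps
#'
#' Reports which of the six scenarios have nonempty support, voxel counts
#' per scenario per network, and the percentage of each query mask (e.g., a
#' subgroup-contrast significance mask) overlapping each present scenario.
#'
#' @param scenario_map a `scenario_label_map`.
#' @param network_masks named list of logical 3D arrays (network extents);
#'   optional.
#' @param query_masks named list of logical 3D arrays; optional.
#' @return list with `present` (scenario ids), `counts` (data.frame
#'   scenario x network voxel counts) and `overlaps` (data.frame query,
#'   scenario, percent).
#' @export
scenario_report <- function(scenario_map, network_masks = NULL,
                            query_masks = NULL) {
  labels <- scenario_map$labels
  codes <- c(1L, 2L, 31L, 32L, 41L, 42L)
  support <- vapply(codes, function(cd) sum(labels == cd), integer(1))
  present <- scenario_id_from_code(codes[support > 0])
  counts <- data.frame(scenario = scenario_id_from_code(codes),
                       total_voxels = support, stringsAsFactors = FALSE)
  if (!is.null(network_masks)) {
    for (nm in names(network_masks)) {
      counts[[nm]] <- vapply(codes, function(cd)
        sum(labels == cd & network_masks[[nm]]), integer(1))
    }
  }
  overlaps <- NULL
  if (!is.null(query_masks)) {
    overlaps <- do.call(rbind, lapply(names(query_masks), function(qn) {
      data.frame(query = qn,
                 scenario = scenario_id_from_code(codes),
                 percent = vapply(codes, function(cd) {
                   if (sum(query_masks[[qn]]) == 0) return(0)
                   overlap_percent(query_masks[[qn]], scenario_map, cd)
                 }, numeric(1)),
                 stringsAsFactors = FALSE)
    }))
  }
  list(present = present, counts = counts, overlaps = overlaps)
}

#' Write a scenario label map as NIfTI plus JSON legend
#' @param scenario_map a `scenario_label_map`.
#' @param path output NIfTI path; the legend is written next to it.
#' @return `path`, invisibly.
#' @export
write_scenario_map <- function(scenario_map, path) {
  RNifti::writeNifti(RNifti::asNifti(scenario_map$labels * 1L), path)
  jsonlite::write_json(scenario_map$legend,
                       sub("\\.nii(\\.gz)?$", "_legend.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}
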