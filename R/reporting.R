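# Result tables mirroring the published layout, tidy CSV export of traces
# and sensitivity output, and run manifests for reproducibility.

#' Base-case results table
#'
#' Lays out the base-case results in the published structure: cost
#' categories, total costs, QALYs, life-years and event counts per arm,
#' with incremental columns versus VKA, followed by the ICERs. Values are
#' unrounded; `print()` rounds costs to the nearest euro and health
#' outcomes to two decimals.
#'
#' @param base_case A `noacce_base_case` from [run_base_case()].
#' @return A `noacce_ce_table` data frame, one row per outcome.
#' @export
ce_table <- function(base_case) {
  stopifnot(inherits(base_case, "noacce_base_case"))
  arms <- base_case$arms
  noacs <- names(base_case$incremental)
  row_of <- function(f) vapply(arms, f, numeric(1))
  rows <- list(
    drug_acquisition_costs = row_of(function(a) a$costs[["drug_acquisition"]]),
    drug_administration_costs = row_of(function(a) a$costs[["administration"]]),
    event_management_costs = row_of(function(a) a$costs[["event_management"]]),
    total_costs = row_of(function(a) a$costs[["total"]]),
    total_qalys = row_of(function(a) a$qalys),
    total_ly = row_of(function(a) a$lys),
    ischaemic_strokes = row_of(function(a) a$events[["ischaemic_stroke"]]),
    myocardial_infarctions = row_of(function(a) a$events[["mi"]]),
    ich = row_of(function(a) a$events[["ich"]]),
    gi_bleeding = row_of(function(a) a$events[["gi"]]))
  out <- data.frame(outcome = names(rows),
                    do.call(rbind, rows), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (a in noacs)
    out[[paste0(a, "_incr")]] <- out[[a]] - out[["vka"]]
  icer_row <- function(what) {
    r <- stats::setNames(rep(NA_real_, ncol(out) - 1L), names(out)[-1L])
    for (a in noacs)
      r[[paste0(a, "_incr")]] <- base_case$incremental[[a]][[what]]
    r
  }
  out <- rbind(out,
               data.frame(outcome = "icer_per_qaly",
                          t(icer_row("icer_qaly")), check.names = FALSE),
               data.frame(outcome = "icer_per_lyg",
                          t(icer_row("icer_ly")), check.names = FALSE))
  rownames(out) <- NULL
  class(out) <- c("noacce_ce_table", "data.frame")
  out
}

#' @export
print.noacce_ce_table <- function(x, ...) {
  fmt <- as.data.frame(x)
  cost_rows <- grepl("costs|icer", fmt$outcome)
  for (j in seq_along(fmt)[-1L]) {
    v <- fmt[[j]]
    fmt[[j]] <- ifelse(is.na(v), "",
                       ifelse(cost_rows,
                              formatC(round(v), format = "d", big.mark = ","),
                              formatC(v, format = "f", digits = 2)))
  }
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Export a cohort trace as tidy CSV
#'
#' One row per cycle per state: cycle, cohort age, state, occupancy.
#'
#' @param arm_result A `noacce_arm` from [run_cohort()].
#' @param path Output CSV path.
#' @return The tidy data frame, invisibly.
#' @export
write_trace <- function(arm_result, path) {
  tr <- arm_result$trace
  occ <- tr$occupancy
  out <- data.frame(
    cycle = rep(seq_len(nrow(occ)) - 1L, times = ncol(occ)),
    age = rep(tr$age, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Export PSA scatter and CEAC as plot-ready CSVs
#'
#' Writes `psa_scatter.csv` (draw, arm, delta_cost, delta_qalys),
#' `ceac.csv` (lambda, arm, probability) and a YAML run manifest into
#' `dir`.
#'
#' @param psa A `noacce_psa` object.
#' @param dir Output directory (created if missing).
#' @param manifest Optional manifest list from [run_manifest()].
#' @return Named character vector of the files written, invisibly.
#' @export
write_psa_outputs <- function(psa, dir, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(scatter = file.path(dir, "psa_scatter.csv"),
             ceac = file.path(dir, "ceac.csv"),
             manifest = file.path(dir, "manifest.yaml"))
  utils::write.csv(psa$samples, files[["scatter"]], row.names = FALSE)
  utils::write.csv(psa$ceac, files[["ceac"]], row.names = FALSE)
  if (is.null(manifest))
    manifest <- list(seed = psa$seed, n_draws = psa$n_draws)
  yaml::write_yaml(manifest, files[["manifest"]])
  invisible(files)
}

#' Export a tornado as plot-ready CSV
#' @param tor A `noacce_tornado` from [tornado()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(tor, path) {
  utils::write.csv(as.data.frame(tor), path, row.names = FALSE)
  invisible(path)
}

#' Reproducibility manifest for a model run
#'
#' Records the config and life-table paths with their MD5 hashes, the
#' seed(s), the package version and a timestamp.
#'
#' @param config_path Path of the parameter config used.
#' @param life_table_path Path of the life table used.
#' @param seed Integer seed(s) involved in the run (if any).
#' @return A named list.
#' @export
run_manifest <- function(config_path, life_table_path, seed = NA_integer_) {
  list(
    config = list(path = config_path,
                  md5 = unname(tools::md5sum(config_path))),
    life_table = list(path = life_table_path,
                      md5 = unname(tools::md5sum(life_table_path))),
    seed = seed,
    package_version = as.character(utils::packageVersion("noacce")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
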