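#' Linear fluorescence calibration
#'
#' @param slope nM per arbitrary fluorescence unit (> 0).
#' @param intercept nM offset.
#' @param readout Name of the calibrated readout.
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept = 0, readout = "sfGFP") {
  if (!is.numeric(slope) || slope <= 0) stop("slope must be > 0")
  structure(list(slope = slope, intercept = intercept, readout = readout),
            class = "calibration_curve")
}

#' Apply a calibration curve to raw fluorescence
#'
#' Elementwise `value * slope + intercept`. Negative resulting
#' concentrations are flagged with a warning but not clipped.
#'
#' @param raw Numeric vector of arbitrary fluorescence units.
#' @param curve A [calibration_curve()].
#' @return Concentrations (nM).
#' @export
apply_calibration <- function(raw, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- raw * curve$slope + curve$intercept
  if (any(out < 0, na.rm = TRUE))
    warning(sum(out < 0, na.rm = TRUE), " calibrated values are negative")
  out
}

#' Generate a synthetic experimental-style fixture dataset
#'
#' Simulates each condition at the generating parameters and perturbs the
#' readout with multiplicative Gaussian noise (`value * (1 + CV * N(0,1))`)
#' per replicate on the plate-reader grid (default 5-min sampling over 3 h,
#' 37 timepoints including t = 0). Seeded and reproducible; the generating
#' parameters travel with the table as metadata, serving as ground truth for
#' parameter-recovery tests.
#'
#' @param network Network to simulate.
#' @param params Generating parameter set.
#' @param conditions Condition grid rows to include.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param replicates Number of replicates (>= 1, default 3).
#' @param t_end,t_step Sampling grid (s).
#' @param seed RNG seed.
#' @return data.frame `condition_id`, `replicate`, `time_s`, `value`, with
#'   attribute `metadata` (list: generating parameters, noise model, seed).
#' @export
generate_fixture <- function(network, params, conditions, cv = 0.05,
                             replicates = 3, t_end = 10800, t_step = 300,
                             seed = 1) {
  stopifnot(cv >= 0, replicates >= 1)
  rows <- withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(conditions))) {
      cond <- conditions[i, ]
      tc <- simulate_network(network, params, compose_doses(cond),
                             t_end = t_end, t_step = t_step)
      y <- tc$readouts[[reporter_unit_id(cond)]]
      for (r in seq_len(replicates)) {
        noisy <- y * (1 + cv * stats::rnorm(length(y)))
        out[[length(out) + 1L]] <- data.frame(
          condition_id = cond$condition_id, replicate = r,
          time_s = tc$times, value = noisy)
      }
    }
    do.call(rbind, out)
  })
  attr(rows, "metadata") <- list(
    generating_parameters = as.list(params), cv = cv,
    replicates = replicates, t_end = t_end, t_step = t_step, seed = seed)
  rows
}

#' Write a fixture table with its metadata sidecar
#'
#' @param fixture data.frame from [generate_fixture()].
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_fixture_csv <- function(fixture, path) {
  utils::write.csv(fixture, path, row.names = FALSE)
  meta <- attr(fixture, "metadata")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a model declaration file
#'
#' Serializes units, resources, toxin configuration, and a parameter set as
#' a YAML config that [read_model_config()] restores losslessly.
#'
#' @param network A `txtl_network`.
#' @param params Optional parameter set stored under `parameters`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(network, params = NULL, path) {
  unit_block <- lapply(network$units, function(u) {
    list(id = u$id,
         promoter = list(name = u$promoter$name,
                         polymerase_class = u$promoter$polymerase_class,
                         kf_tx = u$promoter$kf_tx, kr_tx = u$promoter$kr_tx),
         transcript_length = u$transcript_length,
         translatable = u$translatable, protein_length = u$protein_length,
         kf_rbs = u$kf_rbs, kr_rbs = u$kr_rbs,
         kf_nuc = u$kf_nuc, kr_nuc = u$kr_nuc, k_deg = u$k_deg,
         k_mat = u$k_mat, readout = u$readout)
  })
  cfg <- list(units = unname(unit_block),
              resources = unclass(network$resources),
              toxin = unclass(network$toxin),
              parameters = if (!is.null(params)) as.list(params))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a model declaration file
#'
#' @param path YAML config written by [write_model_config()] (or hand
#'   authored with the same blocks `units`, `resources`, `toxin`,
#'   `parameters`).
#' @return List with `network` (a `txtl_network`) and `params` (named
#'   numeric vector or `NULL`).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  units <- lapply(cfg$units, function(u) {
    pr <- promoter_spec(u$promoter$name, u$promoter$polymerase_class,
                        u$promoter$kf_tx, u$promoter$kr_tx)
    transcription_unit(u$id, pr, u$transcript_length, u$translatable,
                       u$protein_length, u$kf_rbs, u$kr_rbs,
                       u$kf_nuc, u$kr_nuc, u$k_deg, u$k_mat, u$readout)
  })
  res <- do.call(resource_spec, cfg$resources)
  tox <- toxin_config(cfg$toxin$variant, cfg$toxin$b, cfg$toxin$k_toxin,
                      cfg$toxin$toxin_threshold)
  params <- if (!is.null(cfg$parameters)) unlist(cfg$parameters)
  list(network = build_network(units, res, tox), params = params)
}

# JSON run-metadata record shared by CLI subcommands
run_metadata <- function(seed, config_path = NULL, extra = list()) {
  c(list(seed = seed,
         config = config_path,
         config_sha = if (!is.null(config_path) && file.exists(config_path))
           unname(tools::md5sum(config_path)),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         package_version = as.character(utils::packageVersion("cfecrosstalk"))),
    extra)
}
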