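#' Pipeline run configuration
#'
#' Bundles everything the end-to-end run needs: either phantom generation
#' settings or paths to existing NIfTI inputs (exactly one source), the fit
#' configuration, the output directory and the master seed recorded in the
#' output manifest.
#'
#' @param out_dir output directory.
#' @param seed master RNG seed; all child seeds derive from it.
#' @param n_per_group subjects simulated per group (phantom source).
#' @param sigma phantom noise level (see [phantom_spec()]).
#' @param jitter between-subject parameter spread multiplier.
#' @param shape phantom image shape.
#' @param input_nii,input_bval paths of an existing DWI series + sidecar;
#'   when given, the phantom source is disabled and only map fitting and
#'   quantification against `input_roi` run.
#' @param input_roi label-map NIfTI accompanying `input_nii`.
#' @param ratings `"fixture"` for the in-study rating table, a CSV path, or
#'   `NULL` to skip the agreement arm.
#' @param fit a [fit_config()].
#' @param write_maps write parameter-map NIfTIs for the first subject of
#'   each group (default TRUE).
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       n_per_group = 10L,
                       sigma = 2,
                       jitter = 1,
                       shape = c(64L, 64L, 5L),
                       input_nii = NULL,
                       input_bval = NULL,
                       input_roi = NULL,
                       ratings = "fixture",
                       fit = fit_config(),
                       write_maps = TRUE) {
  if (!is.null(input_nii) && (is.null(input_bval) || is.null(input_roi))) {
    stop("`input_nii` requires `input_bval` and `input_roi`")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_per_group = as.integer(n_per_group), sigma = sigma,
         jitter = jitter, shape = as.integer(shape),
         input_nii = input_nii, input_bval = input_bval,
         input_roi = input_roi, ratings = ratings, fit = fit,
         write_maps = isTRUE(write_maps)),
    class = "run_config"
  )
}

.log <- function(level, stage, ...) {
  message(sprintf("[%s] %s: %s", level, stage, paste0(...)))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Phantom cohorts (or a provided DWI series) -> intensity masking and
#' voxelwise segmented IVIM fitting -> ROI quantification with a measurement
#' repeat -> grouped summary with Mann-Whitney comparisons and repeat CoV ->
#' reader-agreement report -> JSON manifest.  All numeric results go to
#' files; logs only narrate progress.  Identical configurations produce
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the output paths and the in-memory result
#'   tables (`measurements`, `summary`, `cov`, `agreement`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (is.null(config$input_nii)) {
    .log("INFO", "phantom", "simulating 2 x ", config$n_per_group,
         " subjects (sigma = ", config$sigma, ", jitter = ", config$jitter, ")")
    cohorts <- .stage("phantom", list(
      patients = make_cohort(config$n_per_group, "patients",
                             base_seed = config$seed, jitter = config$jitter,
                             sigma = config$sigma, shape = config$shape),
      volunteers = make_cohort(config$n_per_group, "volunteers",
                               base_seed = config$seed + 1000L,
                               jitter = config$jitter, sigma = config$sigma,
                               shape = config$shape)
    ))
    .log("INFO", "fit", "voxelwise segmented IVIM fit")
    meas <- .stage("fit+quantify", {
      out <- list()
      for (g in names(cohorts)) {
        rows <- lapply(cohorts[[g]], function(s) {
          maps <- fit_volume(s$series, config$fit)
          measure_subject(maps, s$series, s$labels, subject_id = s$id,
                          repeat_seed = s$seed + 7L)
        })
        out[[g]] <- do.call(rbind, rows)
        out[[g]]$group <- g
        if (config$write_maps) {
          s1 <- cohorts[[g]][[1L]]
          write_parameter_maps(fit_volume(s1$series, config$fit),
                               file.path(config$out_dir, "maps"),
                               prefix = paste0(g, "_01"))
          write_dwi_series(s1$series,
                           file.path(config$out_dir, "maps",
                                     paste0(g, "_01_dwi.nii")))
          write_nifti(s1$labels * 1,
                      file.path(config$out_dir, "maps",
                                paste0(g, "_01_labels.nii")),
                      spacing = s1$series$spacing)
        }
      }
      out
    })

    .log("INFO", "stats", "group summary, Mann-Whitney, repeat CoV")
    measurements <- rbind(meas$patients, meas$volunteers)
    summary_tab <- .stage("group_summary",
                          group_summary(meas$patients, meas$volunteers))
    cov_tab <- .stage("repeat_cov", {
      rows <- list()
      for (g in names(meas)) {
        for (tis in unique(meas[[g]]$tissue)) {
          m <- meas[[g]][meas[[g]]$tissue == tis, ]
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, tissue = tis,
            cov_D_pct = repeat_cov(m$D_mean, m$D_mean_rep2),
            cov_f_pct = repeat_cov(m$f_mean, m$f_mean_rep2))
        }
      }
      do.call(rbind, rows)
    })

    paths$measurements <- file.path(config$out_dir, "measurements.csv")
    utils::write.csv(measurements, paths$measurements, row.names = FALSE)
    paths$summary <- file.path(config$out_dir, "group_summary.csv")
    utils::write.csv(summary_tab, paths$summary, row.names = FALSE)
    paths$cov <- file.path(config$out_dir, "repeat_cov.csv")
    utils::write.csv(cov_tab, paths$cov, row.names = FALSE)
  } else {
    .log("INFO", "input", "reading DWI series from ", config$input_nii)
    series <- .stage("input", read_dwi_series(config$input_nii, config$input_bval))
    roi <- .stage("input", read_nifti(config$input_roi)$data)
    maps <- .stage("fit", fit_volume(series, config$fit))
    if (config$write_maps) {
      write_parameter_maps(maps, file.path(config$out_dir, "maps"))
    }
    labs <- sort(setdiff(unique(as.integer(roi)), 0L))
    labels <- stats::setNames(labs, paste0("label", labs))
    measurements <- .stage("quantify",
                           measure_subject(maps, series, array(as.integer(roi), dim = dim(roi)),
                                           subject_id = "input",
                                           labels = labels,
                                           repeat_seed = config$seed))
    summary_tab <- NULL; cov_tab <- NULL
    paths$measurements <- file.path(config$out_dir, "measurements.csv")
    utils::write.csv(measurements, paths$measurements, row.names = FALSE)
  }

  agreement <- NULL
  if (!is.null(config$ratings)) {
    .log("INFO", "agreement", "reader agreement analysis")
    records <- if (identical(config$ratings, "fixture")) study_fixture()
               else .stage("agreement", read_ratings(config$ratings))
    agreement <- .stage("agreement", agreement_report(records))
    paths$agreement <- file.path(config$out_dir, "agreement.json")
    jsonlite::write_json(agreement, paths$agreement, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    paths$agreement_csv <- file.path(config$out_dir, "agreement.csv")
    utils::write.csv(agreement$comparisons, paths$agreement_csv,
                     row.names = FALSE)
  }

  manifest <- .stage("manifest", {
    cfg_json <- jsonlite::toJSON(
      list(seed = config$seed, n_per_group = config$n_per_group,
           sigma = config$sigma, jitter = config$jitter,
           shape = config$shape, fit = unclass(config$fit),
           ratings = config$ratings,
           input = !is.null(config$input_nii)),
      auto_unbox = TRUE, digits = NA)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    m <- list(
      package = "ivimdwi",
      version = as.character(utils::packageVersion("ivimdwi")),
      seed = config$seed,
      config = jsonlite::fromJSON(cfg_json),
      config_md5 = unname(tools::md5sum(tmp)),
      outputs = lapply(paths, basename)
    )
    unlink(tmp)
    m
  })
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .log("INFO", "done", "outputs in ", config$out_dir)

  invisible(list(paths = paths, measurements = measurements,
                 summary = summary_tab, cov = cov_tab,
                 agreement = agreement, manifest = manifest))
}
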