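#' Configuration for an end-to-end phantom study
#'
#' Bundles every knob of the simulated study: cohort composition, grid and
#' noise, the calibration phantom, the methods to run, and the named seeds.
#' All physical quantities are in mm and SUV. The configuration
#' round-trips losslessly through YAML via [write_study_config()] /
#' [read_study_config()].
#'
#' @param counts named cases-per-type vector (default the 16/30/87
#'   nonsolid/part-solid/solid composition of a stage I adenocarcinoma
#'   cohort).
#' @param ranges per-type parameter ranges, see [default_cohort_ranges()].
#' @param grid_shape,grid_spacing_mm,psf_fwhm_mm,ct_spacing_mm cohort grid
#'   geometry (see [grid_params()]).
#' @param noise_sd additive Gaussian SUV noise.
#' @param rc_diameters_mm,rc_contrast calibration phantom spheres and
#'   sphere-to-background ratio.
#' @param isocontour_fraction isocontour level for RC measurement.
#' @param methods subset of `c("T42", "T42RC", "AIA", "AT40")`.
#' @param cohort_seed,observer_jitter_seed named seeds (noise is drawn from
#'   per-case seeds derived from `cohort_seed`).
#' @param voi_margin_mm VOI margin around the lesion radius.
#' @param bg_roi_radius_mm radius of the mirrored background ROI.
#' @param write_images write per-case NIfTI volumes under `out_dir/cases`.
#' @return object of class `study_config` (a named list).
#' @export
study_config <- function(counts = c(nonsolid = 16, part_solid = 30, solid = 87),
                         ranges = default_cohort_ranges(),
                         grid_shape = c(40L, 24L, 24L),
                         grid_spacing_mm = 3.27,
                         psf_fwhm_mm = 4.5,
                         ct_spacing_mm = 1.25,
                         noise_sd = 0.05,
                         rc_diameters_mm = c(10, 13, 17, 22, 28, 37),
                         rc_contrast = 8,
                         isocontour_fraction = 0.7,
                         methods = c("T42", "T42RC", "AIA", "AT40"),
                         cohort_seed = 20170101L,
                         observer_jitter_seed = 42L,
                         voi_margin_mm = 8,
                         bg_roi_radius_mm = 7.5,
                         write_images = FALSE) {
  methods <- match.arg(methods, c("T42", "T42RC", "AIA", "AT40"),
                       several.ok = TRUE)
  structure(list(counts = counts, ranges = ranges, grid_shape = grid_shape,
                 grid_spacing_mm = grid_spacing_mm, psf_fwhm_mm = psf_fwhm_mm,
                 ct_spacing_mm = ct_spacing_mm, noise_sd = noise_sd,
                 rc_diameters_mm = rc_diameters_mm, rc_contrast = rc_contrast,
                 isocontour_fraction = isocontour_fraction, methods = methods,
                 cohort_seed = as.integer(cohort_seed),
                 observer_jitter_seed = as.integer(observer_jitter_seed),
                 voi_margin_mm = voi_margin_mm,
                 bg_roi_radius_mm = bg_roi_radius_mm,
                 write_images = isTRUE(write_images)),
            class = "study_config")
}

#' Write / read a study configuration as YAML
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return `write_study_config` returns `path` invisibly;
#'   `read_study_config` returns a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  raw <- unclass(config)
  raw$counts <- as.list(raw$counts)  # yaml drops names on atomic vectors
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$counts <- unlist(raw$counts)
  do.call(study_config, raw)
}

#' Run the full phantom study
#'
#' End-to-end pipeline: build the hot-sphere calibration phantom and the
#' recovery-coefficient table; generate the lesion cohort; compute the CT
#' reference (volume, long diameter, consistency) per case; delineate each
#' lesion with the requested methods; evaluate percentage volume error,
#' accuracy and strata; run the two-observer background-jitter reliability
#' experiment for AT40%; and derive the per-stratum method recommendations.
#' Deterministic given the seeds in `config`.
#'
#' @param config a [study_config()].
#' @param out_dir output directory, or `NULL` to skip writing files. When
#'   set, writes `rc_table.csv`, `delineations.csv`, `ct_reference.csv`,
#'   `evaluation.csv`, `strata_summary.csv` and `report.json` (plus
#'   per-case NIfTI under `cases/` when `config$write_images`).
#' @param progress print per-stage timing to stderr.
#' @return object of class `study_report`: list with `rc_table`, `cohort`
#'   (the phantom cases), `references`, `delineations`, `records`,
#'   `strata`, `icc`, `recommendations`, `spearman_type_uptake`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(msg) if (progress) message(sprintf("[%s] %s",
                                                       format(Sys.time(), "%H:%M:%S"), msg))
  grid <- grid_params(config$grid_shape, config$grid_spacing_mm,
                      config$psf_fwhm_mm, config$ct_spacing_mm)

  stage("calibrating recovery coefficients")
  calib <- generate_calibration_phantom(config$rc_diameters_mm,
                                        config$rc_contrast)
  rc_tab <- calibrate_rc_table(calib, config$isocontour_fraction)

  stage("generating cohort")
  cohort <- generate_cohort(config$counts, config$ranges, grid,
                            config$noise_sd, config$cohort_seed)
  n <- length(cohort)

  stage("CT reference and delineation")
  refs <- vector("list", n)
  delin <- list()
  at40_obs <- matrix(NA_real_, n, 2)
  jit <- with_local_seed(config$observer_jitter_seed,
                         matrix(stats::runif(n * 3 * 2, -2, 2), ncol = 6))
  for (i in seq_len(n)) {
    case <- cohort[[i]]
    id <- case$case_id
    voi <- lesion_voi(case, config$voi_margin_mm)
    ref <- tryCatch(segment_ct_volume(case$ct, voi),
                    error = function(e) stop("case ", id, ": ", conditionMessage(e)))
    refs[[i]] <- data.frame(case_id = id, ctv_mm3 = ref$ctv_mm3,
                            long_diameter_mm = ref$long_diameter_mm,
                            nodule_type = ref$consistency,
                            true_type = case$spec$nodule_type,
                            truth_volume_mm3 = case$truth_volume_mm3,
                            stringsAsFactors = FALSE)
    bg <- measure_background(case$pet, case$spec$center_mm,
                             config$bg_roi_radius_mm, lesion_voi = voi)
    run_one <- function(method) {
      res <- switch(method,
        T42 = segment_t42(case$pet, voi),
        T42RC = segment_t42_rc(case$pet, voi, rc_tab, ref$long_diameter_mm),
        AIA = segment_aia(case$pet, voi),
        AT40 = segment_at40(case$pet, voi, bg))
      data.frame(case_id = id, method = method,
                 threshold_suv = res$threshold_suv, mtv_mm3 = res$mtv_mm3,
                 suv_mean = res$suv_mean, suv_max = res$suv_max,
                 converged = res$converged, stringsAsFactors = FALSE)
    }
    rows <- lapply(config$methods, function(m)
      tryCatch(run_one(m), error = function(e)
        stop("case ", id, " method ", m, ": ", conditionMessage(e))))
    delin[[i]] <- do.call(rbind, rows)
    # two simulated observers for AT40%: background ROI jittered +-2 mm
    for (obs in 1:2) {
      bg_j <- measure_background(case$pet,
                                 case$spec$center_mm + jit[i, (3 * obs - 2):(3 * obs)],
                                 config$bg_roi_radius_mm, lesion_voi = voi)
      at40_obs[i, obs] <- segment_at40(case$pet, voi, bg_j)$mtv_mm3
    }
    if (config$write_images && !is.null(out_dir))
      write_phantom_case(case, file.path(out_dir, "cases"))
  }
  references <- do.call(rbind, refs)
  delineations <- do.call(rbind, delin)

  stage("evaluation")
  records <- evaluate_records(delineations, references)
  strata <- summarize_by_strata(records)
  icc <- icc_reliability(at40_obs)
  type_rank <- match(references$true_type, c("nonsolid", "part_solid", "solid"))
  suv_by_case <- delineations$suv_max[match(references$case_id,
                                            delineations$case_id)]
  spearman <- stats::cor(type_rank, suv_by_case, method = "spearman")

  grid_combos <- expand.grid(nodule_type = c("nonsolid", "part_solid", "solid"),
                             size_group = c("small", "large"),
                             uptake_group = c("low", "high"),
                             stringsAsFactors = FALSE)
  grid_combos$recommended <- recommend_method(grid_combos$nodule_type,
                                              grid_combos$size_group,
                                              grid_combos$uptake_group)

  report <- structure(list(rc_table = rc_tab, cohort = cohort,
                           references = references,
                           delineations = delineations, records = records,
                           strata = strata, icc = icc,
                           recommendations = grid_combos,
                           spearman_type_uptake = spearman,
                           config = config),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d lesions, methods: %s\n",
              length(x$cohort), paste(x$config$methods, collapse = ", ")))
  ov <- x$strata[x$strata$stratum == "all", c("method", "n", "accuracy_pct",
                                              "mean_ve", "pearson_r")]
  print(ov, row.names = FALSE, digits = 3)
  cat(sprintf("AT40 inter-observer ICC: %.3f (%s); type-uptake Spearman: %.3f\n",
              x$icc$icc, x$icc$band, x$spearman_type_uptake))
  invisible(x)
}

#' Write the study report files
#'
#' CSV tables plus a JSON report mirroring the accuracy-by-stratum figures.
#' @param report a `study_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(as.data.frame(report$rc_table), "rc_table.csv")
  wcsv(report$delineations, "delineations.csv")
  wcsv(report$references, "ct_reference.csv")
  wcsv(report$records, "evaluation.csv")
  wcsv(report$strata, "strata_summary.csv")
  json <- list(
    seeds = list(cohort_seed = report$config$cohort_seed,
                 observer_jitter_seed = report$config$observer_jitter_seed),
    n_lesions = length(report$cohort),
    methods = report$config$methods,
    accuracy_by_stratum = report$strata,
    icc_at40 = report$icc,
    spearman_type_uptake = report$spearman_type_uptake,
    recommendations = report$recommendations)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
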