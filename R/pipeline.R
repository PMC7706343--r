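#' Pipeline configuration
#'
#' Builds and validates the configuration of the end-to-end pipeline.
#' Unknown keys are rejected so typos fail loudly. Configurations
#' round-trip through JSON via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param input path to a DICOM slice directory (or `NULL` when a volume is
#'   passed to [run_pipeline()] directly).
#' @param output output directory for artifacts.
#' @param seed seed for every source of randomness.
#' @param holder holder-clearance settings: `min_size_frac`,
#'   `closing_radius`, `binarize_method`, `enabled`.
#' @param seg segmentation settings: `metric`, `merge_threshold` (NULL =
#'   radius-based automatic), `connectivity`, `min_volume` (NULL =
#'   automatic).
#' @param traits trait settings: `smooth_sigma` (mm).
#' @param spacing_override,allow_default_spacing passed to
#'   [read_dicom_stack()].
#' @param verbose print stage logs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output = NULL, seed = 1L,
                            holder = list(), seg = list(), traits = list(),
                            spacing_override = NULL,
                            allow_default_spacing = FALSE,
                            verbose = TRUE) {
  holder <- merge_section(list(min_size_frac = 0.25, closing_radius = 3,
                               binarize_method = "otsu", enabled = TRUE),
                          holder, "holder")
  seg <- merge_section(list(metric = "chessboard", merge_threshold = NULL,
                            connectivity = 26, min_volume = NULL),
                       seg, "seg")
  traits <- merge_section(list(smooth_sigma = 0.2), traits, "traits")
  structure(list(input = input, output = output, seed = as.integer(seed),
                 holder = holder, seg = seg, traits = traits,
                 spacing_override = spacing_override,
                 allow_default_spacing = allow_default_spacing,
                 verbose = verbose),
            class = "pipeline_config")
}

merge_section <- function(defaults, given, name) {
  if (is.null(given)) given <- list()
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s) in [", name, "]: ",
         paste(unknown, collapse = ", "))
  utils::modifyList(defaults, given, keep.null = TRUE)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("input", "output", "seed", "holder", "seg", "traits",
             "spacing_override", "allow_default_spacing", "verbose")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full panicle phenotyping pipeline
#'
#' Read (DICOM stack) -> holder clearance -> Otsu segmentation -> improved
#' distance-transform watershed -> per-grain traits -> 22-trait panicle
#' record, writing the label volume and both CSV tables when an output
#' directory is configured. Every stage logs its parameters and counts.
#'
#' @param config a [pipeline_config()].
#' @param volume optional [ct_volume()] bypassing the DICOM reader.
#' @param panicle_id identifier for the panicle record.
#' @return List with `volume`, `cleared`, `labels` ([label_volume()]),
#'   `records` (per-grain data.frame), `traits` (one-row 22-trait
#'   data.frame) and `paths` (written artifacts, if any).
#' @export
run_pipeline <- function(config = pipeline_config(), volume = NULL,
                         panicle_id = "panicle") {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(volume)) {
    if (is.null(config$input)) stop("no input: configure `input` or pass `volume`")
    say("reading DICOM stack from ", config$input)
    volume <- stage("read", read_dicom_stack(
      config$input, spacing_override = config$spacing_override,
      allow_default_spacing = config$allow_default_spacing))
  }
  d <- dim(volume$data)
  say(sprintf("volume %d x %d x %d, spacing %.4g/%.4g/%.4g mm",
              d[1], d[2], d[3],
              volume$spacing[1], volume$spacing[2], volume$spacing[3]))
  cleared <- volume
  if (isTRUE(config$holder$enabled)) {
    hc <- stage("holder", clear_holder(
      volume, min_size_frac = config$holder$min_size_frac,
      closing_radius = config$holder$closing_radius,
      binarize_method = config$holder$binarize_method))
    cleared <- hc$volume
    say(sprintf("holder cleared: edge found in %d/%d slices",
                hc$n_slices_with_edge, d[3]))
  }
  labels <- stage("segmentation", segment_grains(
    cleared, metric = config$seg$metric,
    merge_threshold = config$seg$merge_threshold,
    connectivity = config$seg$connectivity,
    min_volume = config$seg$min_volume))
  say(sprintf("segmentation: Otsu threshold %g, merge threshold %.2f vox, %d grains",
              attr(labels, "threshold"), attr(labels, "merge_threshold"),
              count_grains(labels)))
  records <- stage("traits", grain_records(
    cleared, labels, smooth_sigma = config$traits$smooth_sigma))
  traits <- stage("aggregate", aggregate_panicle(records, panicle_id))
  say(sprintf("traits: GN = %d, TGV = %.2f mm^3", traits$GN, traits$TGV))
  paths <- list()
  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    paths$labels <- file.path(config$output, "labels.nii")
    write_label_volume(labels, paths$labels)
    paths$grains <- file.path(config$output, "grains.csv")
    write_grain_csv(records, paths$grains)
    paths$traits <- file.path(config$output, "panicle_traits.csv")
    write_traits_csv(traits, paths$traits)
    say("artifacts written to ", config$output)
  }
  list(volume = volume, cleared = cleared, labels = labels,
       records = records, traits = traits, paths = paths)
}
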