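#' @useDynLib panicleCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed column order of the 22-trait panicle record.
PANICLE_TRAIT_NAMES <- c(
  "GN", "MGL", "SGL", "MGW", "SGW", "MGT", "SGT", "MLWR", "SLWR",
  "MWTR", "SWTR", "MED", "MS", "TGV", "MGV", "SGV", "TGS", "MGS",
  "SGS", "MCHV", "SCHV", "MGG")

#' Write per-panicle trait records to CSV
#'
#' One row per panicle: an identifier column `panicle` followed by the 22
#' trait columns in fixed order (GN, MGL, SGL, MGW, SGW, MGT, SGT, MLWR,
#' SLWR, MWTR, SWTR, MED, MS, TGV, MGV, SGV, TGS, MGS, SGS, MCHV, SCHV,
#' MGG).
#'
#' @param records a data.frame of panicle trait records (as returned by
#'   [aggregate_panicle()], possibly row-bound), or a list of them.
#' @param path output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_traits_csv <- function(records, path) {
  if (is.data.frame(records)) records <- list(records)
  if (length(records) == 0L) stop("nothing to write: no panicle records")
  df <- do.call(rbind, lapply(records, function(r) {
    if (!all(PANICLE_TRAIT_NAMES %in% names(r)))
      stop("record lacks some of the 22 trait columns")
    r[, c("panicle", PANICLE_TRAIT_NAMES)]
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read per-panicle trait records from CSV
#'
#' @param path CSV written by [write_traits_csv()].
#' @return data.frame with `panicle` plus the 22 trait columns.
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(PANICLE_TRAIT_NAMES, names(df))
  if (length(missing) > 0L)
    stop("trait CSV lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' Write per-grain measurement table to CSV
#'
#' @param records data.frame of grain records (one row per grain, as from
#'   [grain_records()]).
#' @param path output CSV path.
#' @export
write_grain_csv <- function(records, path) {
  if (nrow(records) == 0L) stop("nothing to write: no grain records")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(records)
}

#' Label-volume file round trip
#'
#' Label volumes are stored as NIfTI-2 (a widely supported n-dimensional
#' array container) with 32-bit integer data; voxel spacing travels in the
#' header's float64 pixdim, so the round trip is lossless.
#'
#' @param labels a [label_volume()].
#' @param path output path (`.nii`).
#' @return Invisibly, `path`.
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  arr <- labels$labels
  attr(arr, "pixdim") <- labels$spacing
  img <- RNifti::asNifti(arr, datatype = "int32")
  RNifti::writeNifti(img, path, version = 2)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read label volume: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(img), dim = dim(img))
  label_volume(arr, spacing = RNifti::pixdim(img)[1:3], compact = FALSE)
}
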