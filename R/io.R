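# Plain-text interchange: trial tables as CSV, ledgers as JSON, stat volumes
# as NIfTI (optional, via RNifti) or voxel CSV.

#' Write / read a trial table as CSV
#'
#' @param table a `trial_table`.
#' @param file path.
#' @return (read) a `trial_table`.
#' @export
write_trial_table <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write a variance ledger as JSON
#'
#' @param ledger a `variance_ledger`.
#' @param file path.
#' @export
write_ledger <- function(ledger, file) {
  jsonlite::write_json(unclass(ledger), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a stat volume as a voxel table (CSV)
#'
#' @param volume a `stat_volume` with a grid.
#' @param file path.
#' @export
write_stat_volume_csv <- function(volume, file) {
  if (is.null(volume$grid)) stop("stat volume carries no grid")
  df <- data.frame(volume$grid$positions, value = volume$values,
                   label = volume$grid$labels)
  names(df)[1:3] <- c("x", "y", "z")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a stat volume as NIfTI-1
#'
#' Rasterizes the regular grid into a volume (NA outside the mask) with an
#' affine built from the grid spacing and origin. Requires the `RNifti`
#' package.
#'
#' @param volume a `stat_volume` with a grid.
#' @param file path (`.nii` / `.nii.gz`).
#' @export
write_stat_volume_nifti <- function(volume, file) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export")
  }
  if (is.null(volume$grid)) stop("stat volume carries no grid")
  pos <- volume$grid$positions
  sp <- volume$grid$spacing
  ax <- lapply(1:3, function(k) sort(unique(pos[, k])))
  dims <- vapply(ax, length, integer(1))
  arr <- array(NA_real_, dims)
  idx <- cbind(match(pos[, 1], ax[[1]]), match(pos[, 2], ax[[2]]),
               match(pos[, 3], ax[[3]]))
  arr[idx] <- volume$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp, sp, sp)
  RNifti::writeNifti(img, file)
  invisible(file)
}
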