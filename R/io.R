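#' Write a recording to disk
#'
#' CSV is the lossless canonical format: first column `time_s`, one
#' column per channel named by its label. EDF stores 16-bit samples over
#' a per-channel symmetric physical range, so values round-trip to within
#' `range / 2^16`. Animal metadata, when present, is written to a JSON
#' sidecar `<path>.meta.json` and restored by [read_recording()].
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param format `"csv"` or `"edf"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") {
    tbl <- tibble::as_tibble(t(rec$samples))
    names(tbl) <- rec$channel_labels
    tbl <- dplyr::bind_cols(
      tibble::tibble(time_s = (seq_len(ncol(rec$samples)) - 1) /
                       rec$sampling_rate), tbl)
    readr::write_csv(tbl, path)
  } else {
    write_edf(rec, path)
  }
  if (!is.null(rec$meta)) {
    jsonlite::write_json(unclass(rec$meta), paste0(path, ".meta.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path CSV (see [write_recording()] for the layout) or EDF file.
#' @param format `"csv"`, `"edf"`, or `"auto"` (extension-based).
#' @param sampling_rate required for CSV when the time column is absent;
#'   otherwise inferred from the `time_s` column spacing.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           sampling_rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  rec <- if (format == "csv") {
    if (file.info(path)$size == 0) {
      abort(sprintf("malformed recording CSV: `%s` is empty", path))
    }
    tbl <- suppressMessages(readr::read_csv(path, show_col_types = FALSE))
    if (nrow(tbl) == 0 || ncol(tbl) < 1) {
      abort(sprintf("malformed recording CSV: `%s` has no data", path))
    }
    if ("time_s" %in% names(tbl)) {
      if (nrow(tbl) < 2) abort("recording CSV needs >= 2 samples")
      sampling_rate <- 1 / median(diff(tbl$time_s))
      tbl$time_s <- NULL
    } else if (is.null(sampling_rate)) {
      abort("malformed recording CSV: no `time_s` column and no sampling_rate given")
    }
    if (ncol(tbl) < 1) abort("malformed recording CSV: no channel columns")
    recording(t(as.matrix(tbl)), sampling_rate, names(tbl))
  } else {
    read_edf(path)
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    rec$meta <- do.call(animal_meta, m)
  }
  rec
}

#' Write a 3D volume (mask or label map) to disk
#'
#' Axis order is (z, y, x) throughout. TIFF writes one 8-bit page per z
#' slice (integer values must be <= 255); NIfTI preserves integers
#' exactly at any range.
#'
#' @param vol binary 3D array, or a [labeled_volume()].
#' @param path output path.
#' @param format `"tiff"`, `"nifti"` or `"auto"` (extension-based).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff"
  }
  voxels <- if (inherits(vol, "labeled_volume")) vol$voxels else vol
  if (length(dim(voxels)) != 3) abort("volume must be a 3D array (z, y, x)")
  if (any(voxels != round(voxels))) abort("volume values must be integers")
  if (format == "tiff") {
    if (max(voxels) > 255 || min(voxels) < 0) {
      abort("TIFF volumes support integer values in [0, 255]; use NIfTI")
    }
    pages <- lapply(seq_len(dim(voxels)[1]),
                    function(z) voxels[z, , ] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else {
    RNifti::writeNifti(RNifti::asNifti(aperm(voxels, c(3, 2, 1))), path)
  }
  invisible(path)
}

#' Read a 3D volume from disk
#'
#' @param path TIFF (multi-page) or NIfTI file.
#' @param format `"tiff"`, `"nifti"` or `"auto"`.
#' @param as `"array"` (default) returns the integer 3D array (z, y, x);
#'   `"labeled"` wraps it in a [labeled_volume()].
#' @param label_names optional label -> name map for `as = "labeled"`.
#' @return Integer 3D array or [labeled_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nifti"),
                        as = c("array", "labeled"), label_names = NULL) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff"
  }
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    first <- pages[[1]]
    if (length(dim(first)) != 2) {
      abort("expected single-channel grayscale TIFF pages")
    }
    voxels <- array(0L, c(length(pages), dim(first)))
    for (z in seq_along(pages)) {
      voxels[z, , ] <- as.integer(round(pages[[z]] * 255))
    }
  } else {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) == 2) {
      abort("volume must be 3D; got a 2D image")
    }
    if (length(dim(img)) != 3) abort("volume must be 3D")
    voxels <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
    if (any(voxels != round(voxels))) {
      abort("non-integer voxel values: not a mask or label volume")
    }
    voxels <- array(as.integer(round(voxels)), dim(voxels))
  }
  if (as == "labeled") labeled_volume(voxels, label_names) else voxels
}

#' Write a table as deterministic TSV
#'
#' Stable row order (as given), fixed 6-significant-digit formatting for
#' doubles, and a units suffix appended to numeric column names (e.g.
#' `value.lnuV2` for log-power) so every numeric column carries its
#' units.
#'
#' @param tbl data frame.
#' @param path output path.
#' @param units named character vector mapping column name -> units
#'   suffix; unnamed numeric columns keep their name.
#' @return `path`, invisibly.
#' @export
write_tsv_stable <- function(tbl, path, units = NULL) {
  out <- as.data.frame(tbl)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- signif(out[[nm]], 6)
  }
  if (!is.null(units)) {
    for (nm in intersect(names(units), names(out))) {
      names(out)[names(out) == nm] <- paste0(nm, ".", units[[nm]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the parameters, seed, package version and MD5 content hashes
#' of the inputs of a pipeline run.
#'
#' @param path output JSON path.
#' @param params named list of stage parameters.
#' @param seed integer seed used.
#' @param inputs character vector of input file paths to hash.
#' @param extra optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, params, seed, inputs = character(),
                           extra = list()) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- c(list(
    package = "lfpath",
    version = as.character(utils::packageVersion("lfpath")),
    r_version = as.character(getRversion()),
    seed = seed, params = params, input_md5 = hashes
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
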