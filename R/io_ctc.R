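## Reading and writing time-lapse sequences, 16-bit label masks and
## lineage ("track") text files in the Cell Tracking Challenge layout:
## a sequence is a directory of per-frame TIFFs in ascending filename
## order (t000.tif, t001.tif, ...); tracking references live under
## <seq>_GT/TRA as man_trackNNN.tif plus man_track.txt with one
## "L B E P" line per track.

#' Read a grayscale time-lapse sequence
#'
#' Reads an ordered stack of 2D grayscale frames either from a directory of
#' per-frame TIFF files (ascending filename order) or from a single
#' multi-page TIFF. Intensities are min-max scaled to \code{[0, 1]} over the
#' whole sequence (not per frame), so frame-to-frame contrast variation is
#' preserved.
#'
#' @param path Directory containing frame TIFFs, or a multi-page TIFF file.
#' @return A \code{sequence_handle}: list with \code{frames} (list of
#'   numeric matrices in \code{[0,1]}), \code{frame_ids} (0-based integers)
#'   and \code{dim}.
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  raw <- list()
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) < 2) stop("need at least 2 frames, found ", length(files))
    raw <- lapply(files, function(f) as_gray_matrix(tiff::readTIFF(f, as.is = TRUE)))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2) stop("need at least 2 frames, found ", length(pages))
    raw <- lapply(pages, as_gray_matrix)
  }
  d <- dim(raw[[1]])
  for (m in raw) if (!identical(dim(m), d)) stop("frames have mismatched shapes")
  lo <- min(vapply(raw, min, 0)); hi <- max(vapply(raw, max, 0))
  frames <- if (hi > lo) lapply(raw, function(m) (m - lo) / (hi - lo))
            else lapply(raw, function(m) m * 0)
  structure(list(frames = frames, frame_ids = seq_along(frames) - 1L, dim = d),
            class = "sequence_handle")
}

as_gray_matrix <- function(x) {
  if (length(dim(x)) == 3) x <- x[, , 1]   # first channel of multi-channel input
  storage.mode(x) <- "double"
  x
}

#' Write per-frame 16-bit label masks
#'
#' One single-channel 16-bit TIFF per frame, named
#' \code{<prefix>NNN.tif} with the zero-padded 0-based frame index.
#' Integer labels round-trip exactly through \code{\link{read_label_masks}}.
#'
#' @param labelmaps List of integer label matrices (0 = background).
#' @param path Output directory (created if missing).
#' @param prefix Filename prefix, default \code{"mask"}.
#' @export
write_label_masks <- function(labelmaps, path, prefix = "mask") {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (i in seq_along(labelmaps)) {
    m <- labelmaps[[i]]
    if (any(m < 0) || any(m > 65535)) stop("labels must fit in 16 bits")
    f <- file.path(path, sprintf("%s%03d.tif", prefix, i - 1L))
    tiff::writeTIFF(round(m) / 65535, f, bits.per.sample = 16)
  }
  invisible(NULL)
}

#' Read label masks written in the 16-bit mask convention
#' @param path Directory of mask TIFFs.
#' @param pattern Filename regexp, default any TIFF.
#' @return List of integer label matrices in ascending filename order.
#' @export
read_label_masks <- function(path, pattern = "\\.tiff?$") {
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) stop("no mask files in ", path)
  lapply(files, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  })
}

#' Validate "L B E P" track records
#'
#' Checks the structural invariants of a track table: positive labels,
#' begin <= end, no self-parenting, and every parent ending strictly
#' before its child begins.
#' @param records data.frame with columns label, begin, end, parent.
#' @return The records, invisibly; errors on violation.
#' @export
validate_track_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("label", "begin", "end", "parent") %in% names(records)))
  if (nrow(records) == 0) return(invisible(records))
  if (any(records$label <= 0)) stop("labels must be positive")
  if (any(records$begin > records$end)) stop("begin_frame > end_frame")
  if (any(records$parent == records$label)) stop("a track cannot be its own parent")
  withp <- records[records$parent > 0, , drop = FALSE]
  if (nrow(withp) > 0) {
    pend <- records$end[match(withp$parent, records$label)]
    if (any(is.na(pend))) stop("parent label not present in records")
    if (any(pend >= withp$begin)) stop("parent must end before child begins")
  }
  invisible(records)
}

#' Write a lineage text file ("L B E P" dialect)
#'
#' One line per track: label, begin frame, end frame, parent label
#' (0 = no parent), space separated, sorted by label.
#'
#' @param records data.frame with columns label, begin, end, parent.
#' @param path Output file path.
#' @export
write_track_file <- function(records, path) {
  validate_track_records(records)
  records <- records[order(records$label), , drop = FALSE]
  lines <- sprintf("%d %d %d %d", records$label, records$begin,
                   records$end, records$parent)
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a lineage text file ("L B E P" dialect)
#' @param path File with one "label begin end parent" line per track.
#' @return data.frame with columns label, begin, end, parent.
#' @export
read_track_file <- function(path) {
  if (!file.exists(path)) stop("missing track file: ", path)
  if (length(readLines(path, n = 1)) == 0)
    return(data.frame(label = integer(), begin = integer(),
                      end = integer(), parent = integer()))
  tab <- utils::read.table(path, col.names = c("label", "begin", "end", "parent"))
  validate_track_records(tab)
  tab
}
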