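#' Canonical 21-feature column names
#'
#' Fixed ordering \code{x1..x7, y1..y7, a1..a7}: centroid column, centroid
#' row and area for each of the seven instrument-part classes.
#'
#' @return character vector of length 21.
#' @export
feature_names <- function() {
  c(paste0("x", 1:7), paste0("y", 1:7), paste0("a", 1:7))
}

#' Kinematic features of one segmentation mask
#'
#' Reduces an H x W label mask to the 21 scalars used by the scoring
#' network. For each part class \code{c} present in the mask:
#' \code{x_c} = mean 0-based column index / (W - 1),
#' \code{y_c} = mean 0-based row index / (H - 1),
#' \code{a_c} = pixel count / (H * W). Absent classes contribute an exact
#' (0, 0, 0) triplet, keeping the dimensionality fixed at 21 regardless of
#' how many instruments are visible. Multiple connected components of one
#' class are treated as a single region (centroid of the union, summed
#' area).
#'
#' @param mask integer matrix with labels in 0..7 (0 = background).
#' @return named numeric vector of length 21, all values in \[0, 1\].
#' @export
#' @examples
#' m <- matrix(0L, 10, 10); m[1:2, 1:2] <- 3L
#' extract_frame_features(m)[c("x3", "y3", "a3")]  # 0.5/9, 0.5/9, 0.04
extract_frame_features <- function(mask) {
  stopifnot(is.matrix(mask), all(mask %in% 0:7))
  H <- nrow(mask); W <- ncol(mask)
  out <- stats::setNames(numeric(21), feature_names())
  for (cl in 1:7) {
    px <- which(mask == cl)
    if (!length(px)) next
    rows0 <- (px - 1L) %% H
    cols0 <- (px - 1L) %/% H
    out[cl] <- mean(cols0) / (W - 1)
    out[cl + 7L] <- mean(rows0) / (H - 1)
    out[cl + 14L] <- length(px) / (H * W)
  }
  out
}

#' Assemble a feature sequence from masks or feature rows
#'
#' Stacks per-frame features into the T x 21 matrix consumed by the scoring
#' network, optionally subsampling in time. Frame order is preserved and
#' the result length is \code{ceiling(n_frames / stride)}.
#'
#' @param frames either a list of masks (each passed through
#'   [extract_frame_features()]) or a numeric matrix whose rows are already
#'   21-feature vectors.
#' @param stride temporal subsampling factor (integer >= 1).
#' @return T x 21 matrix with an attached \code{stride} attribute.
#' @export
assemble_sequence <- function(frames, stride = 1L) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be an integer >= 1")
  if (is.list(frames)) {
    frames <- t(vapply(frames, extract_frame_features, numeric(21)))
  }
  frames <- as.matrix(frames)
  if (ncol(frames) != 21) stop("feature rows must have exactly 21 columns")
  if (nrow(frames) < 1) stop("at least one frame is required")
  if (!all(is.finite(frames))) stop("features must be finite")
  out <- frames[seq(1L, nrow(frames), by = stride), , drop = FALSE]
  colnames(out) <- feature_names()
  attr(out, "stride") <- stride
  out
}

#' Read and write feature sequences as CSV
#'
#' CSV files carry the fixed 21-column header \code{x1..x7,y1..y7,a1..a7},
#' one row per frame.
#'
#' @param seq_mat T x 21 feature matrix.
#' @param path file path.
#' @return the matrix (reader) or the path, invisibly (writer).
#' @export
write_sequence_csv <- function(seq_mat, path) {
  stopifnot(ncol(seq_mat) == 21)
  df <- as.data.frame(seq_mat)
  names(df) <- feature_names()
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(identical(names(df), feature_names()))
  as.matrix(df)
}

#' Extract one feature sequence per surgery from a mask directory
#'
#' Convenience wrapper for the mask-to-features stage of the pipeline:
#' reads every mask PNG in a directory (sorted by file name, assumed to be
#' frame order), extracts per-frame features and assembles the sequence.
#'
#' @param mask_dir directory of mask PNG files.
#' @param stride temporal subsampling factor.
#' @return T x 21 feature matrix.
#' @export
features_from_mask_dir <- function(mask_dir, stride = 1L) {
  files <- sort(list.files(mask_dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no mask PNGs found in ", mask_dir)
  assemble_sequence(lapply(files, read_mask_png), stride = stride)
}
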