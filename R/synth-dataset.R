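#' Generate a synthetic surgery dataset on disk
#'
#' Writes \code{n_surgeries} surgery directories, each holding a handful of
#' labeled frames (PNG + label-mask PNG), one feature sequence (CSV) and
#' one rating record (JSON), plus a top-level \code{manifest.json} listing
#' the surgery ids — the unit of bootstrap resampling and train/eval
#' splitting. Regeneration with the same seed is byte-identical.
#'
#' @param n_surgeries number of surgeries (>= 1).
#' @param out_dir output directory (created if missing).
#' @param scene a [scene_spec()] template (its seed is re-derived per
#'   frame).
#' @param trajectory a [trajectory_spec()] template (seed re-derived per
#'   surgery).
#' @param rule a [calibrate_score_rule()] result.
#' @param frames_per_surgery labeled frames written per surgery.
#' @param seed master seed; all per-surgery and per-frame seeds derive
#'   from it.
#' @return invisibly, the manifest (list with surgery ids and paths).
#' @export
generate_dataset <- function(n_surgeries, out_dir,
                             scene = scene_spec(),
                             trajectory = trajectory_spec(),
                             rule = NULL,
                             frames_per_surgery = 3, seed = 1L) {
  if (n_surgeries < 1) stop("n_surgeries must be >= 1")
  if (is.null(rule)) rule <- calibrate_score_rule(trajectory)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  sseeds <- derive_seeds(seed, n_surgeries)
  fseeds <- derive_seeds(seed + 1L, n_surgeries * frames_per_surgery)
  ids <- sprintf("surgery_%03d", seq_len(n_surgeries))
  for (i in seq_len(n_surgeries)) {
    sdir <- file.path(out_dir, ids[i])
    dir.create(file.path(sdir, "frames"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(sdir, "masks"), showWarnings = FALSE)
    for (f in seq_len(frames_per_surgery)) {
      sp <- scene
      sp$seed <- fseeds[(i - 1L) * frames_per_surgery + f]
      sc <- generate_scene(sp)
      write_frame_png(sc$frame,
                      file.path(sdir, "frames", sprintf("frame_%03d.png", f)))
      write_mask_png(sc$mask,
                     file.path(sdir, "masks", sprintf("mask_%03d.png", f)))
    }
    tsp <- trajectory
    tsp$seed <- sseeds[i]
    cs <- generate_trajectory_case(tsp, rule, ids[i])
    write_sequence_csv(cs$sequence, file.path(sdir, "sequence.csv"))
    write_rating_json(cs$record, file.path(sdir, "rating.json"))
  }
  manifest <- list(surgeries = ids, n = n_surgeries,
                   frames_per_surgery = frames_per_surgery, seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read and write rating records as JSON
#'
#' @param record a [rating_record()].
#' @param path file path.
#' @return the record (reader) or the path, invisibly (writer).
#' @export
write_rating_json <- function(record, path) {
  jsonlite::write_json(
    list(surgery_id = record$surgery_id,
         gears = as.list(record$gears), osats = as.list(record$osats),
         task = record$task, rater_id = record$rater_id,
         valid = record$valid),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rating_json
#' @export
read_rating_json <- function(path) {
  x <- jsonlite::read_json(path)
  rating_record(x$surgery_id, unlist(x$gears), unlist(x$osats), x$task,
                rater_id = x$rater_id, valid = isTRUE(x$valid))
}

#' Load a generated dataset from disk
#'
#' Reads the manifest, sequences and ratings written by
#' [generate_dataset()]; frames and masks are listed by path and loaded
#' lazily by the caller.
#'
#' @param dir dataset directory containing \code{manifest.json}.
#' @return list of per-surgery entries: \code{surgery_id}, \code{sequence},
#'   \code{record}, \code{frame_paths}, \code{mask_paths}.
#' @export
load_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  lapply(mf$surgeries, function(id) {
    sdir <- file.path(dir, id)
    list(surgery_id = id,
         sequence = read_sequence_csv(file.path(sdir, "sequence.csv")),
         record = read_rating_json(file.path(sdir, "rating.json")),
         frame_paths = sort(list.files(file.path(sdir, "frames"),
                                       full.names = TRUE)),
         mask_paths = sort(list.files(file.path(sdir, "masks"),
                                      full.names = TRUE)))
  })
}
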