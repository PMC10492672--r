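#' Subcategory names and task labels
#'
#' Canonical orderings used throughout the package: the six GEARS
#' subcategories (Depth Perception, Bimanual Dexterity, Efficiency, Force
#' Sensitivity, Autonomy, Robotic Control), the seven OSATS subcategories
#' (Respect for Tissue, Time and Motion, Instrument Handling, Knowledge of
#' Instruments, Assistance, Flow of Operation, Knowledge of Procedure), and
#' the three surgical task segments.
#'
#' @return character vector of names.
#' @export
gears_subcategories <- function() {
  c("depth_perception", "bimanual_dexterity", "efficiency",
    "force_sensitivity", "autonomy", "robotic_control")
}

#' @rdname gears_subcategories
#' @export
osats_subcategories <- function() {
  c("respect_for_tissue", "time_and_motion", "instrument_handling",
    "knowledge_of_instruments", "assistance", "flow_of_operation",
    "knowledge_of_procedure")
}

#' @rdname gears_subcategories
#' @export
task_labels <- function() c("cut", "recon", "bolster")

#' Construct a per-video rating record
#'
#' Bundles one rater's assessment of one surgery: six GEARS and seven OSATS
#' subcategory scores on the ordinal 1-5 scale, the surgical task label, and
#' a validity flag (records marked invalid by reviewers are excluded from
#' training and metrics).
#'
#' @param surgery_id identifier of the surgery (bootstrap resampling unit).
#' @param gears named integer vector or list, one score in 1..5 per GEARS
#'   subcategory (names as in [gears_subcategories()]).
#' @param osats named integer vector or list, one score in 1..5 per OSATS
#'   subcategory.
#' @param task one of [task_labels()].
#' @param rater_id optional rater identifier.
#' @param valid logical validity flag.
#' @return object of class \code{rating_record}.
#' @export
rating_record <- function(surgery_id, gears, osats, task,
                          rater_id = "synthetic", valid = TRUE) {
  gears <- unlist(gears)[gears_subcategories()]
  osats <- unlist(osats)[osats_subcategories()]
  names(gears) <- gears_subcategories()
  names(osats) <- osats_subcategories()
  stopifnot(!anyNA(gears), !anyNA(osats),
            all(gears %in% 1:5), all(osats %in% 1:5))
  task <- match.arg(task, task_labels())
  structure(
    list(surgery_id = surgery_id,
         gears = stats::setNames(as.integer(gears), gears_subcategories()),
         osats = stats::setNames(as.integer(osats), osats_subcategories()),
         task = task,
         rater_id = rater_id, valid = isTRUE(valid)),
    class = "rating_record"
  )
}

#' @export
print.rating_record <- function(x, ...) {
  cat("<rating_record>", x$surgery_id,
      if (!x$valid) "[INVALID]" else "", "\n")
  cat("  task:", x$task, " rater:", x$rater_id, "\n")
  cat("  GEARS:", paste(names(x$gears), x$gears, sep = "=", collapse = " "), "\n")
  cat("  OSATS:", paste(names(x$osats), x$osats, sep = "=", collapse = " "), "\n")
  invisible(x)
}

check_scoreset <- function(pred, truth) {
  if (is.null(names(pred)) || is.null(names(truth)) ||
      !setequal(names(pred), names(truth))) {
    stop("prediction and truth must share the same subcategory keys")
  }
  truth[names(pred)]
}

#' Exact-match accuracy between two score sets
#'
#' The fraction of subcategories whose scores agree exactly between two
#' raters (or between model and rater). GEARS and OSATS are reported
#' separately (denominators 6 and 7 respectively) when full records are
#' compared.
#'
#' @param pred,truth named integer vectors of subcategory scores with
#'   identical keys, or two \code{rating_record} objects.
#' @return for vectors, a single fraction in \[0, 1\]; for records, a named
#'   vector \code{c(gears, osats, task)} where \code{task} is 1 or 0.
#' @export
matching_accuracy <- function(pred, truth) {
  if (inherits(pred, "rating_record") && inherits(truth, "rating_record")) {
    return(c(gears = mean(pred$gears == truth$gears),
             osats = mean(pred$osats == truth$osats),
             task = as.numeric(pred$task == truth$task)))
  }
  truth <- check_scoreset(pred, truth)
  mean(pred == truth)
}

#' Signed per-subcategory residuals
#'
#' \code{predicted - true} for each subcategory; positive residuals mean the
#' model rates the surgeon's skill higher than the human rater did.
#'
#' @inheritParams matching_accuracy
#' @return named numeric vector of signed differences.
#' @export
residuals_scores <- function(pred, truth) {
  if (inherits(pred, "rating_record") && inherits(truth, "rating_record")) {
    return(stats::setNames(
      c(as.numeric(pred$gears - truth$gears),
        as.numeric(pred$osats - truth$osats)),
      c(gears_subcategories(), osats_subcategories())
    ))
  }
  truth <- check_scoreset(pred, truth)
  stats::setNames(as.numeric(pred) - as.numeric(truth), names(pred))
}
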