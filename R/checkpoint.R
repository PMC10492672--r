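#' Save and load model checkpoints
#'
#' A checkpoint is a single binary file holding the parameter arrays
#' together with the model configuration embedded as JSON, so a checkpoint
#' is self-describing and can be rebuilt without the originating script.
#'
#' @param model a \code{segmenter} or \code{scorer}.
#' @param path checkpoint file path.
#' @return the model (loader) or the path, invisibly (saver).
#' @export
save_checkpoint <- function(model, path) {
  kind <- class(model)[1]
  cfg <- unclass(model$config)
  saveRDS(list(kind = kind,
               config_json = jsonlite::toJSON(cfg, auto_unbox = TRUE),
               params = model$params),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  cfg <- jsonlite::fromJSON(x$config_json)
  model <- if (x$kind == "segmenter") {
    build_segmenter(do.call(seg_config, cfg[names(cfg) != "n_classes"]))
  } else if (x$kind == "scorer") {
    build_scorer(do.call(score_config, cfg))
  } else {
    stop("unknown checkpoint kind: ", x$kind)
  }
  model$params <- x$params
  model
}
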