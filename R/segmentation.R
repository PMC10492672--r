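#' Configuration of the attention-augmented segmentation network
#'
#' An encoder-decoder ("U") fully convolutional network with five encoding
#' blocks, three bottleneck blocks and five decoding blocks. Each encoder
#' block is a 3x3 convolution + ReLU followed by 2x2 max pooling; decoder
#' blocks upsample, merge the encoder skip connection and convolve. A
#' single-head spatial self-attention layer over the bottleneck feature map
#' ("image global attention") and cross-image attention from decoder
#' features to their skip-connection features (in the selected decoder
#' blocks) let the network reweight feature-map locations.
#'
#' @param base_channels channel width of the first encoder block; deeper
#'   blocks use \code{min(2^(l-1), 4) * base_channels}.
#' @param encoder_blocks,decoder_blocks,bottleneck_blocks block counts
#'   (defaults 5, 5, 3).
#' @param global_attention enable bottleneck self-attention.
#' @param cross_attention_decoders integer indices (1 = deepest) of decoder
#'   blocks that apply cross attention to their skip features.
#' @param seed parameter-initialization seed.
#' @return object of class \code{seg_config}.
#' @export
seg_config <- function(base_channels = 8, encoder_blocks = 5,
                       decoder_blocks = 5, bottleneck_blocks = 3,
                       global_attention = TRUE,
                       cross_attention_decoders = c(1, 2), seed = 1L) {
  stopifnot(encoder_blocks == decoder_blocks, base_channels >= 2)
  structure(list(base_channels = as.integer(base_channels),
                 encoder_blocks = as.integer(encoder_blocks),
                 decoder_blocks = as.integer(decoder_blocks),
                 bottleneck_blocks = as.integer(bottleneck_blocks),
                 global_attention = isTRUE(global_attention),
                 cross_attention_decoders =
                   as.integer(cross_attention_decoders),
                 n_classes = 8L, seed = as.integer(seed)),
            class = "seg_config")
}

seg_channels <- function(config) {
  L <- config$encoder_blocks
  config$base_channels * pmin(2^(seq_len(L) - 1), 4)
}

#' Build a segmentation network
#'
#' Instantiates all parameters of the network described by a [seg_config()].
#' Initialization is deterministic in the config seed: the same config built
#' twice yields identical parameters.
#'
#' @param config a [seg_config()].
#' @return object of class \code{segmenter} holding the parameter list and
#'   config.
#' @export
build_segmenter <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  ch <- seg_channels(config)
  L <- config$encoder_blocks
  with_seed(config$seed, {
    p <- list()
    cin <- 3L
    for (l in seq_len(L)) {
      p[[paste0("enc", l, "_W")]] <- he_init(9 * cin, ch[l], 9 * cin)
      p[[paste0("enc", l, "_b")]] <- numeric(ch[l])
      cin <- ch[l]
    }
    for (i in seq_len(config$bottleneck_blocks)) {
      p[[paste0("bot", i, "_W")]] <- he_init(9 * ch[L], ch[L], 9 * ch[L])
      p[[paste0("bot", i, "_b")]] <- numeric(ch[L])
    }
    if (config$global_attention) {
      ap <- attn_init(ch[L], ch[L])
      for (nm in names(ap)) p[[paste0("gattn_", nm)]] <- ap[[nm]]
    }
    cin <- ch[L]
    for (l in seq_len(L)) {
      cskip <- ch[L - l + 1L]
      if (l %in% config$cross_attention_decoders) {
        ap <- attn_init(cskip, cskip)
        for (nm in names(ap)) p[[paste0("xattn", l, "_", nm)]] <- ap[[nm]]
        # cross attention queries come from the upsampled decoder features
        p[[paste0("xattn", l, "_Wqin")]] <- he_init(cin, cskip, cin)
      }
      p[[paste0("dec", l, "_W")]] <- he_init(9 * (cin + cskip), cskip,
                                             9 * (cin + cskip))
      p[[paste0("dec", l, "_b")]] <- numeric(cskip)
      cin <- cskip
    }
    p[["out_W"]] <- he_init(ch[1], config$n_classes, ch[1])
    p[["out_b"]] <- numeric(config$n_classes)
    structure(list(params = p, config = config), class = "segmenter")
  })
}

#' Number of trainable parameters
#' @param model a \code{segmenter} or \code{scorer}.
#' @return integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

check_seg_dims <- function(config, H, W) {
  f <- 2^config$encoder_blocks
  if (H %% f != 0 || W %% f != 0 || H < f || W < f) {
    stop("frame dims ", H, "x", W, " are not divisible by ", f,
         " (required for ", config$encoder_blocks,
         " downsamplings); pad the frame to a multiple of ", f)
  }
}

# Attention over a feature map: flatten H x W x C to (H*W) x C tokens.
flat_tokens <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3])
}

seg_forward <- function(model, frame) {
  p <- model$params
  cfg <- model$config
  d <- dim(frame)
  check_seg_dims(cfg, d[1], d[2])
  L <- cfg$encoder_blocks
  cache <- list(dims = d)
  x <- frame
  for (l in seq_len(L)) {
    cv <- conv2d_fwd(x, p[[paste0("enc", l, "_W")]],
                     p[[paste0("enc", l, "_b")]], 3L)
    rl <- relu_fwd(cv$y)
    pl <- maxpool2_fwd(rl$y)
    cache[[paste0("enc", l)]] <- list(cv = cv, rl = rl, pl = pl,
                                      skip = rl$y)
    x <- pl$y
  }
  for (i in seq_len(cfg$bottleneck_blocks)) {
    cv <- conv2d_fwd(x, p[[paste0("bot", i, "_W")]],
                     p[[paste0("bot", i, "_b")]], 3L)
    rl <- relu_fwd(cv$y)
    cache[[paste0("bot", i)]] <- list(cv = cv, rl = rl)
    x <- rl$y
  }
  if (cfg$global_attention) {
    tok <- flat_tokens(x)
    ap <- list(Wq = p$gattn_Wq, Wk = p$gattn_Wk, Wv = p$gattn_Wv,
               Wo = p$gattn_Wo)
    at <- attn_fwd(tok, tok, ap)
    cache$gattn <- list(at = at, dims = dim(x))
    x <- array(at$y, dim(x))
  }
  for (l in seq_len(L)) {
    up <- upsample2_fwd(x)
    skip <- cache[[paste0("enc", L - l + 1L)]]$skip
    dcache <- list(updims = dim(up))
    if (l %in% cfg$cross_attention_decoders) {
      qin <- flat_tokens(up) %*% p[[paste0("xattn", l, "_Wqin")]]
      ap <- list(Wq = p[[paste0("xattn", l, "_Wq")]],
                 Wk = p[[paste0("xattn", l, "_Wk")]],
                 Wv = p[[paste0("xattn", l, "_Wv")]],
                 Wo = p[[paste0("xattn", l, "_Wo")]])
      at <- attn_fwd(qin, flat_tokens(skip), ap)
      dcache$xattn <- list(at = at, up = up, qin = qin,
                           skipdims = dim(skip))
      skip <- array(at$y, dim(skip))
    }
    d1 <- dim(up)[3]
    merged <- array(c(up, skip), c(dim(up)[1:2], d1 + dim(skip)[3]))
    cv <- conv2d_fwd(merged, p[[paste0("dec", l, "_W")]],
                     p[[paste0("dec", l, "_b")]], 3L)
    rl <- relu_fwd(cv$y)
    dcache$cv <- cv; dcache$rl <- rl; dcache$d1 <- d1
    cache[[paste0("dec", l)]] <- dcache
    x <- rl$y
  }
  cv <- conv2d_fwd(x, p$out_W, p$out_b, 1L)
  cache$out <- cv
  list(logits = cv$y, cache = cache)
}

seg_backward <- function(model, cache, dlogits) {
  p <- model$params
  cfg <- model$config
  L <- cfg$encoder_blocks
  g <- list()
  bk <- conv2d_bwd(dlogits, cache$out, p$out_W)
  g$out_W <- bk$dW; g$out_b <- bk$db
  dx <- bk$dx
  dskip <- vector("list", L)        # gradient flowing into each skip
  for (l in rev(seq_len(L))) {
    dc <- cache[[paste0("dec", l)]]
    dr <- relu_bwd(dx, dc$rl)
    bk <- conv2d_bwd(dr, dc$cv, p[[paste0("dec", l, "_W")]])
    g[[paste0("dec", l, "_W")]] <- bk$dW
    g[[paste0("dec", l, "_b")]] <- bk$db
    d1 <- dc$d1
    dup <- bk$dx[, , seq_len(d1), drop = FALSE]
    dsk <- bk$dx[, , -seq_len(d1), drop = FALSE]
    if (l %in% cfg$cross_attention_decoders) {
      at <- dc$xattn$at
      ap <- list(Wq = p[[paste0("xattn", l, "_Wq")]],
                 Wk = p[[paste0("xattn", l, "_Wk")]],
                 Wv = p[[paste0("xattn", l, "_Wv")]],
                 Wo = p[[paste0("xattn", l, "_Wo")]])
      ab <- attn_bwd(flat_tokens(dsk), at, ap)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        g[[paste0("xattn", l, "_", nm)]] <- ab[[paste0("d", nm)]]
      }
      g[[paste0("xattn", l, "_Wqin")]] <-
        crossprod(flat_tokens(dc$xattn$up), ab$dXq)
      dup <- dup + array(ab$dXq %*% t(p[[paste0("xattn", l, "_Wqin")]]),
                         dim(dup))
      dsk <- array(ab$dXkv, dc$xattn$skipdims)
    }
    dskip[[L - l + 1L]] <- dsk
    dx <- upsample2_bwd(dup)
  }
  if (cfg$global_attention) {
    ga <- cache$gattn
    ap <- list(Wq = p$gattn_Wq, Wk = p$gattn_Wk, Wv = p$gattn_Wv,
               Wo = p$gattn_Wo)
    ab <- attn_bwd(flat_tokens(dx), ga$at, ap)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      g[[paste0("gattn_", nm)]] <- ab[[paste0("d", nm)]]
    }
    dx <- array(ab$dXq + ab$dXkv, ga$dims)
  }
  for (i in rev(seq_len(cfg$bottleneck_blocks))) {
    bc <- cache[[paste0("bot", i)]]
    dr <- relu_bwd(dx, bc$rl)
    bk <- conv2d_bwd(dr, bc$cv, p[[paste0("bot", i, "_W")]])
    g[[paste0("bot", i, "_W")]] <- bk$dW
    g[[paste0("bot", i, "_b")]] <- bk$db
    dx <- bk$dx
  }
  for (l in rev(seq_len(L))) {
    ec <- cache[[paste0("enc", l)]]
    dpool <- maxpool2_bwd(dx, ec$pl)
    dr <- relu_bwd(dpool + dskip[[l]], ec$rl)
    bk <- conv2d_bwd(dr, ec$cv, p[[paste0("enc", l, "_W")]])
    g[[paste0("enc", l, "_W")]] <- bk$dW
    g[[paste0("enc", l, "_b")]] <- bk$db
    dx <- bk$dx
  }
  g
}

#' Predict the instrument-part mask of a frame
#'
#' Runs the network and assigns each pixel the class with the maximal
#' score; ties break toward the lower class index (background first).
#'
#' @param model a [build_segmenter()] network (trained or not).
#' @param frame H x W x 3 array in \[0, 1\].
#' @return H x W integer mask with labels in 0..7.
#' @export
predict_mask <- function(model, frame) {
  lg <- seg_forward(model, frame)$logits
  d <- dim(lg)
  cls <- max.col(matrix(lg, d[1] * d[2], d[3]), ties.method = "first") - 1L
  matrix(as.integer(cls), d[1], d[2])
}

#' Intersection over union of two masks
#'
#' Per-class IoU (overlap pixels divided by union pixels) and its mean.
#' Classes absent from both masks are excluded from the mean rather than
#' counted as perfect, so negative frames do not inflate scores.
#'
#' @param predicted,truth integer masks of identical dimensions.
#' @param classes class labels to evaluate (default 0:7).
#' @return list with \code{per_class} (named, NA for absent classes) and
#'   \code{mean}.
#' @export
#' @examples
#' a <- matrix(0L, 4, 4); b <- a; a[1:2, 1:2] <- 1L; b[2:3, 1:2] <- 1L
#' iou(a, b)$per_class[["1"]]  # 2 pixels overlap / 6 union
iou <- function(predicted, truth, classes = 0:7) {
  if (!all(dim(predicted) == dim(truth))) {
    stop("mask dimension mismatch: ", paste(dim(predicted), collapse = "x"),
         " vs ", paste(dim(truth), collapse = "x"))
  }
  per <- vapply(classes, function(cl) {
    pi <- predicted == cl
    ti <- truth == cl
    u <- sum(pi | ti)
    if (u == 0) NA_real_ else sum(pi & ti) / u
  }, numeric(1))
  names(per) <- as.character(classes)
  list(per_class = per, mean = mean(per, na.rm = TRUE))
}

#' Jointly augment a frame and its mask
#'
#' Applies one random similarity transform (scale, rotation about the image
#' center, translation) identically to the frame and the mask. The frame is
#' resampled with nearest neighbour as is the mask, so mask labels stay in
#' the input label set (plus background where the transform maps outside
#' the frame). Degenerate draws (|scale| < 0.05) are rejected and
#' resampled. Evaluation paths must not call this function.
#'
#' @param frame H x W x 3 array.
#' @param mask matching H x W integer mask.
#' @param params list with \code{scale} = c(min, max) scale factor range,
#'   \code{rotation} = max |angle| in degrees (or an explicit c(min, max)
#'   range), \code{shift} = max |offset| as a fraction of the image size
#'   (or an explicit range). A degenerate range such as c(90, 90) applies
#'   that exact transform.
#' @param seed integer seed for the transform draw.
#' @return list with transformed \code{frame} and \code{mask}, plus the
#'   drawn \code{transform} parameters.
#' @export
augment_pair <- function(frame, mask,
                         params = list(scale = c(0.9, 1.1), rotation = 15,
                                       shift = 0.1),
                         seed = 1L) {
  stopifnot(all(dim(frame)[1:2] == dim(mask)))
  H <- nrow(mask); W <- ncol(mask)
  as_range <- function(x) if (length(x) == 2) x else c(-x, x)
  rot <- as_range(params$rotation)
  sh <- as_range(params$shift)
  runif1 <- function(lo, hi) {
    if (lo == hi) lo else stats::runif(1, lo, hi)
  }
  tr <- with_seed(seed, {
    s <- 0
    for (i in 1:100) {
      s <- runif1(params$scale[1], params$scale[2])
      if (abs(s) >= 0.05) break
    }
    if (abs(s) < 0.05) stop("could not draw a non-degenerate scale")
    list(scale = s,
         theta = runif1(rot[1], rot[2]) * pi / 180,
         dx = runif1(sh[1], sh[2]) * W,
         dy = runif1(sh[1], sh[2]) * H)
  })
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  # inverse map: output (x, y) -> input pixel, nearest neighbour
  xo <- rep(0:(W - 1), each = H)
  yo <- rep(0:(H - 1), times = W)
  ux <- (xo - ctr[1] - tr$dx) / tr$scale
  uy <- (yo - ctr[2] - tr$dy) / tr$scale
  cth <- cos(-tr$theta); sth <- sin(-tr$theta)
  xi <- round(cth * ux - sth * uy + ctr[1])
  yi <- round(sth * ux + cth * uy + ctr[2])
  ok <- xi >= 0 & xi < W & yi >= 0 & yi < H
  src <- yi + xi * H + 1L
  new_mask <- matrix(0L, H, W)
  new_mask[ok] <- mask[src[ok]]
  new_frame <- array(0, dim(frame))
  for (ch in seq_len(dim(frame)[3])) {
    plane <- matrix(0, H, W)
    fch <- frame[, , ch]
    plane[ok] <- fch[src[ok]]
    new_frame[, , ch] <- plane
  }
  list(frame = new_frame, mask = new_mask, transform = tr)
}

#' Train the segmentation network
#'
#' Mini-batch Adam on per-pixel cross-entropy. Each optimizer step logs the
#' batch training IoU; held-out IoU is evaluated (without augmentation)
#' every \code{eval_every} steps and the parameters are checkpointed
#' whenever it improves.
#'
#' @param dataset list of \code{list(frame, mask)} pairs (negative examples
#'   allowed).
#' @param config a [seg_config()].
#' @param epochs,batch_size,lr optimization settings.
#' @param eval_data optional held-out list of pairs.
#' @param eval_every evaluate held-out IoU every this many steps.
#' @param eval_subset cap on the number of held-out pairs scored per
#'   evaluation.
#' @param augment augmentation parameter list as in [augment_pair()], or
#'   \code{NULL} to disable.
#' @param seed shuffling/augmentation seed.
#' @param verbose print progress lines.
#' @return list with \code{model} (final), \code{best_model} (checkpoint at
#'   best held-out IoU), \code{curve} (data.frame batch / train_iou /
#'   eval_iou) and \code{best_eval_iou}.
#' @export
train_segmenter <- function(dataset, config, epochs = 4, batch_size = 4,
                            lr = 3e-3, eval_data = NULL, eval_every = 10,
                            eval_subset = 16, augment = NULL, seed = 1L,
                            verbose = FALSE) {
  if (!length(dataset)) stop("empty dataset")
  if (!any(vapply(dataset, function(d) any(d$mask > 0), logical(1)))) {
    warning("dataset contains no positive (instrument) pixels")
  }
  model <- build_segmenter(config)
  state <- adam_init(model$params)
  curve <- list()
  best <- -Inf
  best_params <- model$params
  step <- 0L
  eval_iou_last <- NA_real_
  rng_seeds <- derive_seeds(seed, epochs * 2L + 1L)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(rng_seeds[ep], sample(length(dataset)))
    aug_seeds <- derive_seeds(rng_seeds[epochs + ep], length(ord))
    for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
      grads <- NULL
      tiou <- 0
      for (j in seq_along(bs)) {
        ex <- dataset[[bs[j]]]
        if (!is.null(augment)) {
          ex <- augment_pair(ex$frame, ex$mask, augment,
                             seed = aug_seeds[bs[j]])
        }
        fw <- seg_forward(model, ex$frame)
        d <- dim(fw$logits)
        ce <- softmax_ce(matrix(fw$logits, d[1] * d[2], d[3]),
                         as.vector(ex$mask) + 1L)
        g <- seg_backward(model, fw$cache,
                          array(ce$dz, d) / length(bs))
        grads <- acc_grads(grads, g)
        pm <- matrix(max.col(ce$P, ties.method = "first") - 1L, d[1], d[2])
        tiou <- tiou + iou(pm, ex$mask)$mean / length(bs)
      }
      upd <- adam_step(model$params, grads, state, lr = lr)
      model$params <- upd$params
      state <- upd$state
      step <- step + 1L
      if (!is.null(eval_data) && step %% eval_every == 0L) {
        eval_iou_last <- evaluate_segmenter(model,
          eval_data[seq_len(min(eval_subset, length(eval_data)))])$mean_iou
        if (eval_iou_last > best) {
          best <- eval_iou_last
          best_params <- model$params
        }
      }
      curve[[step]] <- c(batch = step, train_iou = tiou,
                         eval_iou = eval_iou_last)
      if (verbose && step %% 25 == 0) {
        message(sprintf("step %d train IoU %.3f eval IoU %.3f",
                        step, tiou, eval_iou_last))
      }
    }
  }
  best_model <- model
  best_model$params <- best_params
  list(model = model, best_model = best_model,
       curve = as.data.frame(do.call(rbind, curve)),
       best_eval_iou = if (is.finite(best)) best else NA_real_)
}

#' Mean held-out IoU of a segmentation model
#'
#' @param model a \code{segmenter}.
#' @param dataset list of \code{list(frame, mask)} pairs.
#' @return list with per-pair IoUs and their mean.
#' @export
evaluate_segmenter <- function(model, dataset) {
  ious <- vapply(dataset, function(ex) {
    iou(predict_mask(model, ex$frame), ex$mask)$mean
  }, numeric(1))
  list(per_frame = ious, mean_iou = mean(ious))
}
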