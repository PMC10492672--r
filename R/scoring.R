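#' Configuration of the multi-task scoring network (mtCNN)
#'
#' A shared temporal-convolution trunk over T x 21 feature sequences feeds
#' two pathways: the convolutional features themselves and an attention
#' pathway that produces normalized per-timestep weights. The weighted
#' features are collapsed by averaging over time, giving a fixed-size
#' summary for any sequence length, from which fourteen heads predict the
#' six GEARS subcategories, the seven OSATS subcategories (5-way ordinal
#' classifiers each) and the surgical task (3-way).
#'
#' Attention variants:
#' \describe{
#'   \item{WG}{Weight Gated — 1D convolutions on the input sequence
#'     followed by a temporal softmax produce the weight vectors.}
#'   \item{SA}{Self-Attention — weight vectors computed from the trunk
#'     features through a tanh bottleneck and temporal softmax.}
#'   \item{DP}{Direct self-attention pooling — learned queries attend over
#'     keys/values projected from the trunk features; the attention output
#'     replaces the weighted temporal average.}
#' }
#'
#' @param attention_variant one of \code{"WG"}, \code{"SA"}, \code{"DP"}.
#' @param trunk_channels channel widths of the stacked 1D convolutions.
#' @param kernel temporal kernel size (replicate padding, stride 1).
#' @param n_weights number of attention weight vectors (pooled summaries
#'   are concatenated).
#' @param attn_dim internal attention dimensionality.
#' @param head_hidden hidden width of each output head.
#' @param min_length sequences shorter than this are left-padded with zeros
#'   and the padding masked out of the attention softmax.
#' @param seed parameter-initialization seed.
#' @return object of class \code{score_config}.
#' @export
score_config <- function(attention_variant = c("SA", "WG", "DP"),
                         trunk_channels = c(32, 32, 32), kernel = 5,
                         n_weights = 4, attn_dim = 16, head_hidden = 32,
                         min_length = 16, seed = 1L) {
  attention_variant <- match.arg(attention_variant)
  structure(list(attention_variant = attention_variant,
                 trunk_channels = as.integer(trunk_channels),
                 kernel = as.integer(kernel),
                 n_weights = as.integer(n_weights),
                 attn_dim = as.integer(attn_dim),
                 head_hidden = as.integer(head_hidden),
                 min_length = as.integer(min_length),
                 seed = as.integer(seed)),
            class = "score_config")
}

score_head_names <- function() {
  c(gears_subcategories(), osats_subcategories(), "task")
}
score_head_sizes <- function() {
  stats::setNames(c(rep(5L, 13), 3L), score_head_names())
}

#' Build a scoring network
#'
#' Instantiates the mtCNN parameters for a [score_config()]. The trunk and
#' attention pathway are shared by all fourteen heads; only the head
#' parameters are task-specific. Initialization is deterministic in the
#' config seed.
#'
#' @param config a [score_config()].
#' @return object of class \code{scorer}.
#' @export
build_scorer <- function(config) {
  stopifnot(inherits(config, "score_config"))
  k <- config$kernel
  tc <- config$trunk_channels
  C <- tc[length(tc)]
  m <- config$n_weights
  da <- config$attn_dim
  with_seed(config$seed, {
    p <- list()
    cin <- 49L           # 21 features + differences + speed magnitudes
    for (l in seq_along(tc)) {
      p[[paste0("trunk", l, "_W")]] <- he_init(k * cin, tc[l], k * cin)
      p[[paste0("trunk", l, "_b")]] <- numeric(tc[l])
      cin <- tc[l]
    }
    if (config$attention_variant == "WG") {
      p$wg1_W <- he_init(k * 49L, da, k * 49L)
      p$wg1_b <- numeric(da)
      p$wg2_W <- he_init(k * da, m, k * da)
      p$wg2_b <- numeric(m)
      zdim <- m * C
    } else if (config$attention_variant == "SA") {
      p$sa_W1 <- he_init(C, da, C)
      p$sa_W2 <- he_init(da, m, da)
      zdim <- m * C
    } else {
      p$dp_Q <- he_init(m, da, da)
      p$dp_Wk <- he_init(C, da, C)
      p$dp_Wv <- he_init(C, da, C)
      zdim <- m * da
    }
    for (h in score_head_names()) {
      sz <- score_head_sizes()[[h]]
      p[[paste0("head_", h, "_W1")]] <- he_init(zdim, config$head_hidden,
                                                zdim)
      p[[paste0("head_", h, "_b1")]] <- numeric(config$head_hidden)
      p[[paste0("head_", h, "_W2")]] <- he_init(config$head_hidden, sz,
                                                config$head_hidden)
      p[[paste0("head_", h, "_b2")]] <- numeric(sz)
    }
    structure(list(params = p, config = config, zdim = zdim),
              class = "scorer")
  })
}

pad_sequence <- function(x, min_length) {
  T_ <- nrow(x)
  if (T_ >= min_length) {
    return(list(x = x, mask = rep(1, T_)))
  }
  padn <- min_length - T_
  list(x = rbind(matrix(0, padn, ncol(x)), x),
       mask = c(rep(0, padn), rep(1, min_length - padn)))
}

# Temporal softmax with padding mask: columns of s are weight vectors.
masked_softmax_cols <- function(s, mask) {
  s[mask == 0, ] <- -1e30
  t(softmax_rows(t(s)))
}

# Fixed input lift: the 21 raw features plus their scaled first temporal
# differences (the kinematic signal lives in frame-to-frame displacements,
# which are two orders of magnitude smaller than the positions themselves).
lift_sequence <- function(x) {
  x[, 15:21] <- x[, 15:21] * 25      # areas in ~percent-of-image units
  d <- rbind(matrix(0, 1, 21), diff(x)) * 25
  spd <- sqrt(d[, 1:7]^2 + d[, 8:14]^2)   # per-class centroid speed
  cbind(x, d, spd)
}

score_forward <- function(model, x) {
  cfg <- model$config
  p <- model$params
  if (!all(is.finite(x))) stop("sequence contains non-finite values")
  if (ncol(x) != 21) stop("sequences must have 21 feature columns")
  if (nrow(x) < 2) stop("sequence too short: T must be at least 2")
  pad <- pad_sequence(lift_sequence(as.matrix(x)), cfg$min_length)
  x <- pad$x
  msk <- pad$mask
  cache <- list(x = x, mask = msk)
  h <- x
  for (l in seq_along(cfg$trunk_channels)) {
    cv <- conv1d_fwd(h, p[[paste0("trunk", l, "_W")]],
                     p[[paste0("trunk", l, "_b")]], cfg$kernel)
    rl <- relu_fwd(cv$y)
    cache[[paste0("trunk", l)]] <- list(cv = cv, rl = rl)
    h <- rl$y
  }
  cache$H <- h
  if (cfg$attention_variant == "WG") {
    c1 <- conv1d_fwd(x, p$wg1_W, p$wg1_b, cfg$kernel)
    r1 <- relu_fwd(c1$y)
    c2 <- conv1d_fwd(r1$y, p$wg2_W, p$wg2_b, cfg$kernel)
    al <- masked_softmax_cols(c2$y, msk)
    z <- as.vector(crossprod(al, h))                  # m x C pooled, flat
    cache$att <- list(c1 = c1, r1 = r1, c2 = c2, alpha = al)
  } else if (cfg$attention_variant == "SA") {
    U <- tanh(h %*% p$sa_W1)
    sc <- U %*% p$sa_W2
    al <- masked_softmax_cols(sc, msk)
    z <- as.vector(crossprod(al, h))
    cache$att <- list(U = U, alpha = al)
  } else {
    K <- h %*% p$dp_Wk
    V <- h %*% p$dp_Wv
    sc <- p$dp_Q %*% t(K) / sqrt(cfg$attn_dim)       # m x T
    sc[, msk == 0] <- -1e30
    A <- softmax_rows(sc)
    z <- as.vector(A %*% V)
    cache$att <- list(K = K, V = V, A = A)
  }
  cache$z <- z
  probs <- list()
  for (hn in score_head_names()) {
    z1 <- as.numeric(z %*% p[[paste0("head_", hn, "_W1")]]) +
      p[[paste0("head_", hn, "_b1")]]
    a1 <- pmax(z1, 0)
    lg <- as.numeric(a1 %*% p[[paste0("head_", hn, "_W2")]]) +
      p[[paste0("head_", hn, "_b2")]]
    probs[[hn]] <- as.numeric(softmax_rows(matrix(lg, 1)))
    cache[[paste0("head_", hn)]] <- list(z1 = z1, a1 = a1, lg = lg)
  }
  cache$probs <- probs
  cache
}

# dlogits: named list (head -> gradient in that head's logits).
score_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  g <- list()
  dz <- numeric(length(cache$z))
  for (hn in names(dlogits)) {
    hc <- cache[[paste0("head_", hn)]]
    dl <- dlogits[[hn]]
    g[[paste0("head_", hn, "_W2")]] <- outer(hc$a1, dl)
    g[[paste0("head_", hn, "_b2")]] <- dl
    da1 <- as.numeric(p[[paste0("head_", hn, "_W2")]] %*% dl)
    dz1 <- da1 * (hc$z1 > 0)
    g[[paste0("head_", hn, "_W1")]] <- outer(cache$z, dz1)
    g[[paste0("head_", hn, "_b1")]] <- dz1
    dz <- dz + as.numeric(p[[paste0("head_", hn, "_W1")]] %*% dz1)
  }
  h <- cache$H
  msk <- cache$mask
  m <- cfg$n_weights
  dH <- matrix(0, nrow(h), ncol(h))
  if (cfg$attention_variant %in% c("WG", "SA")) {
    al <- cache$att$alpha
    dpool <- matrix(dz, m, ncol(h))                  # z = t(alpha) %*% H
    dal <- h %*% t(dpool)
    dH <- al %*% dpool
    dsc <- t(softmax_rows_bwd(t(dal), t(al)))
    dsc[msk == 0, ] <- 0
    if (cfg$attention_variant == "WG") {
      bk2 <- conv1d_bwd(dsc, cache$att$c2, p$wg2_W)
      g$wg2_W <- bk2$dW; g$wg2_b <- bk2$db
      dr1 <- relu_bwd(bk2$dx, cache$att$r1)
      bk1 <- conv1d_bwd(dr1, cache$att$c1, p$wg1_W)
      g$wg1_W <- bk1$dW; g$wg1_b <- bk1$db
    } else {
      U <- cache$att$U
      g$sa_W2 <- crossprod(U, dsc)
      dU <- dsc %*% t(p$sa_W2)
      dpre <- dU * (1 - U^2)
      g$sa_W1 <- crossprod(h, dpre)
      dH <- dH + dpre %*% t(p$sa_W1)
    }
  } else {
    A <- cache$att$A; K <- cache$att$K; V <- cache$att$V
    dpool <- matrix(dz, m, cfg$attn_dim)             # z = A %*% V
    dV <- crossprod(A, dpool)
    dA <- dpool %*% t(V)
    dS <- softmax_rows_bwd(dA, A)
    dS[, msk == 0] <- 0
    g$dp_Q <- dS %*% K / sqrt(cfg$attn_dim)
    dK <- crossprod(dS, p$dp_Q) / sqrt(cfg$attn_dim)
    g$dp_Wk <- crossprod(h, dK)
    g$dp_Wv <- crossprod(h, dV)
    dH <- dK %*% t(p$dp_Wk) + dV %*% t(p$dp_Wv)
  }
  for (l in rev(seq_along(cfg$trunk_channels))) {
    tc <- cache[[paste0("trunk", l)]]
    dr <- relu_bwd(dH, tc$rl)
    bk <- conv1d_bwd(dr, tc$cv, p[[paste0("trunk", l, "_W")]])
    g[[paste0("trunk", l, "_W")]] <- bk$dW
    g[[paste0("trunk", l, "_b")]] <- bk$db
    dH <- bk$dx
  }
  g
}

#' Run the scoring network on a feature sequence
#'
#' @param model a [build_scorer()] network.
#' @param sequence T x 21 feature matrix (any T >= 2; short sequences are
#'   zero-padded internally).
#' @return object of class \code{model_outputs}: named list of probability
#'   vectors, one per head (length 5 for the thirteen subcategories, 3 for
#'   the task), each non-negative and summing to 1.
#' @export
score_sequence <- function(model, sequence) {
  cache <- score_forward(model, sequence)
  structure(cache$probs, class = "model_outputs")
}

#' Per-timestep attention weights of a scorer
#'
#' For the WG and SA variants, returns the T x m matrix of temporal weights
#' (each column non-negative and summing to 1 over time). For DP, returns
#' the internal m x T attention map (rows normalized over time) together
#' with the pooled output.
#'
#' @param model a \code{scorer}.
#' @param sequence T x 21 feature matrix.
#' @return for WG/SA a weight matrix; for DP a list
#'   \code{(attention, pooled)}.
#' @export
attention_weights <- function(model, sequence) {
  cache <- score_forward(model, sequence)
  if (model$config$attention_variant %in% c("WG", "SA")) {
    cache$att$alpha
  } else {
    list(attention = cache$att$A,
         pooled = matrix(cache$z, model$config$n_weights,
                         model$config$attn_dim))
  }
}

#' Discrete labels from model outputs
#'
#' Each subcategory head's score is the index of its maximal probability
#' (1-5), ties breaking toward the lower score; the task is the label with
#' maximal probability.
#'
#' @param outputs a \code{model_outputs} object from [score_sequence()].
#' @return list with \code{gears}, \code{osats} (named integer vectors) and
#'   \code{task}.
#' @export
predict_labels <- function(outputs) {
  pick <- function(hn) which.max(outputs[[hn]])
  gears <- vapply(gears_subcategories(), pick, integer(1))
  osats <- vapply(osats_subcategories(), pick, integer(1))
  task <- task_labels()[which.max(outputs$task)]
  list(gears = gears, osats = osats, task = task)
}

#' Multi-task loss of a batch of outputs against rating records
#'
#' Sum over the thirteen subcategory heads of the chosen loss — mean
#' cross-entropy (\code{"CE"}) or the weighted-kappa loss
#' \code{log(1 - kappa + epsilon)} with the soft observed matrix
#' (\code{"WK"}) — plus cross-entropy on the task head (the task classes
#' are unordered, so an ordinal penalty is not meaningful there). The
#' weighted-kappa loss is computed per batch per head; batches of several
#' sequences are required for it to be informative. Records marked invalid
#' must be excluded by the caller.
#'
#' @param outputs_list list of \code{model_outputs}, one per sequence.
#' @param records list of matching [rating_record()]s.
#' @param loss_kind \code{"CE"} or \code{"WK"}.
#' @param epsilon guard constant for the WK logarithm.
#' @return scalar loss.
#' @export
multitask_loss <- function(outputs_list, records, loss_kind = c("CE", "WK"),
                           epsilon = 1e-6) {
  loss_kind <- match.arg(loss_kind)
  if (any(!vapply(records, `[[`, logical(1), "valid"))) {
    stop("invalid rating records must be excluded before computing the loss")
  }
  n <- length(outputs_list)
  total <- 0
  for (hn in score_head_names()) {
    P <- t(vapply(outputs_list, function(o) o[[hn]],
                  numeric(score_head_sizes()[[hn]])))
    y <- vapply(records, function(r) head_target(r, hn), integer(1))
    if (hn == "task" || loss_kind == "CE") {
      total <- total - mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
    } else {
      total <- total + wk_batch_loss(P, y, epsilon = epsilon)$loss
    }
  }
  total
}

head_target <- function(record, head_name) {
  if (head_name == "task") {
    match(record$task, task_labels())
  } else if (head_name %in% gears_subcategories()) {
    record$gears[[head_name]]
  } else {
    record$osats[[head_name]]
  }
}

#' Train the scoring network
#'
#' Mini-batch Adam on the multi-task loss: per-head cross-entropy or the
#' weighted-kappa loss (soft observed matrix accumulated per mini-batch per
#' head; the task head always uses cross-entropy). Invalid rating records
#' are dropped before training.
#'
#' @param cases list of \code{list(sequence, record)} pairs.
#' @param config a [score_config()].
#' @param loss \code{"CE"} or \code{"WK"}.
#' @param epochs,batch_size,lr optimization settings.
#' @param weight_decay decoupled L2 weight decay per Adam step.
#' @param wk_epsilon guard constant of the weighted-kappa logarithm used
#'   during training.
#' @param crop_range train-time augmentation: each presentation uses a
#'   random contiguous window covering this fraction range of the sequence
#'   (the score-rule statistics are time averages, so crops are
#'   label-preserving to first order); \code{NULL} disables.
#' @param seed shuffling seed.
#' @param verbose print epoch losses.
#' @return list with \code{model}, \code{history} (per-epoch mean batch
#'   loss) and the dropped-record count.
#' @export
train_scorer <- function(cases, config, loss = c("CE", "WK"), epochs = 30,
                         batch_size = 16, lr = 2e-3, weight_decay = 1e-3,
                         crop_range = c(0.5, 1), wk_epsilon = 1e-6,
                         seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  keep <- vapply(cases, function(cs) isTRUE(cs$record$valid), logical(1))
  dropped <- sum(!keep)
  cases <- cases[keep]
  if (length(cases) < 2) stop("need at least two valid cases")
  model <- build_scorer(config)
  state <- adam_init(model$params)
  history <- numeric(epochs)
  shuffle_seeds <- derive_seeds(seed, epochs)
  sizes <- score_head_sizes()
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * if (ep <= 0.6 * epochs) 1 else if (ep <= 0.85 * epochs) 1 / 3
                  else 1 / 10
    shuf <- with_seed(shuffle_seeds[ep], {
      ord <- sample(length(cases))
      lo <- if (is.null(crop_range)) rep(1, length(ord))
            else stats::runif(length(ord), crop_range[1], crop_range[2])
      list(ord = ord, lo = lo, st = stats::runif(length(ord)))
    })
    ord <- shuf$ord
    batches <- split(seq_along(ord), ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0
    for (bi in batches) {
      bs <- ord[bi]
      caches <- lapply(seq_along(bs), function(j) {
        sq <- cases[[bs[j]]]$sequence
        if (!is.null(crop_range)) {
          len <- max(16L, ceiling(shuf$lo[bi[j]] * nrow(sq)))
          if (len < nrow(sq)) {
            s0 <- 1L + floor(shuf$st[bi[j]] * (nrow(sq) - len))
            sq <- sq[s0:(s0 + len - 1L), , drop = FALSE]
          }
        }
        score_forward(model, sq)
      })
      recs <- lapply(cases[bs], `[[`, "record")
      nb <- length(bs)
      dlog <- vector("list", nb)
      for (j in seq_len(nb)) dlog[[j]] <- list()
      bl <- 0
      for (hn in score_head_names()) {
        P <- t(vapply(caches, function(ca) ca$probs[[hn]],
                      numeric(sizes[[hn]])))
        y <- vapply(recs, function(r) head_target(r, hn), integer(1))
        if (hn == "task" || loss == "CE") {
          sel <- cbind(seq_len(nb), y)
          bl <- bl - mean(log(pmax(P[sel], 1e-12)))
          dzmat <- P                         # CE grad directly in logits
          dzmat[sel] <- dzmat[sel] - 1
          dzmat <- dzmat / nb
        } else {
          wk <- wk_batch_loss(P, y, epsilon = wk_epsilon)
          bl <- bl + wk$loss
          dzmat <- softmax_rows_bwd(wk$dP, P)
        }
        for (j in seq_len(nb)) dlog[[j]][[hn]] <- dzmat[j, ]
      }
      grads <- NULL
      for (j in seq_len(nb)) {
        grads <- acc_grads(grads, score_backward(model, caches[[j]],
                                                 dlog[[j]]))
      }
      upd <- adam_step(model$params, grads, state, lr = lr_ep,
                       weight_decay = weight_decay)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bl / length(batches)
    }
    history[ep] <- ep_loss
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, ep_loss))
  }
  list(model = model, history = history, dropped_invalid = dropped)
}

#' Evaluate a scorer against ground-truth records
#'
#' Exact-match accuracy per subcategory, overall GEARS/OSATS/task
#' accuracies, and signed residuals (predicted minus true).
#'
#' @param model a trained \code{scorer}.
#' @param cases list of \code{list(sequence, record)} pairs.
#' @return list with \code{gears_acc}, \code{osats_acc}, \code{task_acc},
#'   \code{subcat_acc} (named, 13 entries), \code{residuals} (cases x 13
#'   matrix) and \code{mean_subcat_acc}.
#' @export
evaluate_scorer <- function(model, cases) {
  cases <- Filter(function(cs) isTRUE(cs$record$valid), cases)
  subs <- c(gears_subcategories(), osats_subcategories())
  res <- matrix(0, length(cases), 13, dimnames = list(NULL, subs))
  hit <- matrix(FALSE, length(cases), 13, dimnames = list(NULL, subs))
  task_hit <- logical(length(cases))
  for (i in seq_along(cases)) {
    out <- score_sequence(model, cases[[i]]$sequence)
    lab <- predict_labels(out)
    rec <- cases[[i]]$record
    pred <- c(lab$gears, lab$osats)
    true <- c(rec$gears, rec$osats)
    res[i, ] <- pred - true
    hit[i, ] <- pred == true
    task_hit[i] <- lab$task == rec$task
  }
  list(gears_acc = mean(hit[, gears_subcategories()]),
       osats_acc = mean(hit[, osats_subcategories()]),
       task_acc = mean(task_hit),
       subcat_acc = colMeans(hit),
       residuals = res,
       mean_subcat_acc = mean(hit))
}
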