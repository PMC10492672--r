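#' Split a dataset at surgery granularity
#'
#' Random train/eval partition of surgeries (the whole surgery goes to one
#' side, so no surgery leaks across the split), honoring the training
#' fraction after rounding.
#'
#' @param cases list of per-surgery entries (each with a \code{record}
#'   carrying \code{surgery_id}).
#' @param train_fraction fraction of surgeries assigned to training.
#' @param seed split seed.
#' @return list with \code{train} and \code{eval} sublists.
#' @export
split_by_surgery <- function(cases, train_fraction = 0.8, seed = 1L) {
  ids <- vapply(cases, function(cs) cs$record$surgery_id, character(1))
  uq <- unique(ids)
  if (length(uq) < 2) stop("need at least 2 surgeries to split")
  n_train <- round(train_fraction * length(uq))
  if (n_train < 1 || n_train >= length(uq)) {
    stop("train fraction leaves an empty train or eval set")
  }
  tr_ids <- with_seed(seed, sample(uq, n_train))
  list(train = cases[ids %in% tr_ids],
       eval = cases[!(ids %in% tr_ids)])
}

#' The 0.632 bootstrap estimator
#'
#' Combines the (optimistic) training-set metric and the (pessimistic)
#' out-of-bag metric: \code{0.368 * train + 0.632 * oob}. The weight is the
#' large-n probability that an item appears in a bootstrap resample,
#' \code{1 - 1/e}.
#'
#' @param train_metric,oob_metric metrics in \[0, 1\].
#' @return combined estimate, always between the two inputs.
#' @export
estimate_632 <- function(train_metric, oob_metric) {
  if (any(c(train_metric, oob_metric) < 0) ||
      any(c(train_metric, oob_metric) > 1)) {
    stop("metrics must lie in [0, 1]")
  }
  0.368 * train_metric + 0.632 * oob_metric
}

#' Mean distinct fraction of a bootstrap resample
#'
#' Draws \code{n} indices with replacement from \code{1..n} and measures
#' the fraction of distinct originals, averaged over replicates. Converges
#' to \code{1 - 1/e = 0.632} as n grows — the weighting constant of
#' [estimate_632()].
#'
#' @param n sample size.
#' @param replicates number of replicates.
#' @param seed RNG seed.
#' @return mean distinct fraction.
#' @export
bootstrap_distinct_fraction <- function(n = 10000, replicates = 200,
                                        seed = 1L) {
  with_seed(seed, {
    mean(vapply(seq_len(replicates), function(i) {
      length(unique(sample.int(n, n, replace = TRUE))) / n
    }, numeric(1)))
  })
}

#' Bootstrap evaluation of the scoring network
#'
#' Repeatedly resamples surgeries with replacement as the training multiset,
#' trains a scorer on each resample and evaluates on the out-of-bag
#' surgeries (those not drawn). Rounds whose out-of-bag set would be empty
#' are redrawn. Per-round training and out-of-bag subcategory accuracies
#' and residuals are recorded, along with the combined
#' [estimate_632()] of mean subcategory exact-match accuracy.
#'
#' @param cases list of \code{list(sequence, record)} per surgery.
#' @param rounds bootstrap rounds (the reference protocol uses over 1000;
#'   desk-scale analyses use fewer).
#' @param config a [score_config()].
#' @param loss,epochs,batch_size,lr,weight_decay,crop_range passed to
#'   [train_scorer()].
#' @param seed master seed.
#' @param verbose print per-round summaries.
#' @return object of class \code{bootstrap_result}: data.frame
#'   \code{rounds} (train/oob accuracy per round), matrices of per-round
#'   subcategory accuracies, residual list, and \code{estimate_632}.
#' @export
run_bootstrap <- function(cases, rounds = 50, config = score_config(),
                          loss = "CE", epochs = 20, batch_size = 16,
                          lr = 2e-3, weight_decay = 1e-3,
                          crop_range = c(0.5, 1), seed = 1L,
                          verbose = FALSE) {
  if (rounds < 1) stop("rounds must be >= 1")
  n <- length(cases)
  if (n < 2) stop("dataset too small for bootstrap resampling")
  round_seeds <- derive_seeds(seed, rounds * 2L)
  subs <- c(gears_subcategories(), osats_subcategories())
  rows <- list()
  tr_sub <- matrix(NA_real_, rounds, 13, dimnames = list(NULL, subs))
  ob_sub <- matrix(NA_real_, rounds, 13, dimnames = list(NULL, subs))
  residuals <- vector("list", rounds)
  bags <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    bag <- integer(0)
    att <- 0L
    repeat {    # redraw if the out-of-bag set is empty
      bag <- with_seed(round_seeds[r] + att, sample.int(n, n, replace = TRUE))
      if (length(setdiff(seq_len(n), bag)) > 0) break
      att <- att + 1L
    }
    oob <- setdiff(seq_len(n), bag)
    fit <- train_scorer(cases[bag], config, loss = loss, epochs = epochs,
                        batch_size = batch_size, lr = lr,
                        weight_decay = weight_decay,
                        crop_range = crop_range,
                        seed = round_seeds[rounds + r])
    ev_tr <- evaluate_scorer(fit$model, cases[unique(bag)])
    ev_ob <- evaluate_scorer(fit$model, cases[oob])
    rows[[r]] <- data.frame(round = r, n_oob = length(oob),
                            train_acc = ev_tr$mean_subcat_acc,
                            oob_acc = ev_ob$mean_subcat_acc,
                            train_task = ev_tr$task_acc,
                            oob_task = ev_ob$task_acc)
    tr_sub[r, ] <- ev_tr$subcat_acc
    ob_sub[r, ] <- ev_ob$subcat_acc
    residuals[[r]] <- ev_ob$residuals
    bags[[r]] <- list(bag = unique(bag), oob = oob)
    if (verbose) {
      message(sprintf("round %d: train %.3f oob %.3f (n_oob=%d)",
                      r, ev_tr$mean_subcat_acc, ev_ob$mean_subcat_acc,
                      length(oob)))
    }
  }
  rounds_df <- do.call(rbind, rows)
  structure(list(
    rounds = rounds_df,
    train_subcat = tr_sub,
    oob_subcat = ob_sub,
    residuals = residuals,
    bags = bags,
    estimate_632 = estimate_632(mean(rounds_df$train_acc),
                                mean(rounds_df$oob_acc))
  ), class = "bootstrap_result")
}

#' Per-subcategory bootstrap report
#'
#' Summarizes a [run_bootstrap()] result in the style of a subcategory
#' box-plot figure: accuracy quartiles for training and out-of-bag sets,
#' residual quartiles and outliers per subcategory, and the overall
#' \code{mean +/- sd} strings.
#'
#' @param result a \code{bootstrap_result}.
#' @return list with \code{subcategories} (data.frame of 13 rows),
#'   \code{overall} (formatted mean +/- sd for train/oob/0.632) and
#'   \code{estimate_632}.
#' @export
subcategory_report <- function(result) {
  stopifnot(inherits(result, "bootstrap_result"))
  if (!nrow(result$rounds)) stop("empty bootstrap result")
  subs <- colnames(result$train_subcat)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  tab <- do.call(rbind, lapply(subs, function(s) {
    res_s <- unlist(lapply(result$residuals, function(m) m[, s]))
    rq <- qs(res_s)
    iqr <- rq[3] - rq[1]
    out_lo <- rq[1] - 1.5 * iqr
    out_hi <- rq[3] + 1.5 * iqr
    data.frame(subcategory = s,
               train_q1 = qs(result$train_subcat[, s])[1],
               train_med = qs(result$train_subcat[, s])[2],
               train_q3 = qs(result$train_subcat[, s])[3],
               oob_q1 = qs(result$oob_subcat[, s])[1],
               oob_med = qs(result$oob_subcat[, s])[2],
               oob_q3 = qs(result$oob_subcat[, s])[3],
               resid_q1 = rq[1], resid_med = rq[2], resid_q3 = rq[3],
               n_resid_outliers = sum(res_s < out_lo | res_s > out_hi))
  }))
  fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  list(subcategories = tab,
       overall = c(train = fmt(result$rounds$train_acc),
                   oob = fmt(result$rounds$oob_acc),
                   task_oob = fmt(result$rounds$oob_task)),
       estimate_632 = result$estimate_632)
}
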