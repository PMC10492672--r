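#' Specification of a synthetic instrument trajectory
#'
#' Controls the generator of variable-length 21-feature sequences (centroid
#' x, centroid y and area for each of the seven part classes). Each case
#' draws a surgical regime (cut / recon / bolster) and case-level motion
#' multipliers, simulates smoothed random-walk arm motion with idle periods
#' and area drift, and adds measurement noise emulating segmentation error.
#'
#' @param length_range integer (min, max) sequence length in frames,
#'   min >= 10.
#' @param smoothness baseline random-walk step scale (normalized image units
#'   per frame).
#' @param idle_fraction mean proportion of frames with near-zero motion;
#'   cases draw their own fraction uniformly from \[0, 2 x idle_fraction\].
#' @param area_drift upper bound of the per-case multiplicative area
#'   variation scale.
#' @param noise_sd additive Gaussian noise on observed features (>= 0).
#' @param seed integer seed; same spec + seed is bit-for-bit reproducible.
#' @return object of class \code{trajectory_spec}.
#' @export
trajectory_spec <- function(length_range = c(40L, 120L), smoothness = 0.02,
                            idle_fraction = 0.2, area_drift = 0.25,
                            noise_sd = 0.01, seed = 1L) {
  stopifnot(length_range[1] >= 10, length_range[2] >= length_range[1],
            noise_sd >= 0, smoothness >= 0,
            idle_fraction >= 0, idle_fraction <= 0.45)
  structure(list(length_range = as.integer(length_range),
                 smoothness = smoothness, idle_fraction = idle_fraction,
                 area_drift = area_drift, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Kinematic summary statistics of a feature sequence
#'
#' The five scalar statistics that the synthetic score rule thresholds. All
#' five are time averages of local quantities, so they are recoverable from
#' the sequence by temporal convolution plus attention pooling:
#' \describe{
#'   \item{mean_speed}{mean per-frame centroid displacement over present
#'     classes (normalized image units per frame).}
#'   \item{jerk}{mean absolute second difference of centroid positions
#'     (motion roughness).}
#'   \item{idle_frac}{fraction of frames whose mean speed is at most the
#'     absolute idle threshold of 0.004 units/frame (1 for a static
#'     sequence).}
#'   \item{asymmetry}{absolute difference between left-arm (classes 1-3)
#'     and right-arm (classes 4-6) mean speeds.}
#'   \item{area_var}{mean absolute per-frame change of class areas (area
#'     fraction per frame).}
#' }
#'
#' @param seq_mat T x 21 feature matrix (columns x1..x7, y1..y7, a1..a7).
#' @return named numeric vector of the five statistics.
#' @export
trajectory_stats <- function(seq_mat) {
  stopifnot(ncol(seq_mat) == 21, nrow(seq_mat) >= 2)
  X <- seq_mat[, 1:7, drop = FALSE]
  Y <- seq_mat[, 8:14, drop = FALSE]
  A <- seq_mat[, 15:21, drop = FALSE]
  present <- which(colSums(A) > 0)
  if (!length(present)) {
    return(c(mean_speed = 0, jerk = 0, idle_frac = 1, asymmetry = 0,
             area_var = 0))
  }
  dX <- diff(X[, present, drop = FALSE])
  dY <- diff(Y[, present, drop = FALSE])
  sp <- sqrt(dX^2 + dY^2)                 # (T-1) x n_present
  speed_t <- rowMeans(sp)
  mean_speed <- mean(speed_t)
  d2 <- sqrt(diff(dX)^2 + diff(dY)^2)
  jerk <- if (nrow(sp) >= 2) mean(d2) else 0
  idle_frac <- mean(speed_t <= 0.004)
  arm_speed <- function(cls) {
    p <- intersect(cls, present)
    if (!length(p)) return(0)
    i <- match(p, present)
    mean(sp[, i, drop = FALSE])
  }
  asymmetry <- abs(arm_speed(1:3) - arm_speed(4:6))
  dA <- abs(diff(A[, present, drop = FALSE]))
  c(mean_speed = mean_speed, jerk = jerk, idle_frac = idle_frac,
    asymmetry = asymmetry, area_var = mean(dA))
}

# Mapping from subcategories to (statistic, direction). "rev" means a larger
# statistic indicates poorer skill (score 6 - bin).
rule_mapping <- function() {
  list(
    depth_perception = c("jerk", "rev"),
    bimanual_dexterity = c("asymmetry", "rev"),
    efficiency = c("idle_frac", "rev"),
    force_sensitivity = c("jerk", "rev"),
    autonomy = c("mean_speed", "fwd"),
    robotic_control = c("mean_speed", "rev"),
    respect_for_tissue = c("area_var", "rev"),
    time_and_motion = c("mean_speed", "fwd"),
    instrument_handling = c("jerk", "rev"),
    knowledge_of_instruments = c("asymmetry", "rev"),
    assistance = c("idle_frac", "rev"),
    flow_of_operation = c("idle_frac", "rev"),
    knowledge_of_procedure = c("area_var", "fwd")
  )
}

#' Deterministic rule mapping trajectory statistics to subcategory scores
#'
#' \code{calibrate_score_rule} samples noise-free latent trajectories under a
#' spec and fixes, once, the quintile cut-points of each statistic (so the
#' induced labels are balanced) plus the speed threshold separating the cut
#' and bolster task regimes among needle-free cases. The resulting rule is a
#' pure function: \code{apply_score_rule} bins the five statistics of a
#' sequence into 1-5 scores for all thirteen subcategories and classifies
#' the task (needle present -> recon; fast -> cut; slow -> bolster).
#'
#' @param spec a [trajectory_spec()] defining the sampling distribution.
#' @param n number of calibration samples.
#' @param seed calibration seed.
#' @return object of class \code{score_rule} with per-statistic cut-points.
#' @export
calibrate_score_rule <- function(spec = trajectory_spec(), n = 400,
                                 seed = 20L) {
  seeds <- derive_seeds(seed, n)
  sims <- lapply(seq_len(n), function(i) {
    sp <- spec; sp$seed <- seeds[i]
    lat <- simulate_latent_trajectory(sp)
    list(stats = trajectory_stats(lat$latent), needle = lat$needle)
  })
  stats_mat <- t(vapply(sims, `[[`, numeric(5), "stats"))
  cuts <- lapply(colnames(stats_mat), function(s)
    unname(stats::quantile(stats_mat[, s], c(0.2, 0.4, 0.6, 0.8))))
  names(cuts) <- colnames(stats_mat)
  needle_free <- which(!vapply(sims, `[[`, logical(1), "needle"))
  task_thr <- stats::median(stats_mat[needle_free, "mean_speed"])
  structure(list(cuts = cuts, mapping = rule_mapping(),
                 task_speed_threshold = task_thr),
            class = "score_rule")
}

#' @rdname calibrate_score_rule
#' @param rule a \code{score_rule}.
#' @param seq_mat T x 21 feature matrix (use the noise-free latent sequence
#'   for ground-truth labels).
#' @return \code{apply_score_rule}: list with \code{gears}, \code{osats}
#'   (named integer scores in 1..5) and \code{task}.
#' @export
apply_score_rule <- function(rule, seq_mat) {
  stopifnot(inherits(rule, "score_rule"))
  st <- trajectory_stats(seq_mat)
  score1 <- function(subcat) {
    m <- rule$mapping[[subcat]]
    b <- findInterval(st[[m[1]]], rule$cuts[[m[1]]]) + 1L
    if (m[2] == "rev") 6L - b else b
  }
  gears <- vapply(gears_subcategories(), score1, integer(1))
  osats <- vapply(osats_subcategories(), score1, integer(1))
  needle_area <- mean(seq_mat[, 21])
  task <- if (needle_area > 0) "recon"
          else if (st[["mean_speed"]] > rule$task_speed_threshold) "cut"
          else "bolster"
  list(gears = gears, osats = osats, task = task, stats = st)
}

# Deterministic stream of sub-seeds below 2^31 from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Simulate the noise-free latent trajectory for a spec. Classes 1-3 follow
# the left hand, 4-6 the right hand (small rigid offsets); the needle (7)
# trails the right grasper and is present only in the recon regime.
simulate_latent_trajectory <- function(spec) {
  with_seed(spec$seed, {
    T_ <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
    regime <- sample(c("cut", "recon", "bolster"), 1)
    speed_mult <- switch(regime,
      cut = stats::runif(1, 0.9, 2.0),
      bolster = stats::runif(1, 0.1, 0.6),
      recon = stats::runif(1, 0.1, 2.0))
    rho <- stats::runif(1, 0, 0.95)            # AR(1) smoothing: jerk control
    asym_ratio <- exp(stats::runif(1, -0.9, 0.9))
    idle_frac <- stats::runif(1, 0, 2 * spec$idle_fraction)
    drift_scale <- stats::runif(1, 0.02, max(0.03, spec$area_drift))
    needle <- regime == "recon"
    active <- stats::rbinom(T_, 1, 1 - min(idle_frac, 0.9))
    walk <- function(scale) {
      v <- matrix(0, T_, 2)
      eps <- matrix(stats::rnorm(T_ * 2, sd = scale), T_, 2)
      for (t in 2:T_) v[t, ] <- rho * v[t - 1, ] + (1 - rho) * eps[t, ]
      v * active
    }
    reflect <- function(p) {
      p <- abs(p - 0.05) + 0.05
      0.95 - abs(0.95 - p)
    }
    hand <- function(start, scale) {
      v <- walk(scale)
      pos <- apply(v, 2, cumsum)
      pos[, 1] <- reflect(start[1] + pos[, 1])
      pos[, 2] <- reflect(start[2] + pos[, 2])
      pos
    }
    s <- spec$smoothness * speed_mult
    left <- hand(c(stats::runif(1, 0.2, 0.4), stats::runif(1, 0.3, 0.7)),
                 s * sqrt(asym_ratio))
    right <- hand(c(stats::runif(1, 0.6, 0.8), stats::runif(1, 0.3, 0.7)),
                  s / sqrt(asym_ratio))
    offs <- matrix(stats::runif(14, -0.04, 0.04), 7, 2)
    X <- matrix(0, T_, 7); Y <- matrix(0, T_, 7); A <- matrix(0, T_, 7)
    present <- c(1:6, if (needle) 7L)
    for (cl in present) {
      anchor <- if (cl <= 3) left else right
      X[, cl] <- pmin(pmax(anchor[, 1] + offs[cl, 1], 0), 1)
      Y[, cl] <- pmin(pmax(anchor[, 2] + offs[cl, 2], 0), 1)
      base <- stats::runif(1, 0.01, 0.03)
      # stationary AR(1) in log-area: marginal sd = drift_scale, so the
      # realized coefficient of variation concentrates near drift_scale
      rho_a <- 0.9
      aw <- numeric(T_)
      aw[1] <- stats::rnorm(1, sd = drift_scale)
      innov <- stats::rnorm(T_, sd = drift_scale * sqrt(1 - rho_a^2))
      for (t in 2:T_) aw[t] <- rho_a * aw[t - 1] + innov[t]
      A[, cl] <- base * exp(aw)
    }
    list(latent = cbind(X, Y, A), regime = regime, needle = needle,
         T_ = T_)
  })
}

#' Generate one synthetic scored trajectory case
#'
#' Simulates a noise-free latent trajectory, scores it with the given rule
#' (the ground-truth labels therefore follow a known deterministic rule),
#' and returns the observed sequence: latent plus additive Gaussian feature
#' noise on present classes, clipped to \[0, 1\]. Absent classes keep exact
#' (0, 0, 0) triplets.
#'
#' @param spec a [trajectory_spec()].
#' @param rule a [calibrate_score_rule()] result.
#' @param surgery_id id stored in the rating record.
#' @return list with \code{sequence} (T x 21 matrix), \code{record}
#'   (a [rating_record()]) and \code{latent} (noise-free matrix).
#' @export
generate_trajectory_case <- function(spec, rule, surgery_id = "case") {
  stopifnot(inherits(spec, "trajectory_spec"), inherits(rule, "score_rule"))
  lat <- simulate_latent_trajectory(spec)
  labels <- apply_score_rule(rule, lat$latent)
  obs <- lat$latent
  if (spec$noise_sd > 0) {
    noise_seed <- (spec$seed %% 1000003L) * 2L + 1L
    obs <- with_seed(noise_seed, {
      nz <- which(colSums(lat$latent[, 15:21, drop = FALSE]) > 0)
      # Position error emulates segmentation imperfection: a pose-persistent
      # boundary bias (AR(1), marginal sd = noise_sd) plus a small
      # independent per-frame flicker. Area error is multiplicative
      # (boundary errors scale with region size, not image size).
      pos_cols <- c(nz, nz + 7L)
      T_ <- nrow(obs)
      rho_n <- 0.9
      e <- matrix(0, T_, 21)
      for (j in pos_cols) {
        b <- numeric(T_)
        b[1] <- stats::rnorm(1, sd = spec$noise_sd)
        innov <- stats::rnorm(T_, sd = spec$noise_sd * sqrt(1 - rho_n^2))
        for (t in 2:T_) b[t] <- rho_n * b[t - 1] + innov[t]
        e[, j] <- b + stats::rnorm(T_, sd = spec$noise_sd / 5)
      }
      out <- pmin(pmax(lat$latent + e, 0), 1)
      area_cols <- nz + 14L
      relerr <- exp(matrix(stats::rnorm(nrow(obs) * length(area_cols),
                                        sd = 2 * spec$noise_sd),
                           nrow(obs), length(area_cols)))
      out[, area_cols] <- pmin(lat$latent[, area_cols] * relerr, 1)
      out
    })
  }
  colnames(obs) <- feature_names()
  record <- rating_record(surgery_id, labels$gears, labels$osats,
                          labels$task)
  list(sequence = obs, record = record, latent = lat$latent)
}
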