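#' Configuration for the synthetic BOLD cohort generator
#'
#' Defines a cohort in which every participant watches the same set of
#' stimulus segments (`n_stimuli` clips, each shown once per frame condition,
#' mirroring a 12-stimuli-by-3-frames within-subject design). During the
#' segment for stimulus k under frame f, every signal voxel of participant i
#' carries
#' \deqn{\kappa_f (\cos\theta_i \, s^A(t) + \sin\theta_i \, s^B(t))}
#' where \eqn{s^A, s^B} are orthonormal shared latent time courses specific to
#' that segment and \eqn{\theta_i} is an affine map of participant i's
#' coupling covariate onto \eqn{[0, \gamma\,\pi/2]}. On top of the shared
#' signal each voxel receives AR(1) noise with marginal standard deviation
#' `sigma_noise`, a per-participant quadratic drift, and a linear leak of the
#' six motion regressors. Under this model the expected stimulus-locked
#' correlation between participants i and j at a signal voxel is
#' \eqn{\kappa_f^2 \cos(\theta_i - \theta_j) / (\kappa_f^2 + \sigma^2)}
#' (see [expected_pair_isc()]).
#'
#' @param n_participants number of participants.
#' @param grid_dims integer vector of length 3, voxels per axis.
#' @param voxel_size_mm isotropic voxel size in millimetres.
#' @param tr_s repetition time in seconds.
#' @param n_stimuli number of unique stimuli; each is shown once per frame.
#' @param frames frame condition labels.
#' @param topics topic labels, assigned to stimuli round-robin.
#' @param segment_duration_s duration of one stimulus segment in seconds.
#' @param gap_s inter-stimulus gap in seconds.
#' @param initial_rest_s rest before the first stimulus, seconds.
#' @param transient_s initial part of every segment (seconds) that carries no
#'   stimulus-locked signal, emulating the unsettled hemodynamic response at
#'   stimulus onset (default 12 s = 8 volumes at TR 1.5 s, matching the
#'   transient window the preprocessing stage excludes). Latent streams are
#'   standardized over the post-transient window.
#' @param kappa_by_frame named non-negative coupling amplitudes, one per frame.
#' @param sigma_noise marginal noise standard deviation, > 0.
#' @param ar1_phi AR(1) coefficient of the noise, in [0, 1). The innovation
#'   variance is `sigma_noise^2 * (1 - ar1_phi^2)` so the marginal variance
#'   stays `sigma_noise^2` for any `ar1_phi`.
#' @param gamma_proximity covariate-mixing strength in [0, 1]; 0 gives every
#'   participant the same mixing angle (synchrony independent of covariate
#'   distance), 1 spreads angles over the full quarter circle.
#' @param signal_voxel_fraction fraction of mask voxels carrying the shared
#'   signal, in (0, 1].
#' @param drift_amplitude standard deviation of the per-participant quadratic
#'   drift added to all mask voxels.
#' @param motion_amplitude amplitude of the motion-regressor leak into all
#'   mask voxels.
#' @param ma_width moving-average window (volumes) used to band-limit the
#'   latent streams.
#' @param coupling_covariate name of the covariate column that drives the
#'   mixing angle.
#' @param n_volumes run length in volumes; `NULL` (default) uses exactly the
#'   scheduled length.
#' @param seed integer seed; identical configurations produce bit-identical
#'   cohorts.
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()], [expected_pair_isc()]
#' @export
sim_config <- function(n_participants = 27,
                       grid_dims = c(8L, 8L, 8L),
                       voxel_size_mm = 2.5,
                       tr_s = 1.5,
                       n_stimuli = 12,
                       frames = c("neutral", "threat", "blame"),
                       topics = c("immigration", "climate", "healthcare"),
                       segment_duration_s = 100,
                       gap_s = 4.5,
                       initial_rest_s = 12,
                       transient_s = 12,
                       kappa_by_frame = c(neutral = 0.8, threat = 0.6, blame = 0.4),
                       sigma_noise = 1,
                       ar1_phi = 0.3,
                       gamma_proximity = 0.5,
                       signal_voxel_fraction = 0.1,
                       drift_amplitude = 0.3,
                       motion_amplitude = 0.5,
                       ma_width = 5,
                       coupling_covariate = "pvv_attitude",
                       n_volumes = NULL,
                       seed = 1) {
  cfg <- list(n_participants = as.integer(n_participants),
              grid_dims = as.integer(grid_dims),
              voxel_size_mm = voxel_size_mm,
              tr_s = tr_s,
              n_stimuli = as.integer(n_stimuli),
              frames = as.character(frames),
              topics = as.character(topics),
              segment_duration_s = segment_duration_s,
              gap_s = gap_s,
              initial_rest_s = initial_rest_s,
              transient_s = transient_s,
              kappa_by_frame = kappa_by_frame,
              sigma_noise = sigma_noise,
              ar1_phi = ar1_phi,
              gamma_proximity = gamma_proximity,
              signal_voxel_fraction = signal_voxel_fraction,
              drift_amplitude = drift_amplitude,
              motion_amplitude = motion_amplitude,
              ma_width = as.integer(ma_width),
              coupling_covariate = coupling_covariate,
              n_volumes = if (is.null(n_volumes)) NULL else as.integer(n_volumes),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_participants < 2)
    stop("need at least 2 participants")
  if (length(cfg$grid_dims) != 3 || any(cfg$grid_dims < 2))
    stop("grid_dims must be 3 integers >= 2")
  if (cfg$tr_s <= 0) stop("tr_s must be positive")
  if (!all(cfg$frames %in% names(cfg$kappa_by_frame)))
    stop("kappa_by_frame must name every frame: ",
         paste(setdiff(cfg$frames, names(cfg$kappa_by_frame)), collapse = ", "))
  if (any(cfg$kappa_by_frame < 0)) stop("coupling amplitudes must be >= 0")
  if (cfg$sigma_noise <= 0) stop("sigma_noise must be > 0")
  if (cfg$ar1_phi < 0 || cfg$ar1_phi >= 1) stop("ar1_phi must be in [0, 1)")
  if (cfg$gamma_proximity < 0 || cfg$gamma_proximity > 1)
    stop("gamma_proximity must be in [0, 1]")
  if (cfg$signal_voxel_fraction <= 0 || cfg$signal_voxel_fraction > 1)
    stop("signal_voxel_fraction must be in (0, 1]")
  if (cfg$drift_amplitude < 0 || cfg$motion_amplitude < 0)
    stop("amplitudes must be >= 0")
  if (cfg$ma_width < 1) stop("ma_width must be >= 1")
  if (cfg$segment_duration_s <= 0 || cfg$gap_s < 0 || cfg$initial_rest_s < 0)
    stop("schedule times must be non-negative (segment duration positive)")
  if (cfg$transient_s < 0 || cfg$transient_s >= cfg$segment_duration_s)
    stop("transient_s must be in [0, segment_duration_s)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  n_seg <- x$n_stimuli * length(x$frames)
  cat("Synthetic BOLD cohort configuration\n")
  cat(sprintf("  %d participants, %s grid, TR %.2f s\n",
              x$n_participants, paste(x$grid_dims, collapse = "x"), x$tr_s))
  cat(sprintf("  %d stimuli x %d frames = %d segments of %.0f s (gap %.1f s)\n",
              x$n_stimuli, length(x$frames), n_seg,
              x$segment_duration_s, x$gap_s))
  cat(sprintf("  kappa: %s; sigma %.2f; phi %.2f; gamma %.2f\n",
              paste(sprintf("%s=%.2f", names(x$kappa_by_frame),
                            x$kappa_by_frame), collapse = ", "),
              x$sigma_noise, x$ar1_phi, x$gamma_proximity))
  invisible(x)
}

# moving average with edge truncation, then standardized to mean 0, sd 1
smooth_standardize <- function(x, width) {
  n <- length(x)
  if (width > 1) {
    h <- (width - 1) %/% 2
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    x <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) stop("degenerate latent stream (zero variance)")
  x / s
}

#' Expected pairwise ISC under the generative model
#'
#' Closed-form stimulus-locked correlation between two participants at a
#' signal voxel: with equal coupling amplitude \eqn{\kappa_f} for both
#' participants, unit-variance orthogonal latent streams and independent noise
#' of variance \eqn{\sigma^2}, the covariance of the two series is
#' \eqn{\kappa_f^2 \cos(\theta_i - \theta_j)} and each variance is
#' \eqn{\kappa_f^2 + \sigma^2}, giving
#' \deqn{r = \kappa_f^2 \cos(\theta_i - \theta_j) / (\kappa_f^2 + \sigma^2).}
#'
#' @param config a [sim_config()].
#' @param theta_i,theta_j mixing angles of the two participants (radians).
#' @param frame frame condition label.
#' @return Expected Pearson correlation (vectorized over angles).
#' @export
expected_pair_isc <- function(config, theta_i, theta_j, frame) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(frame %in% config$frames))
    stop("unknown frame: ", paste(setdiff(frame, config$frames), collapse = ", "))
  k <- unname(config$kappa_by_frame[frame])
  k^2 * cos(theta_i - theta_j) / (k^2 + config$sigma_noise^2)
}

#' Mixing angles from a covariate
#'
#' Affine map of covariate scores onto \eqn{[0, \gamma \pi / 2]}; the angle is
#' monotone in the covariate so pairwise synchrony decays with covariate
#' distance (the proximity structure probed by the dyadic regression stage).
#' @param x covariate scores.
#' @param gamma mixing strength in [0, 1].
#' @return angles in radians.
#' @keywords internal
covariate_to_angle <- function(x, gamma) {
  if (gamma == 0) return(rep(0, length(x)))
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  gamma * (pi / 2) * (x - rng[1]) / diff(rng)
}

#' Simulate a synthetic fMRI cohort with known ground truth
#'
#' Generates per-participant 4D BOLD runs on an ellipsoidal brain mask, an
#' events table listing every stimulus segment, six motion nuisance regressors
#' per participant (which genuinely leak into the data), a participant
#' covariate table, and a ground-truth record (signal voxels, mixing angles,
#' latent streams). All outputs are a deterministic function of the
#' configuration, including its seed.
#'
#' @param config a [sim_config()].
#' @return An object of class `isc_cohort`: list with elements `runs` (list of
#'   [bold_run()]), `events` (data.frame: onset, duration, stimulus_id, frame,
#'   topic), `nuisance` (named list of data.frames, 6 motion columns),
#'   `covariates` (data.frame), `mask` (3D 0/1 array), `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  dims <- config$grid_dims
  n <- config$n_participants
  frames <- config$frames
  n_seg <- config$n_stimuli * length(frames)

  # schedule (shared across participants; segment-wise ISC is order-invariant)
  total_s <- config$initial_rest_s +
    n_seg * (config$segment_duration_s + config$gap_s)
  required_vols <- ceiling(total_s / config$tr_s)
  n_vol <- if (is.null(config$n_volumes)) required_vols else config$n_volumes
  if (n_vol < required_vols)
    stop(sprintf(paste0("stimulus schedule overflow: %d volumes required ",
                        "but only %d available"), required_vols, n_vol))

  stim_ids <- sprintf("stim%02d", seq_len(config$n_stimuli))
  stim_topic <- config$topics[((seq_len(config$n_stimuli) - 1) %%
                                 length(config$topics)) + 1]
  seg <- expand.grid(stimulus_id = stim_ids, frame = frames,
                     stringsAsFactors = FALSE)
  seg$topic <- stim_topic[match(seg$stimulus_id, stim_ids)]
  ord <- sample.int(n_seg)
  onset <- config$initial_rest_s +
    (seq_len(n_seg) - 1) * (config$segment_duration_s + config$gap_s)
  seg$onset <- onset[order(ord)]
  seg$duration <- config$segment_duration_s
  events <- data.frame(onset = seg$onset, duration = seg$duration,
                       stimulus_id = seg$stimulus_id, frame = seg$frame,
                       topic = seg$topic, stringsAsFactors = FALSE)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL

  # ellipsoidal mask
  ctr <- (dims + 1) / 2
  rad <- dims / 2
  gx <- (seq_len(dims[1]) - ctr[1]) / rad[1]
  gy <- (seq_len(dims[2]) - ctr[2]) / rad[2]
  gz <- (seq_len(dims[3]) - ctr[3]) / rad[3]
  dist2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  mask <- array(as.integer(dist2 <= 1), dim = dims)
  mask_idx <- which(mask == 1L)
  v_mask <- length(mask_idx)
  if (v_mask < 2) stop("mask is degenerate")

  n_signal <- max(1L, round(config$signal_voxel_fraction * v_mask))
  signal_ids <- sort(sample(mask_idx, n_signal))
  signal_rows <- match(signal_ids, mask_idx)

  # covariates and mixing angles
  covariates <- data.frame(
    participant_id = sprintf("sub%02d", seq_len(n)),
    pvv_attitude = runif(n, 0, 20),
    gl_attitude = runif(n, 0, 20),
    authoritarianism = runif(n, 0, 10),
    age = round(runif(n, 18, 70)),
    gender = sample(c(-0.5, 0.5), n, replace = TRUE),
    education = sample(1:7, n, replace = TRUE),
    stringsAsFactors = FALSE)
  theta <- covariate_to_angle(covariates[[config$coupling_covariate]],
                              config$gamma_proximity)

  # per-segment stimulus-locked volume ranges: the first transient_s seconds
  # of each segment carry no shared signal (unsettled hemodynamic response),
  # so the latent streams live - and are standardized - on the window the
  # analysis retains after transient exclusion
  tv <- (seq_len(n_vol) - 1) * config$tr_s
  seg_vols <- lapply(seq_len(nrow(events)), function(s) {
    which(tv >= events$onset[s] + config$transient_s &
            tv < events$onset[s] + events$duration[s])
  })
  latent <- lapply(seg_vols, function(v) {
    len <- length(v)
    sA <- smooth_standardize(rnorm(len), config$ma_width)
    b <- smooth_standardize(rnorm(len), config$ma_width)
    b <- b - sA * sum(sA * b) / sum(sA * sA)
    sB <- (b - mean(b)) / sd(b)
    list(sA = sA, sB = sB)
  })

  kappa <- config$kappa_by_frame
  runs <- vector("list", n)
  nuisance <- vector("list", n)
  innov_sd <- config$sigma_noise * sqrt(1 - config$ar1_phi^2)

  for (i in seq_len(n)) {
    # AR(1) noise with marginal sd sigma at every mask voxel
    y <- matrix(0, n_vol, v_mask)
    y[1, ] <- rnorm(v_mask, 0, config$sigma_noise)
    eta <- matrix(rnorm((n_vol - 1) * v_mask, 0, innov_sd), n_vol - 1, v_mask)
    for (t in 2:n_vol) y[t, ] <- config$ar1_phi * y[t - 1, ] + eta[t - 1, ]

    # stimulus-locked shared signal at signal voxels
    ci <- cos(theta[i]); si <- sin(theta[i])
    for (s in seq_len(nrow(events))) {
      amp <- unname(kappa[events$frame[s]])
      if (amp > 0) {
        sig <- amp * (ci * latent[[s]]$sA + si * latent[[s]]$sB)
        y[seg_vols[[s]], signal_rows] <- y[seg_vols[[s]], signal_rows] + sig
      }
    }

    # per-participant quadratic drift, global over mask voxels
    if (config$drift_amplitude > 0) {
      tb <- qr.Q(qr(cbind(tv - mean(tv), (tv - mean(tv))^2)))
      d <- drop(tb %*% rnorm(2))
      d <- d / sd(d) * config$drift_amplitude
      y <- y + d
    }

    # six motion regressors; their leak enters every mask voxel
    m <- vapply(1:6, function(k) cumsum(rnorm(n_vol, 0, 1)), numeric(n_vol))
    m <- scale(m)
    if (config$motion_amplitude > 0) {
      w <- matrix(rnorm(6 * v_mask, 0, 1 / sqrt(6)), 6, v_mask)
      y <- y + config$motion_amplitude * (m %*% w)
    }
    nuis <- as.data.frame(m)
    names(nuis) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")

    arr <- matrix(0, prod(dims), n_vol)
    arr[mask_idx, ] <- t(y)
    dim(arr) <- c(dims, n_vol)
    runs[[i]] <- bold_run(covariates$participant_id[i], arr, config$tr_s,
                          provenance = list(source = "simulate_cohort",
                                            seed = config$seed))
    nuisance[[i]] <- nuis
  }
  names(runs) <- covariates$participant_id
  names(nuisance) <- covariates$participant_id

  truth <- list(signal_voxel_ids = signal_ids,
                theta = setNames(theta, covariates$participant_id),
                latent_streams = latent,
                covariate_table = covariates,
                kappa_by_frame = kappa,
                coupling_covariate = config$coupling_covariate)

  structure(list(runs = runs, events = events, nuisance = nuisance,
                 covariates = covariates, mask = mask, truth = truth,
                 config = config),
            class = "isc_cohort")
}

#' @export
print.isc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ISC cohort: %d participants, %s grid, %d segments\n",
              length(x$runs), paste(dim(x$mask), collapse = "x"),
              nrow(x$events)))
  cat(sprintf("  %d mask voxels, %d signal voxels, %d volumes per run\n",
              sum(x$mask), length(x$truth$signal_voxel_ids),
              dim(x$runs[[1]]$data)[4]))
  invisible(x)
}

#' Simulate a framing survey with known injected effects
#'
#' Emulates a between-subject framing survey: each respondent watches one clip
#' (frame sampled as 25% neutral / 50% threat / 25% blame, topic uniform) and
#' rates twelve emotion items on a 0-20 scale, issue importance, and a sharing
#' count, alongside demographic and political covariates. Frame effects are
#' injected additively on the items of the named composites; the implied true
#' composite-level coefficients (accounting for item overlap between
#' composites) are recorded in `attr(, "truth")`.
#'
#' @param n number of respondents.
#' @param effects named list of named vectors: per composite
#'   (`negative_affect`, `anger`, `fear`, `sharing`, `importance`), additive
#'   effects in scale points for the non-neutral frames.
#' @param seed integer seed.
#' @return data.frame with one row per respondent; `attr(, "truth")` holds the
#'   injected item effects and the implied composite-level coefficients.
#' @export
simulate_survey <- function(n = 1800,
                            effects = list(
                              negative_affect = c(threat = 0.5, blame = 0.7),
                              anger = c(threat = 1.5, blame = 2.5),
                              fear = c(threat = 0.5, blame = 0),
                              sharing = c(threat = -0.3, blame = -0.5),
                              importance = c(threat = 0.2, blame = 0)),
                            seed = 1) {
  set.seed(as.integer(seed))
  mapping <- panas_mapping()
  frames <- c("neutral", "threat", "blame")
  frame <- sample(frames, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  topic <- sample(c("immigration", "climate", "healthcare"), n, replace = TRUE)

  eff <- function(comp, fr) {
    e <- effects[[comp]]
    if (is.null(e)) return(rep(0, length(fr)))
    out <- rep(0, length(fr))
    hit <- fr %in% names(e)
    out[hit] <- unname(e[fr[hit]])
    out
  }

  u <- rnorm(n, 0, 1.5)  # trait negativity
  items <- list()
  for (it in mapping$negative_items) {
    mu <- 8 + u + eff("negative_affect", frame)
    if (it %in% mapping$anger) mu <- mu + eff("anger", frame)
    if (it %in% mapping$fear) mu <- mu + eff("fear", frame)
    items[[it]] <- pmin(pmax(round(mu + rnorm(n, 0, 2.5)), 0), 20)
  }
  for (it in mapping$positive_items) {
    mu <- 10 - 0.4 * u
    items[[it]] <- pmin(pmax(round(mu + rnorm(n, 0, 2.5)), 0), 20)
  }

  neg_mu <- 8 + u + eff("negative_affect", frame)
  importance <- pmin(pmax(round(10 + 0.3 * u + eff("importance", frame) +
                                  rnorm(n, 0, 2.5)), 0), 20)
  sharing <- pmax(round(8 + 0.15 * neg_mu + eff("sharing", frame) +
                          rnorm(n, 0, 2)), 0)

  tab <- data.frame(participant_id = sprintf("resp%04d", seq_len(n)),
                    frame = frame, topic = topic, stringsAsFactors = FALSE)
  for (it in c(mapping$negative_items, mapping$positive_items))
    tab[[it]] <- items[[it]]
  tab$importance <- importance
  tab$sharing <- sharing
  tab$age <- round(runif(n, 18, 80))
  tab$gender <- sample(c(-0.5, 0.5), n, replace = TRUE)
  tab$education <- sample(1:7, n, replace = TRUE)
  tab$ideology <- round(runif(n, 1, 7))
  tab$pvv_attitude <- round(runif(n, 0, 20))
  tab$gl_attitude <- round(runif(n, 0, 20))
  tab$authoritarianism <- runif(n, 0, 10)
  tab$skepticism <- runif(n, 0, 10)
  tab$clip_agreement <- round(runif(n, 0, 20))

  # implied composite-level frame coefficients: each item receives the sum of
  # the effects of the composites it belongs to, so a composite's coefficient
  # is the mean of its items' effects
  comp_eff <- list()
  for (comp in c("negative_affect", "anger", "fear")) {
    its <- mapping[[comp]]
    if (comp == "negative_affect") its <- mapping$negative_items
    per_frame <- sapply(c("threat", "blame"), function(fr) {
      mean(vapply(its, function(it) {
        e <- eff("negative_affect", fr) * (it %in% mapping$negative_items) +
          eff("anger", fr) * (it %in% mapping$anger) +
          eff("fear", fr) * (it %in% mapping$fear)
        e[1]
      }, numeric(1)))
    })
    comp_eff[[comp]] <- per_frame
  }
  comp_eff$sharing <- sapply(c("threat", "blame"), function(fr) eff("sharing", fr)[1])
  comp_eff$importance <- sapply(c("threat", "blame"),
                                function(fr) eff("importance", fr)[1])

  attr(tab, "truth") <- list(item_effects = effects,
                             composite_effects = comp_eff,
                             mapping = mapping)
  tab
}
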