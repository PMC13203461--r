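#' Configuration for the synthetic fixation generator
#'
#' Bundles and validates every generative parameter of the simulator:
#' cohort and design sizes, the event-order procedure, the Markov gaze model
#' on the target face, the fixation-duration model, and the spatial layout.
#' Defaults emulate a facial-expression-recognition session: a cohort of 27
#' observers, 24 face items shown twice each, target faces viewed for about
#' ten fixations under a strongly centre-biased transition structure, and
#' log-normal fixation durations with a 250 ms median.
#'
#' @param n_participants Number of participants.
#' @param n_items Number of face items.
#' @param trials_per_item Presentations of each item per participant; trials
#'   run sequentially, cycling through items.
#' @param procedure Event order within a trial: `"pre_context"` (context
#'   image 500 ms, then target face 3000 ms, then response screen) or
#'   `"post_context"` (target face first, then context, then response screen;
#'   the event preceding a face is then the previous trial's response screen).
#' @param fixations_per_face List `list(mean, min)`: the number of fixations
#'   on each target face is Poisson with this mean, truncated below at `min`.
#' @param order Markov order of the gaze model (1 or 2).
#' @param transition_matrix A [build_fixture_matrix()] object (or any object
#'   with elements `order`, `states`, `prob`) driving target-face zone
#'   sequences; defaults to the order-`order` reference matrix.
#' @param duration_model List `list(meanlog, sdlog)` of the log-normal
#'   fixation-duration distribution in ms.
#' @param spatial_jitter_sd Gaussian jitter (px) of fixation positions about
#'   their zone centre, truncated to the zone rectangle.
#' @param face_layout AOI layout tibble; defaults to
#'   [default_face_layout()] over the `n_items` items.
#' @param anchor_sd Gaussian spread (px) of context-image and response-screen
#'   fixations about their anchor points.
#' @param n_context_fix,n_response_fix Fixations generated on each context
#'   image / response screen.
#' @param screen Screen size in px, `c(width, height)`.
#' @param seed Integer seed; a fixed seed makes [generate_fixations()] output
#'   byte-identical across runs.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_participants = 27,
                         n_items = 24,
                         trials_per_item = 2,
                         procedure = c("pre_context", "post_context"),
                         fixations_per_face = list(mean = 10, min = 3),
                         order = 1L,
                         transition_matrix = NULL,
                         duration_model = list(meanlog = log(250), sdlog = 0.4),
                         spatial_jitter_sd = 60,
                         face_layout = NULL,
                         anchor_sd = 80,
                         n_context_fix = 2,
                         n_response_fix = 3,
                         screen = c(1920, 1080),
                         seed = 1L) {
  procedure <- match.arg(procedure)
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2", call. = FALSE)
  if (is.null(transition_matrix)) transition_matrix <- build_fixture_matrix(order)
  if (is.null(face_layout)) {
    face_layout <- default_face_layout(sprintf("item%02d", seq_len(n_items)),
                                       screen = screen)
  }
  validate_aoi_layout(face_layout)
  if (!setequal(transition_matrix$states, aoi_states())) {
    stop("transition matrix states do not match the layout zones ",
         paste(aoi_states(), collapse = ", "), call. = FALSE)
  }
  stopifnot(
    n_participants >= 1, n_items >= 1, trials_per_item >= 1,
    fixations_per_face$mean > 0, fixations_per_face$min >= 1,
    duration_model$sdlog > 0, spatial_jitter_sd > 0, anchor_sd > 0,
    n_context_fix >= 1, n_response_fix >= 1
  )
  if (fixations_per_face$min < transition_matrix$order + 1) {
    stop("`fixations_per_face$min` must be at least order + 1 so every face ",
         "sequence yields a transition", call. = FALSE)
  }
  out <- list(
    n_participants = as.integer(n_participants),
    n_items = as.integer(n_items),
    trials_per_item = as.integer(trials_per_item),
    procedure = procedure,
    fixations_per_face = fixations_per_face,
    order = as.integer(transition_matrix$order),
    transition_matrix = transition_matrix,
    duration_model = duration_model,
    spatial_jitter_sd = spatial_jitter_sd,
    face_layout = face_layout,
    anchor_sd = anchor_sd,
    n_context_fix = as.integer(n_context_fix),
    n_response_fix = as.integer(n_response_fix),
    screen = screen,
    seed = as.integer(seed)
  )
  class(out) <- "synth_config"
  out
}

#' Read and write simulator configurations
#'
#' Serializes a [synth_config()] (including its transition matrix and AOI
#' layout) to a structured YAML file and back.
#'
#' @param config A `synth_config` object.
#' @param path File path.
#' @return `read_synth_config()` returns a `synth_config`;
#'   `write_synth_config()` invisibly returns `path`.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  obj <- unclass(config)
  tm <- obj$transition_matrix
  obj$transition_matrix <- list(
    order = tm$order, states = tm$states,
    prob = stats::setNames(
      lapply(seq_len(nrow(tm$prob)), function(i) as.numeric(tm$prob[i, ])),
      rownames(tm$prob))
  )
  lay <- obj$face_layout
  obj$face_layout <- lapply(split(lay, seq_len(nrow(lay))), function(r)
    list(item = r$item, zone = r$zone,
         rect = as.numeric(r[c("x_min", "y_min", "x_max", "y_max")])))
  names(obj$face_layout) <- NULL
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  obj <- yaml::read_yaml(path)
  tm <- obj$transition_matrix
  prob <- do.call(rbind, lapply(tm$prob, as.numeric))
  dimnames(prob) <- list(names(tm$prob), unlist(tm$states))
  tmat <- list(order = as.integer(tm$order), states = unlist(tm$states),
               prob = prob)
  lay <- dplyr::bind_rows(lapply(obj$face_layout, function(r)
    tibble::tibble(item = r$item, zone = r$zone,
                   x_min = r$rect[[1]], y_min = r$rect[[2]],
                   x_max = r$rect[[3]], y_max = r$rect[[4]])))
  synth_config(
    n_participants = obj$n_participants, n_items = obj$n_items,
    trials_per_item = obj$trials_per_item, procedure = obj$procedure,
    fixations_per_face = obj$fixations_per_face,
    order = as.integer(tm$order), transition_matrix = tmat,
    duration_model = obj$duration_model,
    spatial_jitter_sd = obj$spatial_jitter_sd, face_layout = lay,
    anchor_sd = obj$anchor_sd, n_context_fix = obj$n_context_fix,
    n_response_fix = obj$n_response_fix,
    screen = unlist(obj$screen), seed = obj$seed
  )
}

#' Sample a zone-label sequence from a Markov gaze model
#'
#' Simulates a fixation-zone sequence from a first- or second-order Markov
#' chain over the three facial zones. Initial states are drawn from the
#' chain's stationary distribution (for order 2, the stationary distribution
#' of the induced chain on state pairs), so sequences start in steady state
#' and pooled estimates are unbiased for the generating rows. Uses the
#' current R random-number stream; seed with `set.seed()` for reproducibility.
#'
#' @param matrix A `fixture_matrix` or any list with elements `order`,
#'   `states`, `prob` (rows = conditioning contexts, columns = destinations).
#' @param length Sequence length; must be at least `order + 1`.
#' @param init Optional starting state(s): a character vector of `order` zone
#'   labels overriding the stationary draw.
#' @return Character vector of zone labels of the requested length.
#' @examples
#' set.seed(1)
#' sample_markov_sequence(build_fixture_matrix(1), 10)
#' @export
sample_markov_sequence <- function(matrix, length, init = NULL) {
  ord <- matrix$order
  states <- matrix$states
  P <- matrix$prob
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  if (length < ord + 1) {
    stop(sprintf("`length` must be at least order + 1 = %d", ord + 1),
         call. = FALSE)
  }
  n <- as.integer(length)
  s <- integer(n)
  if (ord == 1L) {
    if (is.null(init)) {
      pi0 <- stationary_distribution(P)
      s[1] <- sample.int(3L, 1L, prob = pi0)
    } else {
      s[1] <- match(init[1], states)
    }
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(n)
    for (t in 2:n) {
      r <- s[t - 1L]
      s[t] <- 1L + (u[t] > cum[r, 1L]) + (u[t] > cum[r, 2L])
    }
  } else {
    # induced chain on pairs gives the steady-state starting pair
    if (is.null(init)) {
      Tpair <- pair_chain_matrix(P, states)
      pi0 <- stationary_distribution(Tpair)
      pair <- sample.int(9L, 1L, prob = pi0)
      s[1] <- (pair - 1L) %/% 3L + 1L
      s[2] <- (pair - 1L) %% 3L + 1L
    } else {
      s[1] <- match(init[1], states)
      s[2] <- match(init[2], states)
    }
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(n)
    for (t in 3:n) {
      r <- (s[t - 2L] - 1L) * 3L + s[t - 1L]
      s[t] <- 1L + (u[t] > cum[r, 1L]) + (u[t] > cum[r, 2L])
    }
  }
  states[s]
}

# Transition matrix of the induced chain on ordered state pairs.
pair_chain_matrix <- function(P, states) {
  ctx <- context_labels(2L, states)
  Tpair <- matrix(0, 9, 9, dimnames = list(ctx, ctx))
  for (r in seq_len(9)) {
    recent <- (r - 1L) %% 3L + 1L
    for (k in seq_len(3)) {
      Tpair[r, (recent - 1L) * 3L + k] <- P[r, k]
    }
  }
  Tpair
}

# Exact truncated-normal draws via inverse-CDF; vectorized over all args.
rtruncnorm_vec <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lo), hi - 1e-9)
}

#' Generate a synthetic fixation table
#'
#' Simulates a full session of fixation records for every participant, item
#' and trial in a [synth_config()]. Target-face fixation sequences realize
#' the configured Markov chain over the three facial zones, with positions
#' jittered about zone centres (truncated to the zone rectangle, so each
#' fixation maps back to its generating zone). Context-image fixations are
#' scattered about the screen centre and response-screen fixations about one
#' of four response-icon positions, providing the preceding-event anchors
#' used by [anchor_transitions()]. Durations are log-normal.
#'
#' @param config A `synth_config` object.
#' @return A tibble of fixation records with columns `participant`, `item`,
#'   `trial`, `condition`, `event_type` (context / target / response),
#'   `t_onset_ms`, `duration_ms`, `x_px`, `y_px`, `valid`, and `zone` (the
#'   generating facial zone, `NA` for non-target events). Ordered by
#'   participant, trial and onset.
#' @examples
#' cfg <- synth_config(n_participants = 2, n_items = 2, trials_per_item = 1)
#' fx <- generate_fixations(cfg)
#' head(fx)
#' @export
generate_fixations <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n_trials <- config$n_items * config$trials_per_item
  items <- sprintf("item%02d", rep_len(seq_len(config$n_items), n_trials))
  participants <- sprintf("P%02d", seq_len(config$n_participants))
  lay <- config$face_layout
  emoji_x <- config$screen[1] * c(0.2, 0.4, 0.6, 0.8)
  emoji_y <- config$screen[2] * 0.5

  tm <- config$transition_matrix
  states <- aoi_states()
  N <- config$n_participants * n_trials  # target presentations overall

  # per-presentation design, participant-major then trial order
  pid_tr <- rep(participants, each = n_trials)
  trial_tr <- rep(seq_len(n_trials), times = config$n_participants)
  item_tr <- rep(items, times = config$n_participants)

  # zone-label sequences for every presentation in one pass
  n_t <- pmax(config$fixations_per_face$min,
              stats::rpois(N, config$fixations_per_face$mean))
  zi <- sim_label_runs(tm, n_t)

  # target fixation positions: zone centre + truncated Gaussian jitter
  lay_key <- paste(lay$item, lay$zone, sep = "\r")
  tfix_trial <- rep(seq_len(N), times = n_t)
  li <- match(paste(item_tr[tfix_trial], states[zi], sep = "\r"), lay_key)
  total_t <- sum(n_t)
  tx <- rtruncnorm_vec(total_t, (lay$x_min[li] + lay$x_max[li]) / 2,
                       config$spatial_jitter_sd, lay$x_min[li], lay$x_max[li])
  ty <- rtruncnorm_vec(total_t, (lay$y_min[li] + lay$y_max[li]) / 2,
                       config$spatial_jitter_sd, lay$y_min[li], lay$y_max[li])

  n_c <- config$n_context_fix
  cfix_trial <- rep(seq_len(N), each = n_c)
  cx <- stats::rnorm(N * n_c, config$screen[1] / 2, config$anchor_sd)
  cy <- stats::rnorm(N * n_c, config$screen[2] / 2, config$anchor_sd)

  n_r <- config$n_response_fix
  icon <- sample(emoji_x, N, replace = TRUE)
  rfix_trial <- rep(seq_len(N), each = n_r)
  rx <- stats::rnorm(N * n_r, icon[rfix_trial], config$anchor_sd)
  ry <- stats::rnorm(N * n_r, emoji_y, config$anchor_sd)

  block <- function(trial_idx, event, x, y, zone, ev_rank, fix_idx) {
    list(trial_idx = trial_idx, event_type = rep(event, length(x)),
         x_px = x, y_px = y, zone = zone,
         ev_rank = rep(ev_rank, length(x)), fix_idx = fix_idx)
  }
  ranks <- if (config$procedure == "pre_context") c(context = 1L, target = 2L,
                                                    response = 3L)
           else c(target = 1L, context = 2L, response = 3L)
  parts <- list(
    block(cfix_trial, "context", cx, cy, rep(NA_character_, N * n_c),
          ranks[["context"]], rep(seq_len(n_c), N)),
    block(tfix_trial, "target", tx, ty, states[zi],
          ranks[["target"]], sequence(n_t)),
    block(rfix_trial, "response", rx, ry, rep(NA_character_, N * n_r),
          ranks[["response"]], rep(seq_len(n_r), N))
  )
  col <- function(nm) unlist(lapply(parts, `[[`, nm), use.names = FALSE)
  tbl <- tibble::tibble(
    trial_idx = col("trial_idx"), event_type = col("event_type"),
    x_px = col("x_px"), y_px = col("y_px"), zone = col("zone"),
    ev_rank = col("ev_rank"), fix_idx = col("fix_idx"))
  tbl <- tbl[order(tbl$trial_idx, tbl$ev_rank, tbl$fix_idx), ]

  tbl$participant <- pid_tr[tbl$trial_idx]
  tbl$item <- item_tr[tbl$trial_idx]
  tbl$trial <- trial_tr[tbl$trial_idx]
  tbl$duration_ms <- stats::rlnorm(nrow(tbl), config$duration_model$meanlog,
                                   config$duration_model$sdlog)
  # strictly increasing onsets per participant preserve event/fixation order
  tbl$t_onset_ms <- stats::ave(tbl$duration_ms + 1, tbl$participant,
                               FUN = cumsum)
  tbl$condition <- config$procedure
  tbl$valid <- TRUE
  tbl[, c("participant", "item", "trial", "condition", "event_type",
          "t_onset_ms", "duration_ms", "x_px", "y_px", "valid", "zone")]
}

# Simulate all presentations' zone sequences in a single integer loop:
# each run restarts from the chain's steady state. Returns state indices.
sim_label_runs <- function(tm, run_lengths) {
  P <- tm$prob
  ord <- tm$order
  if (any(run_lengths < ord + 1)) {
    stop("every run must be at least order + 1 fixations long", call. = FALSE)
  }
  total <- sum(run_lengths)
  starts <- cumsum(c(1L, run_lengths[-length(run_lengths)]))
  is_start <- logical(total)
  is_start[starts] <- TRUE
  cumP <- t(apply(P, 1, cumsum))
  u <- stats::runif(total)
  s <- integer(total)
  if (ord == 1L) {
    cpi <- cumsum(stationary_distribution(P))
    for (t in seq_len(total)) {
      if (is_start[t]) {
        s[t] <- 1L + (u[t] > cpi[1L]) + (u[t] > cpi[2L])
      } else {
        r <- s[t - 1L]
        s[t] <- 1L + (u[t] > cumP[r, 1L]) + (u[t] > cumP[r, 2L])
      }
    }
  } else {
    states <- tm$states
    pi_pair <- stationary_distribution(pair_chain_matrix(P, states))
    pair_draws <- cumsum(pi_pair)
    second <- logical(total)
    second[pmin(starts + 1L, total)] <- TRUE
    for (t in seq_len(total)) {
      if (is_start[t]) {
        pair <- 1L
        while (u[t] > pair_draws[pair] && pair < 9L) pair <- pair + 1L
        s[t] <- (pair - 1L) %/% 3L + 1L
        s[t + 1L] <- (pair - 1L) %% 3L + 1L
      } else if (second[t]) {
        # already set together with the first state of the run
      } else {
        r <- (s[t - 2L] - 1L) * 3L + s[t - 1L]
        s[t] <- 1L + (u[t] > cumP[r, 1L]) + (u[t] > cumP[r, 2L])
      }
    }
  }
  s
}

#' Write a fixation table to a tab-separated file
#'
#' Writes the canonical UTF-8 TSV export consumed by [read_fixations()].
#' The generating-zone column of synthetic tables is an internal ground-truth
#' annotation and is not written.
#'
#' @param fixations A fixation tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fixations <- function(fixations, path) {
  cols <- intersect(c("participant", "item", "trial", "condition", "event_type",
                      "t_onset_ms", "duration_ms", "x_px", "y_px", "valid"),
                    names(fixations))
  readr::write_tsv(fixations[, cols], path)
  invisible(path)
}
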