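#' Mixed-effects models of gaze stability
#'
#' Fits random-intercept linear mixed models to a stability table:
#' * `aoi_only` - `stability ~ zone + (1 | participant)` on participant x
#'   zone aggregates (re-aggregated from finer grains as total duration over
#'   total path length when needed);
#' * `aoi_by_event` - `stability ~ zone * condition + (1 | participant)` on
#'   the rows as given (typically trial-level), requiring a `condition`
#'   column with two levels.
#'
#' Estimation is delegated to [lmerTest::lmer()] (REML). Fixed-effect
#' contrasts are reported against the lower facial zone as reference.
#' Per-term F tests use the Wald F from the fitted model with
#' containment/residual denominator degrees of freedom,
#' `n_obs - rank(fixed-effects design)` — e.g. 78 for 27 participants x 3
#' zones — with the method recorded in the result. Singular fits are
#' flagged, not silently accepted.
#'
#' @param table A stability tibble from [stability_table()] with columns
#'   `participant`, `zone`, `stability` (and `total_duration`,
#'   `path_length` for re-aggregation; `condition` for `aoi_by_event`).
#' @param variant `"aoi_only"` or `"aoi_by_event"`.
#' @return An object of class `stability_lmm`: list with the fitted
#'   `model`, `variant`, `anova` (tibble: term, F, df_num, df_den, p),
#'   `contrasts` (tibble: term, estimate, se, t, p), `reference`, `n_obs`,
#'   `n_participants`, `singular`, `ddf_method`.
#' @export
fit_stability_lmm <- function(table, variant = c("aoi_only", "aoi_by_event")) {
  variant <- match.arg(variant)
  tab <- table
  if (variant == "aoi_only") {
    if (anyDuplicated(tab[c("participant", "zone")])) {
      if (!all(c("total_duration", "path_length") %in% names(tab))) {
        stop("cannot aggregate to participant x zone without total_duration ",
             "and path_length columns", call. = FALSE)
      }
      tab <- dplyr::summarise(
        dplyr::group_by(tab, .data$participant, .data$zone),
        total_duration = sum(.data$total_duration),
        path_length = sum(.data$path_length), .groups = "drop")
      tab$stability <- tab$total_duration / tab$path_length
    }
    form <- stability ~ zone + (1 | participant)
  } else {
    if (!"condition" %in% names(tab)) {
      stop("`aoi_by_event` requires a `condition` column", call. = FALSE)
    }
    tab$condition <- factor(tab$condition)
    if (nlevels(tab$condition) < 2) {
      stop("`aoi_by_event` requires at least 2 condition levels", call. = FALSE)
    }
    form <- stability ~ zone * condition + (1 | participant)
  }
  tab$zone <- stats::relevel(factor(tab$zone, levels = aoi_states()),
                             ref = "LFZ")
  if (nlevels(droplevels(tab$zone)) < 2) {
    stop("need at least 2 zones with data", call. = FALSE)
  }

  model <- lmerTest::lmer(form, data = tab, REML = TRUE)
  singular <- lme4::isSingular(model)
  if (singular) message("fit_stability_lmm: singular fit (a variance component is zero)")

  X <- lme4::getME(model, "X")
  n_obs <- nrow(X)
  ddf <- n_obs - qr(X)$rank
  a <- suppressMessages(stats::anova(model))  # Wald F per term
  anova_tbl <- tibble::tibble(
    term = rownames(a),
    F = a[["F value"]],
    df_num = a[["NumDF"]],
    df_den = ddf,
    p = stats::pf(a[["F value"]], a[["NumDF"]], ddf, lower.tail = FALSE)
  )
  cf <- summary(model)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  contrasts <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    t = cf[, "t value"],
    p = stats::pt(abs(cf[, "t value"]), ddf, lower.tail = FALSE) * 2
  )
  out <- list(model = model, variant = variant, formula = form,
              anova = anova_tbl, contrasts = contrasts,
              reference = "LFZ", n_obs = n_obs,
              n_participants = length(unique(tab$participant)),
              singular = singular, ddf_method = "containment/residual")
  class(out) <- "stability_lmm"
  out
}

#' @export
print.stability_lmm <- function(x, ...) {
  cat(sprintf("Stability mixed model (%s): %d obs, %d participants%s\n",
              x$variant, x$n_obs, x$n_participants,
              if (x$singular) " [singular fit]" else ""))
  cat("ANOVA (", x$ddf_method, " ddf):\n", sep = "")
  print(as.data.frame(x$anova), digits = 4)
  cat("Contrasts (reference ", x$reference, "):\n", sep = "")
  print(as.data.frame(x$contrasts), digits = 4)
  invisible(x)
}
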