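#' Sentence-level train/evaluation split
#'
#' Holds out `round(eval_fraction * n)` whole sentences; every repetition of
#' a sentence falls on one side only, so no sentence content leaks between
#' training and evaluation.
#'
#' @param sentence_ids Vector of unique sentence ids.
#' @param eval_fraction Fraction of sentences held out.
#' @param seed Integer seed.
#' @return A list of class `split_spec` with `train_sentence_ids`,
#'   `eval_sentence_ids` and `seed`.
#' @export
sentence_level_split <- function(sentence_ids, eval_fraction = 0.2, seed = 1L) {
  sentence_ids <- sort(unique(sentence_ids))
  n <- length(sentence_ids)
  if (n < 5) stop("need at least 5 sentences to split", call. = FALSE)
  if (eval_fraction <= 0 || eval_fraction >= 1)
    stop("eval_fraction must be in (0, 1)", call. = FALSE)
  n_eval <- round(eval_fraction * n)
  if (n_eval < 1 || n_eval >= n)
    stop("eval_fraction leaves an empty split", call. = FALSE)
  with_seed(seed, {
    eval_ids <- sort(sentence_ids[sample.int(n, n_eval)])
    structure(list(train_sentence_ids = setdiff(sentence_ids, eval_ids),
                   eval_sentence_ids = eval_ids,
                   seed = as.integer(seed)),
              class = "split_spec")
  })
}

#' Guard against sentence leakage between splits
#'
#' Errors unless the train and evaluation sentence sets are disjoint and the
#' segments' sentences are fully covered. Run as part of every experiment,
#' not only in tests.
#'
#' @param split A `split_spec`.
#' @param info Optional segment info tibble with a `sentence_id` column to
#'   check coverage against.
#' @return Invisibly `TRUE`.
#' @export
assert_no_leakage <- function(split, info = NULL) {
  both <- intersect(split$train_sentence_ids, split$eval_sentence_ids)
  if (length(both) > 0)
    stop("sentence leakage: ids in both splits: ",
         paste(both, collapse = ", "), call. = FALSE)
  if (!is.null(info)) {
    missing <- setdiff(unique(info$sentence_id),
                       c(split$train_sentence_ids, split$eval_sentence_ids))
    if (length(missing) > 0)
      stop("sentences missing from the split: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Discretized decoding accuracy
#'
#' Fraction of correctly classified fixed-length segments.
#'
#' @param model A trained `speech_cnn`.
#' @param eval_segments A (balanced) `segment_set`.
#' @return A one-row tibble: `mode`, `accuracy`, `n_segments`.
#' @export
discretized_accuracy <- function(model, eval_segments) {
  if (dim(eval_segments$x)[3] == 0) stop("empty evaluation set", call. = FALSE)
  pred <- predict(model, eval_segments)
  tibble::tibble(mode = "discretized",
                 accuracy = mean(pred$pred_label == eval_segments$info$label),
                 n_segments = nrow(pred))
}

#' Causal continuous decoding over a recording
#'
#' Simulates streaming decoding: a window of `window` seconds advances in
#' steps of `step` seconds across each trial; window start times live on the
#' step grid in seconds and are mapped to the nearest sample of the
#' (decimated) signal. Each window is classified independently and compared
#' with the ground-truth state at its final time point, so no future sample
#' is read. Accuracy is aggregated per sentence trial, never pooled over
#' windows.
#'
#' @param model A trained `speech_cnn`.
#' @param rec A causally preprocessed, z-scored, downsampled
#'   `seeg_recording` restricted to the model's channels, with its `state`
#'   ground truth.
#' @param schedule The `trial_schedule`.
#' @param trial_ids Optional subset of trials to decode (e.g. held-out
#'   sentences only).
#' @param window Window length (s).
#' @param step Step size (s).
#' @return A tibble with one row per decoded trial: `trial_id`,
#'   `sentence_id`, `repetition`, `n_windows`, `accuracy`.
#' @export
continuous_decode <- function(model, rec, schedule, trial_ids = NULL,
                              window = 0.100, step = 0.005) {
  fs <- rec$sampling_rate
  T_len <- round(window * fs)
  if (T_len != model$T)
    stop("window length does not match the model's segment length",
         call. = FALSE)
  bd <- trial_boundaries(schedule)
  bd <- bd[is.finite(bd$speech_onset), ]
  if (!is.null(trial_ids)) bd <- bd[bd$trial_id %in% trial_ids, ]
  if (is.null(rec$state)) stop("recording carries no ground-truth state",
                               call. = FALSE)
  n_total <- n_samples(rec)

  rows <- vector("list", nrow(bd))
  for (i in seq_len(nrow(bd))) {
    t0 <- bd$trial_onset[i]
    t1 <- min(bd$trial_offset[i], (n_total - 1) / fs)
    # window starts on the step grid, mapped to the nearest sample
    starts_s <- seq(t0, t1 - window, by = step)
    if (length(starts_s) < 1) {
      warning(sprintf("trial %d shorter than one window; skipped",
                      bd$trial_id[i]), call. = FALSE)
      next
    }
    i0 <- round(starts_s * fs) + 1L            # nearest-sample window start
    i0 <- i0[i0 + T_len - 1L <= n_total]
    nw <- length(i0)
    x <- array(0, dim = c(model$C, T_len, nw))
    for (w in seq_len(nw))
      x[, , w] <- rec$signal[, i0[w]:(i0[w] + T_len - 1L), drop = FALSE]
    truth <- rec$state[i0 + T_len - 1L]        # state at the final time point
    pred <- predict(model, x)
    rows[[i]] <- tibble::tibble(
      trial_id = bd$trial_id[i],
      sentence_id = bd$sentence_id[i],
      repetition = bd$repetition[i],
      n_windows = nw,
      accuracy = mean(pred$pred_label == truth))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no trial long enough to decode", call. = FALSE)
  out
}

#' Statistical comparison of evaluation conditions
#'
#' Wraps the standard tests used to compare decoding conditions:
#' * `one_way`: one-way ANOVA across groups plus Tukey HSD pairwise
#'   comparisons.
#' * `two_way`: two-way fixed-effects ANOVA with interaction plus
#'   Bonferroni-corrected simple effects of `factor1` within each level of
#'   `factor2`.
#' * `vs_chance`: one-sample t-test of `value` against `mu` (two-sided).
#' * `paired_two_group` / `two_group`: independent-samples Welch t-tests of
#'   `value` between the two levels of `group`, Bonferroni-corrected across
#'   strata of `factor2` when present.
#'
#' Zero-variance degenerate inputs yield `p = 1` by convention instead of an
#' error.
#'
#' @param data A data frame with a numeric `value` column and grouping
#'   columns `group` (and `factor2` for two-way/stratified designs).
#' @param design One of `"one_way"`, `"two_way"`, `"vs_chance"`,
#'   `"two_group"`.
#' @param mu Chance level for `vs_chance`.
#' @return A list of class `condition_comparison` with tibbles `omnibus`
#'   and (where applicable) `pairwise`.
#' @export
compare_conditions <- function(data,
                               design = c("one_way", "two_way", "vs_chance",
                                          "two_group"),
                               mu = 0.5) {
  design <- match.arg(design)
  out <- switch(design,
    one_way = {
      data$group <- factor(data$group)
      if (any(table(data$group) < 2))
        stop("need >= 2 observations per group", call. = FALSE)
      if (stats::sd(data$value) == 0) {
        omnibus <- tibble::tibble(term = "group", statistic = NA_real_,
                                  df1 = nlevels(data$group) - 1L,
                                  df2 = nrow(data) - nlevels(data$group),
                                  p_value = 1)
        pairwise <- NULL
      } else {
        fit <- stats::aov(value ~ group, data = data)
        tab <- summary(fit)[[1]]
        omnibus <- tibble::tibble(term = "group",
                                  statistic = tab$`F value`[1],
                                  df1 = tab$Df[1], df2 = tab$Df[2],
                                  p_value = tab$`Pr(>F)`[1])
        tk <- stats::TukeyHSD(fit)$group
        pairwise <- tibble::tibble(contrast = rownames(tk),
                                   estimate = tk[, "diff"],
                                   p_value = tk[, "p adj"])
      }
      list(omnibus = omnibus, pairwise = pairwise)
    },
    two_way = {
      data$group <- factor(data$group)
      data$factor2 <- factor(data$factor2)
      cells <- table(data$group, data$factor2)
      if (nlevels(data$group) < 2 || nlevels(data$factor2) < 2 ||
          any(cells < 2))
        stop("two-way design needs >= 2 levels per factor and >= 2 ",
             "observations per cell", call. = FALSE)
      fit <- stats::aov(value ~ group * factor2, data = data)
      tab <- summary(fit)[[1]]
      omnibus <- tibble::tibble(term = trimws(rownames(tab)[-nrow(tab)]),
                                statistic = tab$`F value`[-nrow(tab)],
                                df1 = tab$Df[-nrow(tab)],
                                df2 = tab$Df[nrow(tab)],
                                p_value = tab$`Pr(>F)`[-nrow(tab)])
      # Bonferroni-corrected simple effects of group within factor2 levels
      lv <- levels(data$factor2)
      pw <- purrr::map_dfr(lv, function(l) {
        d <- data[data$factor2 == l, ]
        g <- split(d$value, droplevels(d$group))
        if (length(g) != 2 || (stats::sd(d$value) == 0))
          return(tibble::tibble(stratum = l, estimate = NA_real_, p_value = 1))
        ht <- stats::t.test(g[[1]], g[[2]])
        tibble::tibble(stratum = l,
                       estimate = unname(diff(rev(ht$estimate))),
                       p_value = ht$p.value)
      })
      pw$p_value <- pmin(1, pw$p_value * length(lv))
      list(omnibus = omnibus, pairwise = pw)
    },
    vs_chance = {
      v <- data$value
      if (stats::sd(v) == 0) {
        omnibus <- tibble::tibble(term = "vs_chance",
                                  statistic = NA_real_,
                                  df1 = length(v) - 1L, df2 = NA_integer_,
                                  p_value = if (isTRUE(all.equal(mean(v), mu))) 1 else 0)
      } else {
        ht <- stats::t.test(v, mu = mu)
        omnibus <- tibble::tibble(term = "vs_chance",
                                  statistic = unname(ht$statistic),
                                  df1 = unname(ht$parameter),
                                  df2 = NA_integer_,
                                  p_value = ht$p.value)
      }
      list(omnibus = omnibus, pairwise = NULL)
    },
    two_group = {
      data$group <- factor(data$group)
      if (nlevels(data$group) != 2) stop("two_group needs 2 levels", call. = FALSE)
      strata <- if ("factor2" %in% names(data)) factor(data$factor2)
                else factor(rep("all", nrow(data)))
      lv <- levels(strata)
      pw <- purrr::map_dfr(lv, function(l) {
        d <- data[strata == l, ]
        g <- split(d$value, d$group)
        if (stats::sd(d$value) == 0)
          return(tibble::tibble(stratum = l, estimate = NA_real_, p_value = 1))
        ht <- stats::t.test(g[[1]], g[[2]])
        tibble::tibble(stratum = l,
                       estimate = unname(diff(rev(ht$estimate))),
                       p_value = ht$p.value)
      })
      pw$p_value <- pmin(1, pw$p_value * length(lv))
      list(omnibus = NULL, pairwise = pw)
    })
  structure(c(out, list(design = design)), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> design:", x$design, "\n")
  if (!is.null(x$omnibus)) { cat("omnibus:\n"); print(x$omnibus) }
  if (!is.null(x$pairwise)) { cat("pairwise:\n"); print(x$pairwise) }
  invisible(x)
}

#' @export
tidy.condition_comparison <- function(x, ...) {
  if (!is.null(x$omnibus)) x$omnibus else x$pairwise
}
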