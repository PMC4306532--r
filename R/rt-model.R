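# Reaction-time regressor variants and the variance-accounting ledger.
#
# The cascade mirrors the order of the behavioral analysis: linear ITI
# effect, renormalization of the nine current x previous condition cells,
# blockwise linear detrending. Every step preserves the grand mean
# (renormalization, not residualization to zero), so the variants stay on the
# RT scale; Pearson correlations downstream are location-invariant anyway.

#' Remove the linear inter-trial-interval effect
#'
#' Subtracts the least-squares linear effect of ITI; the grand mean is
#' preserved. A constant ITI returns the input unchanged with a warning and
#' the attribute `flag = "constant-covariate"`.
#'
#' @param rt per-trial reaction times, ms.
#' @param iti per-trial inter-trial intervals, s.
#' @return corrected RT vector; attributes `slope` and `df` (model degrees of
#'   freedom used, for ledger bias adjustment).
#' @export
correct_iti <- function(rt, iti) {
  if (length(rt) < 3) stop("need at least 3 trials")
  if (length(iti) != length(rt)) stop("rt/iti misalignment")
  if (stats::var(iti) == 0) {
    warning("constant ITI; returning input unchanged")
    return(structure(rt, slope = 0, df = 0L, flag = "constant-covariate"))
  }
  b <- stats::cov(rt, iti) / stats::var(iti)
  out <- rt - b * (iti - mean(iti))
  structure(out, slope = b, df = 1L)
}

#' Residualize RT for mean V1 band amplitude
#'
#' Same contract as [correct_iti()] with the trial-mean V1 oscillatory
#' amplitude as covariate: removes the linear trend of the RT's association
#' with V1 power, preserving the grand mean. After correction the output is
#' exactly orthogonal to the covariate.
#'
#' @param rt per-trial reaction times, ms.
#' @param v1_amp per-trial mean V1 band amplitude (see
#'   [v1_amplitude_regressor()]).
#' @return corrected RT vector (attributes as [correct_iti()]).
#' @export
correct_v1_power <- function(rt, v1_amp) {
  correct_iti(rt, v1_amp)
}

#' Renormalize RT across current x previous condition cells
#'
#' Subtracts each (current, previous) cell's mean and adds back the grand
#' mean, so all filled cells have exactly the grand-mean RT. Trials whose
#' previous condition is the dedicated `"start"` level form their own cells
#' keyed by current condition. Cells with fewer than `min_cell` trials fall
#' back to the current-condition marginal mean (flagged).
#'
#' @param rt per-trial reaction times, ms.
#' @param current,previous per-trial condition labels.
#' @param min_cell minimum trials per cell (default 5).
#' @return corrected RT vector; attributes `df` (number of distinct means
#'   minus 1) and `fallback_cells` (labels of under-filled cells, if any).
#' @export
renormalize_conditions <- function(rt, current, previous, min_cell = 5) {
  n <- length(rt)
  stopifnot(length(current) == n, length(previous) == n)
  grand <- mean(rt)
  cell <- paste(current, previous, sep = ":")
  counts <- table(cell)
  small <- names(counts)[counts < min_cell]
  use_marginal <- cell %in% small
  cell_means <- tapply(rt, cell, mean)
  marg_means <- tapply(rt, current, mean)
  sub <- ifelse(use_marginal, marg_means[as.character(current)],
                cell_means[cell])
  out <- rt - as.numeric(sub) + grand
  out <- out - mean(out) + grand   # exact under fallback too
  # only fully fitted cell means overfit; marginal fallbacks are estimated
  # from the whole condition margin and contribute ~nothing
  df <- sum(counts >= min_cell)
  structure(out, df = max(0L, as.integer(df) - 1L),
            fallback_cells = if (length(small)) small else NULL)
}

#' Remove blockwise linear trends and block offsets
#'
#' Within each block, subtracts that block's least-squares line over the
#' within-block trial index (offset and slope), then adds back the grand
#' mean: output blockwise trend slopes are exactly zero and every block mean
#' equals the grand mean. Blocks with fewer than 3 trials are skipped
#' (flagged).
#'
#' @param rt per-trial reaction times, ms.
#' @param block per-trial block index.
#' @param time_in_block per-trial within-block trial index.
#' @return corrected RT vector; attributes `slopes` (per block), `df`, and
#'   `skipped_blocks` if any.
#' @export
detrend_blocks <- function(rt, block, time_in_block) {
  n <- length(rt)
  stopifnot(length(block) == n, length(time_in_block) == n)
  grand <- mean(rt)
  out <- rt
  blocks <- sort(unique(block))
  slopes <- stats::setNames(rep(NA_real_, length(blocks)), blocks)
  skipped <- character(0)
  df <- 0L
  for (b in blocks) {
    i <- which(block == b)
    if (length(i) < 3) {
      skipped <- c(skipped, as.character(b))
      next
    }
    t_c <- time_in_block[i] - mean(time_in_block[i])
    sl <- sum(t_c * rt[i]) / sum(t_c^2)
    out[i] <- rt[i] - mean(rt[i]) - sl * t_c + grand
    slopes[as.character(b)] <- sl
    df <- df + 2L
  }
  if (df > 0) df <- df - 1L   # grand mean is retained
  structure(out, slopes = slopes, df = df,
            skipped_blocks = if (length(skipped)) skipped else NULL)
}

#' Convert a Pearson correlation to percent variance explained
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return `100 * r^2`.
#' @export
variance_explained <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1")
  100 * r^2
}

#' Build the regressor variants and the variance ledger
#'
#' Applies the correction cascade in sequence (ITI, then current x previous
#' condition, then blockwise trends) and, if a V1 amplitude regressor is
#' supplied, the V1-power residualization of the raw RT. The ledger reports
#' each step's share of the raw RT variance in two forms: the raw sequential
#' variance reductions `fraction_*` (which telescope exactly:
#' `fraction_iti + fraction_condition + fraction_block_trends +
#' fraction_residual = 1`), and bias-adjusted shares `fraction_*_adj` that
#' subtract the expected least-squares overfit (`df` model terms times the
#' residual mean square) from each removed sum of squares — the appropriate
#' quantity when comparing recovered shares with the generating values.
#'
#' @param table a `trial_table` with `rt` (included trials only).
#' @param v1_amp optional per-trial mean V1 band amplitude.
#' @param min_cell passed to [renormalize_conditions()].
#' @return object of class `regressor_set`: `raw_rt`, `rt_corrected`,
#'   `rt_detrended`, `rt_v1corrected` (or `NULL`), and `ledger` (class
#'   `variance_ledger`).
#' @export
build_regressors <- function(table, v1_amp = NULL, min_cell = 5) {
  rt <- table$rt
  n <- length(rt)
  ss_raw <- sum((rt - mean(rt))^2)

  r1 <- correct_iti(rt, table$iti)
  r2 <- renormalize_conditions(r1, table$condition, table$prev_condition,
                               min_cell = min_cell)
  r3 <- detrend_blocks(r2, table$block, table$time_in_block)

  ss <- c(raw = ss_raw,
          iti = sum((r1 - mean(r1))^2),
          cond = sum((r2 - mean(r2))^2),
          block = sum((r3 - mean(r3))^2))
  dfs <- c(iti = attr(r1, "df"), cond = attr(r2, "df"),
           block = attr(r3, "df"))
  removed <- c(iti = ss[["raw"]] - ss[["iti"]],
               cond = ss[["iti"]] - ss[["cond"]],
               block = ss[["cond"]] - ss[["block"]])
  after <- c(iti = ss[["iti"]], cond = ss[["cond"]], block = ss[["block"]])
  df_cum <- cumsum(dfs)
  # expected overfit of each step: df * residual mean square after the step
  mse <- after / pmax(1, n - 1 - df_cum)
  adj <- pmax(0, removed - dfs * mse) / ss_raw
  names(adj) <- names(removed)

  v1c <- NULL
  frac_v1 <- NA_real_
  frac_v1_adj <- NA_real_
  if (!is.null(v1_amp)) {
    v1c <- as.numeric(correct_v1_power(rt, v1_amp))
    ss_v1 <- sum((v1c - mean(v1c))^2)
    frac_v1 <- (ss_raw - ss_v1) / ss_raw
    frac_v1_adj <- max(0, (ss_raw - ss_v1) - ss_v1 / (n - 3)) / ss_raw
  }

  ledger <- structure(list(
    fraction_iti = removed[["iti"]] / ss_raw,
    fraction_condition = removed[["cond"]] / ss_raw,
    fraction_block_trends = removed[["block"]] / ss_raw,
    fraction_v1 = frac_v1,
    fraction_residual = ss[["block"]] / ss_raw,
    fraction_iti_adj = adj[["iti"]],
    fraction_condition_adj = adj[["cond"]],
    fraction_block_trends_adj = adj[["block"]],
    fraction_v1_adj = frac_v1_adj,
    n_trials = n), class = "variance_ledger")

  structure(list(raw_rt = rt, rt_corrected = as.numeric(r2),
                 rt_detrended = as.numeric(r3), rt_v1corrected = v1c,
                 ledger = ledger),
            class = "regressor_set")
}

#' @export
print.variance_ledger <- function(x, ...) {
  cat("variance_ledger (n =", x$n_trials, "):\n")
  cat(sprintf("  ITI          %6.2f%%  (adj %6.2f%%)\n",
              100 * x$fraction_iti, 100 * x$fraction_iti_adj))
  cat(sprintf("  condition    %6.2f%%  (adj %6.2f%%)\n",
              100 * x$fraction_condition, 100 * x$fraction_condition_adj))
  cat(sprintf("  block trends %6.2f%%  (adj %6.2f%%)\n",
              100 * x$fraction_block_trends, 100 * x$fraction_block_trends_adj))
  if (!is.na(x$fraction_v1)) {
    cat(sprintf("  V1 power     %6.2f%%  (adj %6.2f%%)\n",
                100 * x$fraction_v1, 100 * x$fraction_v1_adj))
  }
  cat(sprintf("  residual     %6.2f%%\n", 100 * x$fraction_residual))
  invisible(x)
}
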