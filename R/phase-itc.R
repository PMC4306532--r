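# Quintile-sorted inter-trial coherence (ITC) analysis of phase-RT
# dependence, with a shuffle-based null: if the phase of ongoing oscillations
# influences RT, trials within an RT quintile have more similar phases than
# trials shuffled into quintiles at random.

#' Split trials into RT quintiles
#'
#' Stable sort by RT (ties keep trial order), contiguous fifths; with a
#' remainder `r < 5` the first `r` quintiles get one extra trial.
#'
#' @param rt per-trial reaction times.
#' @return integer vector of quintile labels 1..5, in trial order.
#' @export
split_quintiles <- function(rt) {
  n <- length(rt)
  if (n < 5) stop("need at least 5 trials")
  sizes <- n %/% 5 + (seq_len(5) <= n %% 5)
  lab <- rep(seq_len(5), times = sizes)
  out <- integer(n)
  out[order(rt)] <- lab   # order() is stable: ties by trial index
  out
}

#' Inter-trial coherence of a trial group
#'
#' Modulus of the mean unit phasor across the group's trials, per
#' (frequency, time) cell: 1 = perfect phase alignment, 0 = uniform phase.
#' Amplitude never enters (phase-only statistic).
#'
#' @param phases trials x freqs x time array of phases in radians (a
#'   trials x k matrix is treated as one-dimensional cells).
#' @param group indices (or logical mask) of the trials to include.
#' @return freqs x time matrix (or vector) of ITC values in `[0, 1]`.
#' @export
compute_itc <- function(phases, group = seq_len(dim(phases)[1])) {
  if (is.matrix(phases)) phases <- array(phases, c(dim(phases), 1L))
  sub <- phases[group, , , drop = FALSE]
  if (dim(sub)[1] < 1) stop("empty trial group")
  drop(Mod(colMeans(exp(1i * sub))))
}

# mean over groups of within-group ITC; groups = list of index vectors
.grouped_itc_stat <- function(phases, groups) {
  acc <- 0
  for (g in groups) acc <- acc + compute_itc(phases, g)
  acc / length(groups)
}

.itc_result <- function(observed, null_draws, n_shuffles, seed,
                        p_method = "normal") {
  null_mean <- apply(null_draws, c(1, 2), mean)
  null_sd <- apply(null_draws, c(1, 2), stats::sd)
  tval <- (observed - null_mean) / null_sd
  p <- if (p_method == "normal") {
    stats::pnorm(tval, lower.tail = FALSE)
  } else {
    (1 + apply(sweep(null_draws, c(1, 2), observed, `>=`), c(1, 2), sum)) /
      (1 + n_shuffles)
  }
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, t = tval, p = p,
                 n_shuffles = n_shuffles, seed = seed,
                 p_method = p_method),
            class = "itc_result")
}

#' Quintile ITC bootstrap test of a phase-RT relationship
#'
#' Observed statistic: the mean over RT quintiles of the within-quintile ITC,
#' per (frequency, time) cell. Null: the same statistic with trials shuffled
#' into quintiles at random, repeated `n_shuffles` times; `t = (observed -
#' null mean) / null SD` and one-sided p-values from the Gaussian tail of the
#' shuffle null (`p_method = "empirical"` gives exact permutation p-values
#' for small designs instead).
#'
#' @param phases trials x freqs x time phase array (from [hilbert_tf()]).
#' @param rt per-trial reaction times.
#' @param n_shuffles number of random shuffles (default 100).
#' @param seed RNG seed.
#' @param p_method `"normal"` (default) or `"empirical"`.
#' @return object of class `itc_result`: `observed`, `null_mean`, `null_sd`,
#'   `t`, `p` (all freqs x time), `n_shuffles`, `seed`.
#' @export
quintile_itc_test <- function(phases, rt, n_shuffles = 100, seed = 1,
                              p_method = c("normal", "empirical")) {
  p_method <- match.arg(p_method)
  if (n_shuffles < 2) stop("need at least 2 shuffles")
  if (is.matrix(phases)) phases <- array(phases, c(dim(phases), 1L))
  n <- dim(phases)[1]
  q <- split_quintiles(rt)
  groups <- split(seq_len(n), q)
  observed <- .grouped_itc_stat(phases, groups)
  observed <- matrix(observed, dim(phases)[2], dim(phases)[3])
  set.seed(seed)
  null_draws <- array(NA_real_, c(dim(phases)[2], dim(phases)[3], n_shuffles))
  for (s in seq_len(n_shuffles)) {
    qs <- sample(q)
    null_draws[, , s] <- .grouped_itc_stat(phases, split(seq_len(n), qs))
  }
  .itc_result(observed, null_draws, n_shuffles, seed, p_method)
}

#' Label-based ITC contrast (e.g. left vs right choices)
#'
#' Same machinery as [quintile_itc_test()] with label groups replacing RT
#' quintiles: tests whether phases are more coherent across trials leading to
#' the same outcome than across randomly regrouped trials.
#'
#' @param phases trials x freqs x time phase array.
#' @param labels per-trial group labels (at least 2 levels, each with at
#'   least 2 trials).
#' @inheritParams quintile_itc_test
#' @return an `itc_result`.
#' @export
label_itc_contrast <- function(phases, labels, n_shuffles = 100, seed = 1,
                               p_method = c("normal", "empirical")) {
  p_method <- match.arg(p_method)
  if (n_shuffles < 2) stop("need at least 2 shuffles")
  if (is.matrix(phases)) phases <- array(phases, c(dim(phases), 1L))
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 label groups")
  if (any(tab < 2)) stop("every label group needs at least 2 trials")
  n <- dim(phases)[1]
  groups <- split(seq_len(n), labels)
  observed <- matrix(.grouped_itc_stat(phases, groups),
                     dim(phases)[2], dim(phases)[3])
  set.seed(seed)
  null_draws <- array(NA_real_, c(dim(phases)[2], dim(phases)[3], n_shuffles))
  for (s in seq_len(n_shuffles)) {
    ls <- sample(labels)
    null_draws[, , s] <- .grouped_itc_stat(phases, split(seq_len(n), ls))
  }
  .itc_result(observed, null_draws, n_shuffles, seed, p_method)
}

#' Supra-threshold clusters of an ITC map
#'
#' A cluster is a 4-connected component of cells with `p < alpha` spanning at
#' least `min_freqs` adjacent frequencies and `min_times` adjacent time bins.
#'
#' @param result an `itc_result` (or any list with a `p` matrix).
#' @param alpha cell-wise threshold (default 0.05).
#' @param min_freqs,min_times minimum extent (default 2 x 2).
#' @return `data.frame` of clusters: id, extent, minimum p.
#' @export
itc_clusters <- function(result, alpha = 0.05, min_freqs = 2, min_times = 2) {
  p <- result$p
  mask <- !is.na(p) & p < alpha
  lab <- matrix(0L, nrow(p), ncol(p))
  cur <- 0L
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      a <- ij[1]; b <- ij[2]
      if (a < 1 || b < 1 || a > nrow(p) || b > ncol(p)) next
      if (!mask[a, b] || lab[a, b] != 0L) next
      lab[a, b] <- cur
      stack <- c(stack, list(c(a - 1, b), c(a + 1, b),
                             c(a, b - 1), c(a, b + 1)))
    }
  }
  out <- list()
  for (k in seq_len(cur)) {
    cells <- which(lab == k, arr.ind = TRUE)
    if (length(unique(cells[, 1])) >= min_freqs &&
        length(unique(cells[, 2])) >= min_times) {
      out[[length(out) + 1]] <- data.frame(
        cluster = length(out) + 1, n_cells = nrow(cells),
        freq_lo = min(cells[, 1]), freq_hi = max(cells[, 1]),
        time_lo = min(cells[, 2]), time_hi = max(cells[, 2]),
        min_p = min(p[cells]))
    }
  }
  if (!length(out)) {
    return(data.frame(cluster = integer(0), n_cells = integer(0),
                      freq_lo = integer(0), freq_hi = integer(0),
                      time_lo = integer(0), time_hi = integer(0),
                      min_p = numeric(0)))
  }
  do.call(rbind, out)
}
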