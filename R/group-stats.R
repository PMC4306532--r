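# Group-level inference: one-sample tests of per-subject statistics against
# zero, sign-flip permutation testing with max-statistic (omnibus) correction
# across voxels, and Benjamini-Hochberg FDR control over declared families.

#' One-sample group test against zero
#'
#' Per-cell one-sample t-test of the subjects' values (r-values for
#' amplitude analyses, t-values for phase analyses) against zero, two-sided.
#' r-values enter untransformed by default (a Fisher-z option is provided).
#'
#' @param values subjects x cells matrix (or per-subject vector for one
#'   cell).
#' @param fisher_z apply `atanh` before testing (default `FALSE`).
#' @return list: `t`, `p` (two-sided), `mean`, `n_subjects`,
#'   `zero_variance` (logical per cell; such cells get `t = Inf` with the
#'   sign of the mean, `p = NA`).
#' @export
one_sample_group_test <- function(values, fisher_z = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) == 1 && nrow(values) == 1) stop("need at least 2 subjects")
  if (nrow(values) < 2) stop("need at least 2 subjects")
  if (fisher_z) values <- atanh(values)
  n <- nrow(values)
  m <- colMeans(values)
  s <- apply(values, 2, stats::sd)
  zero_var <- s == 0
  tval <- ifelse(zero_var, ifelse(m == 0, 0, sign(m) * Inf),
                 m / (s / sqrt(n)))
  p <- ifelse(zero_var & m != 0, NA_real_,
              2 * stats::pt(-abs(tval), df = n - 1))
  list(t = tval, p = p, mean = m, n_subjects = n, zero_variance = zero_var)
}

# all 2^n sign patterns (rows), identity first
.all_sign_flips <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(m) <- NULL
  m
}

#' Sign-flip permutation test with omnibus (max-statistic) correction
#'
#' Permutes the signs of the subject maps, recomputes the one-sample t per
#' voxel for every flip, and corrects for multiple comparisons across voxels
#' with the permutation distribution of the maximum |t|: the corrected
#' p-value of a voxel is the fraction of flips whose maximum |t| over voxels
#' reaches its observed |t|. All `2^n` flips are enumerated when
#' `n_subjects <= 12` (4096 flips); otherwise `n_perm` random flips
#' (including the identity) are drawn.
#'
#' @param maps subjects x voxels matrix of per-subject statistics.
#' @param n_perm number of Monte-Carlo flips (ignored in exhaustive mode);
#'   must be at least 10.
#' @param seed RNG seed (unused in exhaustive mode, which is seed-free).
#' @param exhaustive force/forbid exhaustive enumeration (`NULL` = auto).
#' @return object of class `group_map_result`: `mean`, `t`, `p_corrected`,
#'   `p_uncorrected`, `max_t_null`, `n_subjects`, `n_permutations`,
#'   `exhaustive`, `seed`.
#' @export
permutation_omnibus <- function(maps, n_perm = 4096, seed = 1,
                                exhaustive = NULL) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 2) stop("need at least 2 subjects")
  if (is.null(exhaustive)) exhaustive <- n <= 12
  if (!exhaustive && n_perm < 10) stop("need at least 10 permutations")
  if (exhaustive) {
    S <- .all_sign_flips(n)
  } else {
    set.seed(seed)
    S <- matrix(sample(c(1, -1), (n_perm - 1) * n, replace = TRUE),
                n_perm - 1, n)
    S <- rbind(rep(1, n), S)
  }
  P <- nrow(S)
  M <- (S %*% maps) / n                       # flip means, P x V
  Q <- matrix(colSums(maps^2), P, ncol(maps), byrow = TRUE)
  v <- (Q - n * M^2) / (n - 1)
  tmat <- M / sqrt(pmax(v, 0) / n)
  tmat[!is.finite(tmat)] <- 0
  t_obs <- tmat[1, ]                          # identity flip
  maxabs <- apply(abs(tmat), 1, max)
  p_corr <- vapply(abs(t_obs), function(t0) mean(maxabs >= t0 - 1e-12),
                   numeric(1))
  p_unc <- vapply(seq_along(t_obs), function(vx) {
    mean(abs(tmat[, vx]) >= abs(t_obs[vx]) - 1e-12)
  }, numeric(1))
  structure(list(mean = colMeans(maps), t = t_obs,
                 p_corrected = p_corr, p_uncorrected = p_unc,
                 max_t_null = maxabs, n_subjects = n,
                 n_permutations = P, exhaustive = exhaustive,
                 seed = if (exhaustive) NA_integer_ else seed),
            class = "group_map_result")
}

#' @export
print.group_map_result <- function(x, ...) {
  cat("group_map_result:", length(x$t), "voxels,", x$n_subjects, "subjects,",
      x$n_permutations, if (x$exhaustive) "exhaustive" else "Monte-Carlo",
      "sign flips\n")
  cat("  min corrected p:", format(min(x$p_corrected), digits = 3), "\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR correction over a declared family
#'
#' Standard step-up false discovery rate control over the whole declared
#' family (frequencies/bands x time bins x ROIs x regressor types, as
#' labelled by `context`).
#'
#' @param pvals vector of p-values in `(0, 1]`.
#' @param q FDR level (default 0.05).
#' @param context optional `data.frame` of labels, one row per p-value.
#' @return object of class `fdr_result`: `p`, `p_adjusted`, `reject`,
#'   `q`, `context`.
#' @export
fdr_correct <- function(pvals, q = 0.05, context = NULL) {
  if (!length(pvals)) stop("empty p-value family")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (!is.null(context) && nrow(context) != length(pvals)) {
    stop("context rows must match the p-values")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  structure(list(p = pvals, p_adjusted = adj, reject = adj <= q,
                 q = q, context = context),
            class = "fdr_result")
}
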