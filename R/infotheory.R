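#' Encode a binary Kenyon-cell state as an integer code
#'
#' The population state of `n_kc` binary Kenyon cells is one of `2^n_kc`
#' patterns; cell `i` contributes `2^(i-1)` when active, so codes run from 0
#' (all silent) to `2^n_kc - 1`. The encoding is bijective; [decode_state()]
#' inverts it.
#'
#' @param kc trials x `n_kc` 0/1 matrix (a vector is one trial).
#' @return Numeric vector of state codes, one per trial.
#' @examples
#' encode_state(c(1, 0, 0, 1)) # 1 + 8
#' @export
encode_state <- function(kc) {
  if (is.vector(kc)) kc <- matrix(kc, nrow = 1)
  drop(kc %*% 2^(seq_len(ncol(kc)) - 1))
}

#' @rdname encode_state
#' @param code integer state code(s) in `[0, 2^n_kc)`.
#' @param n_kc number of Kenyon cells.
#' @return `decode_state()`: a `length(code)` x `n_kc` 0/1 matrix.
#' @export
decode_state <- function(code, n_kc) {
  check_count(n_kc, "n_kc")
  if (any(code < 0) || any(code >= 2^n_kc)) {
    stop_invalid("`code` must lie in [0, 2^n_kc).")
  }
  out <- matrix(0L, nrow = length(code), ncol = n_kc)
  for (i in seq_len(n_kc)) {
    out[, i] <- as.integer(code %% 2 >= 1)
    code <- code %/% 2
  }
  out
}

#' Tabulate trial records into a joint odor-by-state contingency table
#'
#' @param trials a data frame with columns `odor` (1-based odor label) and
#'   `state` (integer state code), one row per trial.
#' @param n_odors number of odors; defaults to the largest label seen.
#' @return An `n_odors` x n-observed-states integer matrix of class
#'   `flymi_counts`; columns are named by state code and carry only states
#'   that occur (unobserved states contribute nothing to the estimator).
#'   The per-odor trial count is in attribute `trials_per_odor`.
#' @examples
#' tabulate_trials(data.frame(odor = c(1, 1, 2), state = c(5, 5, 0)))
#' @export
tabulate_trials <- function(trials, n_odors = max(trials$odor, 1)) {
  n_odors <- check_count(n_odors, "n_odors")
  if (nrow(trials) == 0) {
    counts <- matrix(0L, nrow = n_odors, ncol = 0)
    return(structure(counts,
      trials_per_odor = 0L,
      class = c("flymi_counts", class(counts))
    ))
  }
  if (any(trials$odor < 1 | trials$odor > n_odors | trials$odor != round(trials$odor))) {
    stop_invalid("odor labels must be integers in 1..n_odors.")
  }
  if (any(trials$state < 0)) stop_invalid("state codes must be >= 0.")
  counts <- counts_from_codes(trials$odor, trials$state, n_odors)
  per_odor <- rowSums(counts)
  balanced <- length(unique(per_odor)) == 1
  structure(counts,
    trials_per_odor = if (balanced) as.integer(per_odor[1]) else NA_integer_,
    class = c("flymi_counts", class(counts))
  )
}

# Fast core: contingency table over observed states only.
counts_from_codes <- function(odor, code, n_odors) {
  states <- sort(unique(code))
  s <- match(code, states)
  counts <- matrix(
    tabulate(odor + (s - 1L) * n_odors, nbins = n_odors * length(states)),
    nrow = n_odors
  )
  colnames(counts) <- format(states, scientific = FALSE, trim = TRUE)
  counts
}

# MI (in `base` log units) of a nonneg count matrix, rows = odors.
mi_from_counts <- function(counts, base = 2, guard = 1e-8) {
  total <- sum(counts)
  if (total == 0) stop_invalid("the contingency table is empty.")
  pnk <- counts / total
  pk <- rowSums(pnk)
  pn <- colSums(pnk)
  # unobserved states are assigned a tiny floor probability; inert under the
  # 0 * log 0 = 0 convention because their joint mass is zero too
  pn[pn == 0] <- guard
  ratio <- pnk / outer(pk, pn)
  nz <- pnk > 0
  sum(pnk[nz] * log(ratio[nz], base = base))
}

#' Plug-in mutual information between odor identity and Kenyon-cell state
#'
#' The maximum-likelihood ("plug-in") estimator: empirical joint
#' probabilities `p(n, k)` over odors `k` and state codes `n` are plugged
#' into `sum p(n,k) log( p(n,k) / (p(n) p(k)) )`. Odors are presented
#' equiprobably, so with balanced trial counts `p(k) = 1/K`. Zero joint
#' cells contribute 0; the probability of a never-observed state is floored
#' at `guard` for calculability (numerically inert under that convention).
#'
#' @param x a `flymi_counts` table, a plain odor-by-state count matrix, or a
#'   trial data frame as accepted by [tabulate_trials()].
#' @param base logarithm base: 2 (bits, default) or `exp(1)` (nats).
#' @param guard floor probability for unobserved states. Default `1e-8`.
#' @return Mutual information (non-negative, at most `log(K, base)` and
#'   `log(number of states, base)`).
#' @examples
#' # perfect 4-odor channel: 2 bits
#' plugin_mi(diag(4) * 25)
#' @export
plugin_mi <- function(x, base = 2, guard = 1e-8) {
  if (is.data.frame(x)) x <- tabulate_trials(x)
  if (!is.matrix(x) || any(x < 0)) {
    stop_invalid("`x` must be a non-negative count matrix or a trial data frame.")
  }
  mi_from_counts(x, base = base, guard = guard)
}

#' Solve the quadratic-in-1/N extrapolation system
#'
#' Given plug-in estimates at sample sizes `N`, `N/2` and `N/4`, fits
#' `MI(N') = MI_inf + a/N' + b/N'^2` exactly (three equations, three
#' unknowns) and returns the extrapolated `MI_inf` together with the bias
#' coefficients, so `MI_corrected = MI(N) - (a/N + b/N^2)`.
#'
#' @param mi_n,mi_half,mi_quarter plug-in MI at `N`, `N/2`, `N/4`.
#' @param n the full sample size `N` (trials per odor).
#' @return A list with `mi_inf`, `a`, `b`.
#' @examples
#' solve_extrapolation(1.0, 1.1, 1.3, n = 100)
#' @export
solve_extrapolation <- function(mi_n, mi_half, mi_quarter, n) {
  check_scalar_number(n, "n", lower = 0, strict_lower = TRUE)
  x <- c(1 / n, 2 / n, 4 / n)
  a_mat <- cbind(1, x, x^2)
  sol <- solve(a_mat, c(mi_n, mi_half, mi_quarter))
  list(mi_inf = sol[[1]], a = sol[[2]], b = sol[[3]])
}

# Fast core used by the sweep drivers: odor/code vectors already split by
# odor into a K x T code matrix. One random stratified partition into 2
# disjoint halves and 4 disjoint quarters per odor (drawn from the current
# RNG stream) feeds the extrapolation.
qe_mi_codes <- function(code_mat, base = 2, guard = 1e-8) {
  n_odors <- nrow(code_mat)
  n_trials <- ncol(code_mat)
  odor <- rep(seq_len(n_odors), times = n_trials)
  mi_full <- mi_from_counts(counts_from_codes(odor, as.vector(code_mat), n_odors),
    base = base, guard = guard
  )
  perm <- t(vapply(seq_len(n_odors), function(k) sample.int(n_trials), integer(n_trials)))
  sub_mi <- function(cols_list) {
    mean(vapply(cols_list, function(cols) {
      sub <- vapply(
        seq_len(n_odors),
        function(k) code_mat[k, perm[k, cols]], numeric(length(cols))
      )
      # sub: length(cols) x n_odors; odors vary along columns
      mi_from_counts(
        counts_from_codes(rep(seq_len(n_odors), each = length(cols)), as.vector(sub), n_odors),
        base = base, guard = guard
      )
    }, numeric(1)))
  }
  half <- n_trials %/% 2
  quarter <- n_trials %/% 4
  mi_half <- sub_mi(list(seq_len(half), half + seq_len(half)))
  mi_quarter <- sub_mi(lapply(0:3, function(i) i * quarter + seq_len(quarter)))
  sol <- solve_extrapolation(mi_full, mi_half, mi_quarter, n_trials)
  list(
    mi_uncorrected = mi_full, mi_half = mi_half, mi_quarter = mi_quarter,
    mi_inf = sol$mi_inf, a = sol$a, b = sol$b, n_trials = n_trials
  )
}

#' Bias-corrected mutual information by quadratic extrapolation
#'
#' With finitely many trials the plug-in estimator is biased upward. The
#' quadratic-extrapolation correction models the bias as a second-order
#' expansion in 1/N: the estimator is re-run on a random stratified
#' partition of the trials into 2 disjoint halves (averaged) and 4 disjoint
#' quarters (averaged), the exact quadratic `MI(N') = MI_inf + a/N' + b/N'^2`
#' is solved through the three points, and `MI_inf` is reported as the
#' corrected estimate. Partitions are stratified per odor so every
#' subsample keeps the odors equiprobable. A (rare) negative extrapolation
#' is floored at zero with a warning.
#'
#' @param trials data frame with columns `odor` and `state`, balanced across
#'   odors; the per-odor trial count must be divisible by 4 and at least 8.
#' @param base logarithm base (2 = bits).
#' @param guard floor probability for unobserved states.
#' @param seed optional integer seeding the partition draw locally.
#' @return An object of class `flymi_mi`: a list with elements
#'   `mi_corrected`, `mi_uncorrected`, `coef_a`, `coef_b`, `mi_half`,
#'   `mi_quarter`, `n_trials`, `n_odors`, `base`, `clamped`. Supports
#'   [tidy()], [glance()] and `print()`.
#' @examples
#' trials <- data.frame(odor = rep(1:4, each = 16), state = rep(1:4, each = 16))
#' mi_extrapolate(trials) # deterministic channel: correction changes nothing
#' @export
mi_extrapolate <- function(trials, base = 2, guard = 1e-8, seed = NULL) {
  counts <- tabulate_trials(trials)
  n_trials <- attr(counts, "trials_per_odor")
  if (is.na(n_trials)) {
    stop_invalid("every odor must contribute the same number of trials.")
  }
  if (n_trials < 8 || n_trials %% 4 != 0) {
    stop_invalid("trials per odor must be >= 8 and divisible by 4.")
  }
  n_odors <- nrow(counts)
  code_mat <- matrix(0, nrow = n_odors, ncol = n_trials)
  for (k in seq_len(n_odors)) {
    code_mat[k, ] <- trials$state[trials$odor == k]
  }
  res <- local_seed(seed, qe_mi_codes(code_mat, base = base, guard = guard))
  finish_mi_estimate(res, n_odors, base)
}

finish_mi_estimate <- function(res, n_odors, base) {
  clamped <- res$mi_inf < 0
  if (clamped) {
    warn(sprintf(
      "extrapolated MI was negative (%.4g); reporting 0.", res$mi_inf
    ), class = "flymi_warning_clamped")
  }
  structure(
    list(
      mi_corrected = max(res$mi_inf, 0),
      mi_uncorrected = res$mi_uncorrected,
      coef_a = res$a, coef_b = res$b,
      mi_half = res$mi_half, mi_quarter = res$mi_quarter,
      n_trials = res$n_trials, n_odors = n_odors,
      base = base, clamped = clamped
    ),
    class = "flymi_mi"
  )
}

#' @export
print.flymi_mi <- function(x, ...) {
  unit <- if (isTRUE(all.equal(x$base, 2))) "bits" else sprintf("log-base-%g units", x$base)
  cat(sprintf(
    "Mutual information (%d odors, %d trials/odor)\n  plug-in: %.4f %s\n  corrected (quadratic extrapolation): %.4f %s%s\n",
    x$n_odors, x$n_trials, x$mi_uncorrected, unit, x$mi_corrected, unit,
    if (x$clamped) " [clamped at 0]" else ""
  ))
  invisible(x)
}

#' Tidy an MI estimate
#'
#' @param x a `flymi_mi` object from [mi_extrapolate()].
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per quantity (`term`,
#'   `estimate`); `glance()`: a one-row tibble with the corrected and
#'   uncorrected estimates, bias coefficients and sample sizes.
#' @method tidy flymi_mi
#' @export
tidy.flymi_mi <- function(x, ...) {
  tibble::tibble(
    term = c("mi_corrected", "mi_uncorrected", "coef_a", "coef_b"),
    estimate = c(x$mi_corrected, x$mi_uncorrected, x$coef_a, x$coef_b)
  )
}

#' @rdname tidy.flymi_mi
#' @method glance flymi_mi
#' @export
glance.flymi_mi <- function(x, ...) {
  tibble::tibble(
    mi_corrected = x$mi_corrected, mi_uncorrected = x$mi_uncorrected,
    coef_a = x$coef_a, coef_b = x$coef_b,
    mi_half = x$mi_half, mi_quarter = x$mi_quarter,
    n_odors = x$n_odors, n_trials = x$n_trials,
    base = x$base, clamped = x$clamped
  )
}
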