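#' Configure a simulated olfactory-information experiment
#'
#' Bundles and validates every parameter of the protocol: circuit sizes,
#' the transfer steepness `beta`, grids over concentration, connectivity
#' rate `r`, Kenyon-cell threshold `theta` and inhibition strength `alpha`,
#' the replication structure (flies, trials), and the master seed from which
#' all per-task streams are derived (see [derive_seed()]).
#'
#' Defaults follow the study protocol: 10 Kenyon cells reading 50 OPNs,
#' 5-odor panels at one shared concentration, 100 trials per odor, 20 fly
#' replicates, `beta = 1.32`, thresholds 1-20 and `r = 0.3`.
#'
#' @param n_kc number of Kenyon cells (10 or 20 in the study).
#' @param n_glomeruli number of glomeruli / OPNs. Default 50.
#' @param n_odors odors per panel. Default 5.
#' @param n_trials trials per odor; must be divisible by 4 (the
#'   bias-correction partitions the data into halves and quarters).
#' @param n_flies number of connectome replicates averaged over.
#' @param beta concentration-to-activity steepness, > 0.
#' @param concentration concentration grid, each value in `(0, 1]`.
#' @param theta integer threshold grid, values >= 1.
#' @param r connectivity-rate grid, values strictly in `(0, 1)`.
#' @param alpha inhibition grid: `NULL` for the no-inhibition condition
#'   only, or a numeric vector of strengths, optionally including `NA` for
#'   the no-inhibition condition alongside inhibited ones.
#' @param seed master seed; every panel, connectome, trial, inhibition draw
#'   and subsampling partition derives its own stream from it.
#' @param inhibition_activity how mushroom-body activity enters the
#'   inhibition law: `"fraction"` (default) or `"count"`; see
#'   [inhibition_probability()].
#' @param log_base logarithm base for MI (2 = bits).
#' @param shared_panel if `TRUE`, all flies smell the identical odor panel;
#'   by default each fly replicate gets its own panel so the average spans
#'   odor-structure as well as connectome variability.
#' @param mu_opn,sigma2_opn mean and variance of the reached-OPN count.
#' @return A validated list of class `flymi_config`.
#' @examples
#' experiment_config(concentration = 0.75, alpha = c(NA, 0.9), seed = 1)
#' @export
experiment_config <- function(n_kc = 10, n_glomeruli = 50, n_odors = 5,
                              n_trials = 100, n_flies = 20, beta = 1.32,
                              concentration = 0.15, theta = 1:20, r = 0.3,
                              alpha = NULL, seed = 1L,
                              inhibition_activity = c("fraction", "count"),
                              log_base = 2, shared_panel = FALSE,
                              mu_opn = 35, sigma2_opn = 8) {
  inhibition_activity <- match.arg(inhibition_activity)
  cfg <- list(
    n_kc = check_count(n_kc, "n_kc"),
    n_glomeruli = check_count(n_glomeruli, "n_glomeruli"),
    n_odors = check_count(n_odors, "n_odors"),
    n_trials = check_count(n_trials, "n_trials", lower = 8L),
    n_flies = check_count(n_flies, "n_flies"),
    beta = beta, concentration = concentration,
    theta = theta, r = r, alpha = alpha,
    seed = check_count(seed, "seed", lower = 0L),
    inhibition_activity = inhibition_activity,
    log_base = log_base, shared_panel = isTRUE(shared_panel),
    mu_opn = mu_opn, sigma2_opn = sigma2_opn
  )
  check_scalar_number(beta, "beta", lower = 0, strict_lower = TRUE)
  check_scalar_number(log_base, "log_base", lower = 1, strict_lower = TRUE)
  check_scalar_number(mu_opn, "mu_opn", lower = 0, strict_lower = TRUE)
  check_scalar_number(sigma2_opn, "sigma2_opn", lower = 0, strict_lower = TRUE)
  if (cfg$n_trials %% 4 != 0) stop_invalid("`n_trials` must be divisible by 4.")
  if (length(concentration) < 1 || any(concentration <= 0 | concentration > 1)) {
    stop_invalid("`concentration` values must lie in (0, 1].")
  }
  if (length(theta) < 1 || any(theta < 1 | theta != round(theta))) {
    stop_invalid("`theta` values must be integers >= 1.")
  }
  if (length(r) < 1 || any(r <= 0 | r >= 1)) {
    stop_invalid("`r` values must lie strictly in (0, 1).")
  }
  if (!is.null(alpha)) {
    if (length(alpha) < 1 || any(alpha[!is.na(alpha)] <= 0)) {
      stop_invalid("`alpha` values must be > 0 (NA marks the no-inhibition condition).")
    }
  }
  structure(cfg, class = "flymi_config")
}

#' @export
print.flymi_config <- function(x, ...) {
  cat("flymi experiment configuration\n")
  show <- function(v) if (length(v) > 6) sprintf("%s, ... (%d values)", paste(head(v, 6), collapse = ", "), length(v)) else paste(v, collapse = ", ")
  cat(sprintf("  circuit: %d KCs x %d OPNs, beta = %g\n", x$n_kc, x$n_glomeruli, x$beta))
  cat(sprintf(
    "  panel: %d odors, concentration {%s}\n  replication: %d flies x %d trials/odor, master seed %d\n",
    x$n_odors, show(x$concentration), x$n_flies, x$n_trials, x$seed
  ))
  cat(sprintf("  theta {%s}; r {%s}; alpha {%s} (%s activity)\n",
    show(x$theta), show(x$r),
    if (is.null(x$alpha)) "none" else show(ifelse(is.na(x$alpha), "none", x$alpha)),
    x$inhibition_activity
  ))
  invisible(x)
}

# Alpha grid as used internally: NA encodes the no-inhibition condition.
alpha_grid <- function(cfg) if (is.null(cfg$alpha)) NA_real_ else cfg$alpha

# Summed synaptic drive for every (odor, trial): (K * n_trials) x n_kc,
# odor-major blocks of n_trials rows. Consumes the current RNG stream.
simulate_drive <- function(panel, connectome, n_trials, beta) {
  ng <- ncol(connectome)
  w_t <- t(unclass(connectome))
  blocks <- lapply(seq_len(nrow(panel)), function(k) {
    p <- activation_probability(panel$concentration[k], beta)
    sample_al_matrix(panel$reachable[[k]], p, ng, n_trials) %*% w_t
  })
  do.call(rbind, blocks)
}

# One fly at one (concentration, r): MI over the full theta x alpha grid.
# Seeds are derived per task from the master seed so results are identical
# whatever order grid points are evaluated in.
fly_grid_mi <- function(cfg, panel, ci, ri, fly) {
  conc <- cfg$concentration[ci]
  panel$concentration <- conc
  connectome <- sample_connectome(
    cfg$n_kc, cfg$n_glomeruli, cfg$r[ri],
    seed = derive_seed(cfg$seed, "connectome", fly, ri)
  )
  drive <- local_seed(
    derive_seed(cfg$seed, "trials", fly, ci, ri),
    simulate_drive(panel, connectome, cfg$n_trials, cfg$beta)
  )
  alphas <- alpha_grid(cfg)
  grid <- tidyr::expand_grid(ti = seq_along(cfg$theta), ai = seq_along(alphas))
  mi <- purrr::pmap_dbl(grid, function(ti, ai) {
    kc <- matrix(as.integer(drive > cfg$theta[ti]), nrow = nrow(drive))
    if (!is.na(alphas[ai])) {
      kc <- local_seed(
        derive_seed(cfg$seed, "inhibition", fly, ci, ri, ti, ai),
        apply_inhibition_matrix(kc, alphas[ai], cfg$inhibition_activity)
      )
    }
    codes <- encode_state(kc)
    code_mat <- t(matrix(codes, nrow = cfg$n_trials, ncol = cfg$n_odors))
    res <- local_seed(
      derive_seed(cfg$seed, "partition", fly, ci, ri, ti, ai),
      qe_mi_codes(code_mat, base = cfg$log_base)
    )
    max(res$mi_inf, 0)
  })
  tibble::tibble(
    concentration = conc, r = cfg$r[ri],
    theta = as.numeric(cfg$theta[grid$ti]), alpha = alphas[grid$ai],
    fly = fly, mi = mi
  )
}

fly_panel <- function(cfg, fly) {
  draw_odor_panel(
    cfg$n_odors, cfg$concentration[1], cfg$mu_opn, cfg$sigma2_opn,
    cfg$n_glomeruli,
    seed = derive_seed(cfg$seed, "panel", if (cfg$shared_panel) 0L else fly)
  )
}

#' Sweep mutual information over the experiment's parameter grids
#'
#' Runs the full protocol: for every fly replicate an odor panel and, per
#' connectivity rate, a fresh Bernoulli connectome are drawn; every
#' (concentration, r) cell is simulated once per fly and re-thresholded for
#' each `theta` and inhibition strength; bias-corrected MI is estimated per
#' fly and averaged across flies. All randomness derives from the master
#' seed by task-labelled streams, so a sweep is reproducible bit-for-bit
#' and independent of evaluation order.
#'
#' @param config a [experiment_config()].
#' @param per_fly if `TRUE`, return one row per fly instead of the
#'   across-fly summary.
#' @return A tibble of class `flymi_sweep`, one row per grid point:
#'   `concentration`, `r`, `theta`, `alpha` (`NA` = no inhibition),
#'   `mi_mean`, `mi_sd`, `n_flies` (or per-fly rows with `fly`, `mi`). The
#'   configuration is attached as attribute `config`.
#' @examples
#' cfg <- experiment_config(
#'   n_odors = 3, n_trials = 16, n_flies = 2,
#'   theta = c(2, 4), seed = 11
#' )
#' mi_sweep(cfg)
#' @export
mi_sweep <- function(config, per_fly = FALSE) {
  stopifnot(inherits(config, "flymi_config"))
  cells <- tidyr::expand_grid(
    ci = seq_along(config$concentration),
    ri = seq_along(config$r)
  )
  rows <- purrr::map(seq_len(config$n_flies), function(fly) {
    panel <- fly_panel(config, fly)
    purrr::pmap(cells, function(ci, ri) fly_grid_mi(config, panel, ci, ri, fly))
  })
  long <- dplyr::bind_rows(purrr::flatten(rows))
  out <- if (per_fly) {
    long
  } else {
    dplyr::summarise(
      long,
      mi_mean = mean(.data$mi), mi_sd = sd(.data$mi),
      n_flies = dplyr::n(),
      .by = c("concentration", "r", "theta", "alpha")
    )
  }
  attr(out, "config") <- config
  class(out) <- c("flymi_sweep", class(tibble::tibble()))
  out
}

#' Bias-corrected MI for a single fly replicate
#'
#' Convenience wrapper around the sweep engine for a configuration whose
#' grids are all singletons: one connectome, `n_trials` trials of each of
#' the panel's odors, one threshold and inhibition setting. Uses exactly the
#' per-task seed streams of [mi_sweep()], so `run_fly()` over
#' `1:n_flies` averages to the corresponding sweep cell.
#'
#' @param config a [experiment_config()] with scalar `concentration`, `r`,
#'   `theta` and at most one `alpha` entry.
#' @param panel optional `flymi_panel` to present instead of the fly's own
#'   derived panel.
#' @param fly replicate index (seeds the panel, connectome and trials).
#' @return Bias-corrected mutual information (scalar, >= 0).
#' @examples
#' cfg <- experiment_config(n_odors = 3, n_trials = 16, theta = 4, seed = 5)
#' run_fly(cfg, fly = 1)
#' @export
run_fly <- function(config, panel = NULL, fly = 1L) {
  stopifnot(inherits(config, "flymi_config"))
  if (length(config$concentration) != 1 || length(config$r) != 1 ||
    length(config$theta) != 1 || length(alpha_grid(config)) != 1) {
    stop_invalid("`run_fly()` needs scalar concentration, r, theta and alpha; use `mi_sweep()` for grids.")
  }
  fly <- check_count(fly, "fly")
  if (is.null(panel)) panel <- fly_panel(config, fly)
  validate_odor_panel(panel)
  fly_grid_mi(config, panel, 1L, 1L, fly)$mi[1]
}

#' Threshold (or connectivity) maximising mean mutual information
#'
#' Reads a sweep result along its threshold axis (after optionally
#' filtering to one slice of the other axes) and returns the `theta` with
#' the highest across-fly mean MI. Ties are broken toward the smaller
#' threshold, with a message. `argmax_connectivity()` is the transposed
#' read-out along `r`.
#'
#' @param result a `flymi_sweep` (summary form).
#' @param ... optional `dplyr::filter()` conditions selecting one slice,
#'   e.g. `concentration == 0.15, is.na(alpha)`.
#' @return The maximising `theta` (respectively `r`), as a scalar.
#' @examples
#' cfg <- experiment_config(
#'   n_odors = 3, n_trials = 16, n_flies = 2,
#'   theta = c(2, 4, 6), seed = 3
#' )
#' argmax_threshold(mi_sweep(cfg))
#' @export
argmax_threshold <- function(result, ...) {
  argmax_axis(result, "theta", ...)
}

#' @rdname argmax_threshold
#' @export
argmax_connectivity <- function(result, ...) {
  argmax_axis(result, "r", ...)
}

argmax_axis <- function(result, axis, ...) {
  df <- dplyr::filter(tibble::as_tibble(result), ...)
  if (nrow(df) == 0) {
    abort("no sweep rows left after filtering.", class = "flymi_error_empty_filter")
  }
  if (anyDuplicated(df[[axis]])) {
    abort(
      sprintf(
        "several rows per `%s` remain; filter the other axes down to one slice first.",
        axis
      ),
      class = "flymi_error_empty_filter"
    )
  }
  best <- df[[axis]][df$mi_mean == max(df$mi_mean)]
  if (length(best) > 1) {
    rlang::inform(sprintf(
      "tie between %s = {%s}; taking the smallest.", axis, paste(best, collapse = ", ")
    ))
  }
  min(best)
}

#' Write / read a sweep result as annotated CSV
#'
#' The CSV carries the full configuration (including the master seed and
#' package version) in `#`-prefixed header comments, so a result file is
#' self-describing and replayable; `read_sweep_csv()` restores both the
#' table and the configuration attribute.
#'
#' @param result a `flymi_sweep`.
#' @param path file path.
#' @return `write_sweep_csv()` returns `result` invisibly;
#'   `read_sweep_csv()` the reconstructed `flymi_sweep`.
#' @export
write_sweep_csv <- function(result, path) {
  cfg <- attr(result, "config")
  hdr <- c(
    "# flymi sweep result",
    sprintf("# version: flymi %s", as.character(utils::packageVersion("flymi")))
  )
  if (!is.null(cfg)) {
    fields <- vapply(
      names(unclass(cfg))[!vapply(unclass(cfg), is.null, logical(1))],
      function(nm) {
        sprintf(
          "# config %s: %s", nm,
          paste(format(cfg[[nm]], digits = 17, scientific = FALSE, trim = TRUE), collapse = ",")
        )
      },
      character(1)
    )
    hdr <- c(hdr, fields)
  }
  readr::write_lines(hdr, path)
  readr::write_csv(tibble::as_tibble(result), path, append = TRUE, col_names = TRUE)
  invisible(result)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  out <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  if ("alpha" %in% names(out)) out$alpha <- as.numeric(out$alpha)
  for (col in c("n_flies", "fly")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  hdr <- grep("^# config ", readr::read_lines(path, n_max = 50), value = TRUE)
  cfg <- NULL
  if (length(hdr) > 0) {
    kv <- regmatches(hdr, regexec("^# config ([^:]+): (.*)$", hdr))
    vals <- setNames(
      lapply(kv, function(m) {
        v <- strsplit(m[3], ",")[[1]]
        num <- suppressWarnings(as.numeric(v))
        if (all(!is.na(num) | v == "NA")) num else if (identical(v, "TRUE") || identical(v, "FALSE")) as.logical(v) else v
      }),
      vapply(kv, `[`, character(1), 2)
    )
    if (identical(vals$alpha, NA_real_) && length(vals$alpha) == 1 && !any(!is.na(out$alpha))) {
      # a pure no-inhibition config round-trips alpha = NULL
      vals$alpha <- NULL
    }
    cfg <- try(do.call(experiment_config, vals[names(vals) %in% names(formals(experiment_config))]), silent = TRUE)
    if (inherits(cfg, "try-error")) cfg <- NULL
  }
  attr(out, "config") <- cfg
  class(out) <- c("flymi_sweep", class(tibble::tibble()))
  out
}

#' Summarise a sweep
#'
#' `glance()` on a sweep reports the grid extent and the best cell.
#'
#' @param x a `flymi_sweep`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance flymi_sweep
#' @export
glance.flymi_sweep <- function(x, ...) {
  best <- x[which.max(x$mi_mean), ]
  tibble::tibble(
    n_cells = nrow(x),
    n_theta = length(unique(x$theta)),
    n_r = length(unique(x$r)),
    n_alpha = length(unique(x$alpha)),
    mi_max = best$mi_mean,
    theta_best = best$theta,
    r_best = best$r,
    alpha_best = best$alpha
  )
}
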