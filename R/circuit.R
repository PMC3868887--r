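#' Probability that a reached projection neuron fires
#'
#' Concentration-to-activity transfer function of the antennal lobe: a
#' projection neuron reached by an odor of concentration `c` fires with
#' probability `1 - exp(-beta * c)`. `beta` sets how steeply activity
#' saturates with concentration; the model default is 1.32.
#'
#' Strictly increasing in both arguments, zero at zero concentration, and
#' bounded below 1.
#'
#' @param concentration odor concentration(s), >= 0 (vectorised).
#' @param beta transfer steepness, > 0.
#' @return Activation probabilities in `[0, 1)`.
#' @examples
#' activation_probability(c(0.15, 0.75))
#' @export
activation_probability <- function(concentration, beta = 1.32) {
  if (!is.numeric(concentration) || any(is.na(concentration)) || any(concentration < 0)) {
    stop_invalid("`concentration` must be numeric and >= 0.")
  }
  check_scalar_number(beta, "beta", lower = 0, strict_lower = TRUE)
  1 - exp(-beta * concentration)
}

#' Probability that a Kenyon-cell spike is deleted by feedback inhibition
#'
#' Inhibition onto the mushroom body grows with the body's own activity in
#' the current trial, before inhibition: every pre-inhibition spike is
#' deleted independently with probability `exp(-alpha * activity)`. Larger
#' `alpha` therefore means *weaker* inhibition, and trials with little
#' Kenyon-cell activity are suppressed hardest.
#'
#' The activity argument of the exponential can be measured two ways:
#' * `"fraction"` (default): the fraction of active Kenyon cells,
#'   `n_active / n_kc`, in `[0, 1]` -- the mean of the binary population
#'   state. Requires `n_kc`.
#' * `"count"`: the raw number of active cells.
#'
#' @param n_active number of Kenyon cells active before inhibition
#'   (vectorised, >= 0).
#' @param alpha inhibition strength parameter, > 0 (model range 0.05-1.75).
#' @param activity `"fraction"` or `"count"`, see Details.
#' @param n_kc population size, required for `activity = "fraction"`.
#' @return Deletion probabilities in `(0, 1]`.
#' @examples
#' inhibition_probability(5, alpha = 0.9, activity = "count") # exp(-4.5)
#' inhibition_probability(5, alpha = 0.9, n_kc = 10) # exp(-0.45)
#' @export
inhibition_probability <- function(n_active, alpha,
                                   activity = c("fraction", "count"),
                                   n_kc = NULL) {
  activity <- match.arg(activity)
  if (!is.numeric(n_active) || any(is.na(n_active)) || any(n_active < 0)) {
    stop_invalid("`n_active` must be numeric and >= 0.")
  }
  check_scalar_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  chi <- if (activity == "fraction") {
    if (is.null(n_kc)) stop_invalid("`n_kc` is required when activity = \"fraction\".")
    check_count(n_kc, "n_kc")
    n_active / n_kc
  } else {
    n_active
  }
  exp(-alpha * chi)
}

#' Draw a random OPN-to-Kenyon-cell connectome
#'
#' One "fly": a binary connection matrix in which each projection neuron
#' synapses onto each Kenyon cell independently with probability `r` (the
#' connectivity rate, about 0.3 in flies).
#'
#' @param n_kc number of Kenyon cells (rows).
#' @param n_glomeruli number of projection neurons (columns). Default 50.
#' @param r connectivity rate, strictly inside `(0, 1)`.
#' @param seed optional integer for a local seeded draw.
#' @return A 0/1 matrix of class `flymi_connectome` with `n_kc` rows,
#'   `n_glomeruli` columns and attribute `r`.
#' @examples
#' cn <- sample_connectome(10, r = 0.3, seed = 1)
#' mean(cn)
#' @export
sample_connectome <- function(n_kc, n_glomeruli = 50, r, seed = NULL) {
  check_count(n_kc, "n_kc")
  check_count(n_glomeruli, "n_glomeruli")
  check_scalar_number(r, "r", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  local_seed(seed, {
    w <- matrix(
      as.integer(runif(n_kc * n_glomeruli) < r),
      nrow = n_kc, ncol = n_glomeruli
    )
    structure(w, r = r, class = c("flymi_connectome", class(w)))
  })
}

#' Write / read a connectome as a dense 0/1 CSV matrix
#'
#' Rows are Kenyon cells, columns are projection neurons; the connectivity
#' rate used to draw the matrix is stored in an `r` column-header comment-free
#' side channel (a `rate` column is not used; the rate is re-estimable from
#' the matrix and carried in the attribute on read only if supplied).
#'
#' @param connectome a `flymi_connectome` (any 0/1 matrix is accepted).
#' @param path file path.
#' @return `write_connectome()` returns the connectome invisibly;
#'   `read_connectome()` returns a `flymi_connectome`.
#' @export
write_connectome <- function(connectome, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(connectome)), .name_repair = "minimal")
  names(df) <- paste0("opn_", seq_len(ncol(df)))
  readr::write_csv(df, path)
  invisible(connectome)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  w <- as.matrix(df)
  dimnames(w) <- NULL
  storage.mode(w) <- "integer"
  if (!all(w %in% c(0L, 1L))) stop_invalid("connectome entries must be 0/1.")
  structure(w, r = mean(w), class = c("flymi_connectome", class(w)))
}

# Internal: sample antennal-lobe states for one odor given its reachable set.
# Returns an n_trials x n_glomeruli 0/1 matrix.
sample_al_matrix <- function(reachable, p_act, n_glomeruli, n_trials) {
  al <- matrix(0L, nrow = n_trials, ncol = n_glomeruli)
  k <- length(reachable)
  if (k > 0 && p_act > 0) {
    al[, reachable] <- as.integer(runif(n_trials * k) < p_act)
  }
  al
}

#' Sample antennal-lobe activity for an odor
#'
#' Each projection neuron reached by the odor fires independently with
#' probability [activation_probability()] at the odor's concentration;
#' unreached OPNs stay silent. Trial-to-trial variability of the antennal
#' lobe comes entirely from this sampling.
#'
#' @param odor a single row of a [draw_odor_panel()] panel (or any list with
#'   `reachable` and `concentration` fields).
#' @param beta transfer steepness of [activation_probability()].
#' @param n_trials number of independent trials to sample.
#' @param n_glomeruli universe size; defaults to the panel row's attribute
#'   when present, else 50.
#' @param seed optional integer for a local seeded draw.
#' @return An `n_trials` x `n_glomeruli` 0/1 matrix (rows = trials).
#' @export
sample_al_state <- function(odor, beta = 1.32, n_trials = 1,
                            n_glomeruli = attr(odor, "n_glomeruli") %||% 50,
                            seed = NULL) {
  reachable <- if (is.list(odor$reachable)) odor$reachable[[1]] else odor$reachable
  conc <- odor$concentration[1]
  p <- activation_probability(conc, beta)
  check_count(n_trials, "n_trials")
  local_seed(seed, sample_al_matrix(reachable, p, n_glomeruli, n_trials))
}

#' Threshold Kenyon-cell response to antennal-lobe activity
#'
#' Kenyon cells are binary integrate-and-fire units: cell `i` fires in a
#' trial iff its summed synaptic input (its connectome row dotted with the
#' antennal-lobe state) *strictly exceeds* the firing threshold `theta`.
#' Deterministic: consumes no randomness.
#'
#' @param connectome a `flymi_connectome` (Kenyon cells x OPNs).
#' @param al antennal-lobe 0/1 matrix, trials x OPNs (a vector is treated as
#'   one trial).
#' @param theta integer firing threshold, >= 1 (model range 1-20).
#' @return A trials x `n_kc` 0/1 matrix of Kenyon-cell states.
#' @examples
#' cn <- sample_connectome(4, 10, r = 0.5, seed = 1)
#' kc_response(cn, matrix(1, 1, 10), theta = 3)
#' @export
kc_response <- function(connectome, al, theta) {
  if (is.vector(al)) al <- matrix(al, nrow = 1)
  check_count(theta, "theta")
  if (ncol(al) != ncol(connectome)) {
    abort(
      sprintf(
        "antennal-lobe state has %d OPNs but the connectome expects %d.",
        ncol(al), ncol(connectome)
      ),
      class = "flymi_error_dimension"
    )
  }
  drive <- al %*% t(unclass(connectome))
  matrix(as.integer(drive > theta), nrow = nrow(al))
}

# Internal: one simultaneous pass of spike deletion over a trials x n_kc
# state matrix. The deletion probability of every spike in a trial is
# computed from that trial's pre-inhibition state.
apply_inhibition_matrix <- function(kc, alpha, activity) {
  n_kc <- ncol(kc)
  counts <- rowSums(kc)
  p_del <- inhibition_probability(counts, alpha, activity = activity, n_kc = n_kc)
  deleted <- matrix(runif(length(kc)) < p_del, nrow = nrow(kc)) # recycles by trial row
  out <- kc
  out[deleted] <- 0L
  out
}

#' Apply activity-dependent feedback inhibition to Kenyon-cell states
#'
#' Every spike in a trial is deleted independently with the trial's
#' [inhibition_probability()], computed from the pre-inhibition state in a
#' single simultaneous pass (no iteration to a fixed point). Silent cells
#' stay silent; the returned state is the final mushroom-body output.
#'
#' @param kc trials x `n_kc` 0/1 matrix (a vector is one trial).
#' @param alpha inhibition strength, > 0; larger is weaker.
#' @param activity `"fraction"` (default) or `"count"`; see
#'   [inhibition_probability()].
#' @param seed optional integer for a local seeded draw.
#' @return A 0/1 matrix of the same shape as `kc`.
#' @export
apply_inhibition <- function(kc, alpha, activity = c("fraction", "count"),
                             seed = NULL) {
  activity <- match.arg(activity)
  if (is.vector(kc)) kc <- matrix(kc, nrow = 1)
  check_scalar_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  local_seed(seed, apply_inhibition_matrix(kc, alpha, activity))
}

#' Simulate mushroom-body responses to one odor
#'
#' Composes the full feed-forward path for `n_trials` presentations of one
#' odor: antennal-lobe sampling ([sample_al_state()]), threshold Kenyon-cell
#' response ([kc_response()]), and -- when `alpha` is given -- feedback
#' inhibition ([apply_inhibition()]). `alpha = NULL` is the no-inhibition
#' condition.
#'
#' @inheritParams sample_al_state
#' @inheritParams kc_response
#' @param alpha inhibition strength, or `NULL` for no inhibition.
#' @param activity inhibition activity measure, see [inhibition_probability()].
#' @return A trials x `n_kc` 0/1 matrix of final Kenyon-cell states.
#' @examples
#' panel <- draw_odor_panel(2, 0.75, seed = 7)
#' cn <- sample_connectome(10, r = 0.3, seed = 8)
#' simulate_trial(panel[1, ], cn, theta = 5, n_trials = 3, seed = 9)
#' @export
simulate_trial <- function(odor, connectome, theta, beta = 1.32, alpha = NULL,
                           n_trials = 1, activity = c("fraction", "count"),
                           seed = NULL) {
  activity <- match.arg(activity)
  local_seed(seed, {
    al <- sample_al_state(odor, beta, n_trials, n_glomeruli = ncol(connectome))
    kc <- kc_response(connectome, al, theta)
    if (is.null(alpha)) kc else apply_inhibition_matrix(kc, alpha, activity)
  })
}
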