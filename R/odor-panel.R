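#' Draw the number of projection neurons an odor reaches
#'
#' An odor is a blend of chemicals and excites a random subset of the 50
#' antennal-lobe glomeruli (one projection neuron, OPN, per glomerulus). The
#' size of that subset is Gaussian with mean `mu` and variance `sigma2`,
#' rounded to the nearest integer and clamped to `[1, n_glomeruli]` so every
#' odor reaches at least one OPN. At the defaults (mean 35, variance 8,
#' sd ~ 2.83) clamping is vanishingly rare.
#'
#' @param n number of draws.
#' @param mu mean reached-OPN count (> 0). Default 35.
#' @param sigma2 variance of the reached-OPN count (> 0). Default 8.
#' @param n_glomeruli number of glomeruli / OPNs. Default 50.
#' @return Integer vector of length `n` with values in `[1, n_glomeruli]`.
#' @examples
#' withr::with_seed(1, draw_reached_count(5))
#' @export
draw_reached_count <- function(n = 1, mu = 35, sigma2 = 8, n_glomeruli = 50) {
  check_count(n, "n")
  check_scalar_number(mu, "mu", lower = 0, strict_lower = TRUE)
  check_scalar_number(sigma2, "sigma2", lower = 0, strict_lower = TRUE)
  check_count(n_glomeruli, "n_glomeruli")
  x <- round(rnorm(n, mean = mu, sd = sqrt(sigma2)))
  as.integer(pmin(pmax(x, 1), n_glomeruli))
}

#' Generate a panel of synthetic odors
#'
#' Draws `n_odors` equiprobable odors over a universe of `n_glomeruli`
#' projection neurons. Each odor reaches a uniformly chosen subset of OPNs
#' whose size comes from [draw_reached_count()], and all odors in a panel
#' share one concentration (an experiment presents many odors at the same
#' concentration).
#'
#' @param n_odors number of odors in the panel.
#' @param concentration shared odor concentration, in `(0, 1]`.
#' @param seed optional integer; when given the panel is drawn under a local
#'   seeded stream, leaving the caller's RNG untouched.
#' @inheritParams draw_reached_count
#' @return A tibble of class `flymi_panel` with one row per odor and columns
#'   `odor` (1-based label), `concentration`, `n_reached`, and `reachable`
#'   (list-column of sorted OPN indices in `1:n_glomeruli`). The universe
#'   size is carried in the `n_glomeruli` attribute.
#' @examples
#' panel <- draw_odor_panel(5, concentration = 0.15, seed = 42)
#' panel
#' @export
draw_odor_panel <- function(n_odors, concentration, mu = 35, sigma2 = 8,
                            n_glomeruli = 50, seed = NULL) {
  check_count(n_odors, "n_odors")
  check_scalar_number(concentration, "concentration",
    lower = 0, upper = 1, strict_lower = TRUE
  )
  local_seed(seed, {
    sizes <- draw_reached_count(n_odors, mu, sigma2, n_glomeruli)
    panel <- tibble::tibble(
      odor = seq_len(n_odors),
      concentration = concentration,
      n_reached = sizes,
      reachable = lapply(sizes, function(s) sort(sample.int(n_glomeruli, s)))
    )
    new_odor_panel(panel, n_glomeruli)
  })
}

new_odor_panel <- function(panel, n_glomeruli) {
  attr(panel, "n_glomeruli") <- as.integer(n_glomeruli)
  class(panel) <- c("flymi_panel", class(tibble::tibble()))
  validate_odor_panel(panel)
}

#' Validate an odor panel
#'
#' Checks the structural invariants of a panel: unique 1-based odor labels,
#' duplicate-free reachable sets within bounds, at least one reachable OPN
#' per odor, and a concentration in `(0, 1]` shared within the panel.
#'
#' @param panel a `flymi_panel` (or compatible data frame with attribute
#'   `n_glomeruli`).
#' @return `panel`, invisibly usable in a pipe; errors on violation.
#' @export
validate_odor_panel <- function(panel) {
  ng <- attr(panel, "n_glomeruli")
  if (is.null(ng)) stop_invalid("panel lacks an `n_glomeruli` attribute.")
  if (!identical(sort(panel$odor), seq_len(nrow(panel)))) {
    stop_invalid("odor labels must be unique and equal to 1..n_odors.")
  }
  if (any(panel$concentration <= 0 | panel$concentration > 1)) {
    stop_invalid("concentration must lie in (0, 1].")
  }
  ok <- vapply(panel$reachable, function(s) {
    length(s) >= 1 && !anyDuplicated(s) && all(s >= 1 & s <= ng) &&
      all(s == as.integer(s))
  }, logical(1))
  if (!all(ok)) {
    stop_invalid("each reachable set must be a duplicate-free subset of 1:n_glomeruli.")
  }
  if (!identical(as.integer(panel$n_reached), vapply(panel$reachable, length, integer(1)))) {
    stop_invalid("n_reached must equal the size of the reachable set.")
  }
  panel
}

#' Write / read an odor panel as CSV
#'
#' One row per odor: label, concentration, universe size and the reachable
#' OPN indices as a comma-separated (quoted) field, so panels can be archived
#' and experiments replayed.
#'
#' @param panel a `flymi_panel`.
#' @param path file path.
#' @return `write_odor_panel()` returns `panel` invisibly;
#'   `read_odor_panel()` returns the reconstructed `flymi_panel`.
#' @export
write_odor_panel <- function(panel, path) {
  validate_odor_panel(panel)
  out <- tibble::tibble(
    odor = panel$odor,
    concentration = panel$concentration,
    n_glomeruli = attr(panel, "n_glomeruli"),
    reachable_opns = vapply(panel$reachable, paste, character(1), collapse = ",")
  )
  readr::write_csv(out, path)
  invisible(panel)
}

#' @rdname write_odor_panel
#' @export
read_odor_panel <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(reachable_opns = readr::col_character()),
    progress = FALSE
  )
  reach <- lapply(strsplit(raw$reachable_opns, ","), function(s) as.integer(s))
  panel <- tibble::tibble(
    odor = as.integer(raw$odor),
    concentration = raw$concentration,
    n_reached = vapply(reach, length, integer(1)),
    reachable = reach
  )
  new_odor_panel(panel, raw$n_glomeruli[1])
}
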