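#' Define the ensemble's learners as base-quality strata
#'
#' Each "learner" in the ensemble is a stratum of read observations defined
#' by a bin of Phred base qualities. Quality strata have genuinely different
#' error profiles, which is exactly what the per-learner confusion matrices
#' of the EM model capture. Bins are half-open `[breaks[i], breaks[i+1])`
#' with the last bin open-ended, so the spec is exhaustive and
#' non-overlapping over all non-negative qualities.
#'
#' @param breaks Increasing integer vector of lower bin boundaries; the
#'   first element must be 0. Default `c(0, 10, 20, 30)` gives four
#'   learners: Q0-9, Q10-19, Q20-29, Q30+.
#' @return An object of class `learner_spec` with fields `breaks`,
#'   `n_learners`, and human-readable `labels`.
#' @examples
#' spec <- learner_spec()
#' assign_learner(37, 60, spec)  # 3 (0-based id of the Q30+ bin)
#' @export
learner_spec <- function(breaks = c(0L, 10L, 20L, 30L)) {
  breaks <- as.integer(breaks)
  if (length(breaks) < 1L || breaks[1] != 0L || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing and start at 0")
  L <- length(breaks)
  upper <- c(breaks[-1] - 1L, NA_integer_)
  labels <- ifelse(is.na(upper),
                   sprintf("Q%d+", breaks),
                   sprintf("Q%d-%d", breaks, upper))
  structure(list(breaks = breaks, n_learners = L, labels = labels),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat("learner_spec:", x$n_learners, "base-quality bins:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Assign an observation to a learner
#'
#' Pure deterministic mapping from a base quality to the 0-based id of the
#' unique quality bin containing it. Mapping quality is accepted for
#' interface symmetry with the read filters but does not influence the bin.
#'
#' @param base_quality Integer Phred base quality (vectorized), >= 0.
#' @param mapping_quality Integer Phred mapping quality (unused for binning).
#' @param spec A [learner_spec()].
#' @return Integer vector of 0-based learner ids in `[0, n_learners)`.
#' @export
assign_learner <- function(base_quality, mapping_quality = NA_integer_,
                           spec = learner_spec()) {
  if (any(base_quality < 0, na.rm = TRUE))
    stop("negative base quality")
  findInterval(base_quality, spec$breaks) - 1L
}
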