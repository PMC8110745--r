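## Mutation-rate estimation from accumulation time series.

#' Mutation accumulation time series
#'
#' A container for counts of mutations observed at sampled generations: one
#' `generation` column plus any number of count channels (conventionally
#' `fixed` for mutations at population frequency >= `f_fix`, `mean` for the
#' estimated mean number carried by a clone, `lr` for large
#' rearrangements, `spm` for raw point-mutation totals).
#'
#' @param generation Strictly increasing vector of non-negative generation
#'   numbers.
#' @param ... Named count channels, each the same length as `generation`,
#'   all values >= 0.
#' @param f_fix Fixation threshold on population frequency (default 0.96).
#' @param f_detect Detection threshold on population frequency (default
#'   0.04); variants at or below it are unobservable.
#' @return A data.frame of class `"mutation_series"` with attributes
#'   `f_fix` and `f_detect`.
#' @export
mutation_series <- function(generation, ..., f_fix = 0.96, f_detect = 0.04) {
  channels <- list(...)
  if (!is.numeric(generation) || any(!is.finite(generation)) ||
      any(generation < 0) || is.unsorted(generation, strictly = TRUE)) {
    stop("`generation` must be strictly increasing and non-negative.",
         call. = FALSE)
  }
  if (length(channels) == 0L || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("supply at least one named count channel.", call. = FALSE)
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch) || length(ch) != length(generation) ||
        any(!is.finite(ch)) || any(ch < 0)) {
      stop(sprintf("channel `%s` must be non-negative and match `generation` in length.",
                   nm), call. = FALSE)
    }
  }
  out <- data.frame(generation = generation, channels)
  attr(out, "f_fix") <- f_fix
  attr(out, "f_detect") <- f_detect
  class(out) <- c("mutation_series", "data.frame")
  out
}

#' Estimate a per-generation mutation rate from an accumulation series
#'
#' Least-squares slope of cumulative mutation counts against generation
#' number over a short-time window. The default regression is through the
#' origin: the ancestral strain at generation 0 is the zero-mutation
#' reference. A free intercept is available for robustness checks and for
#' fitting a post-changepoint segment, whose counts do not extrapolate to
#' zero at generation 0.
#'
#' @param generations Numeric vector of generation numbers.
#' @param counts Cumulative mutation counts at those generations.
#' @param max_generation Upper limit of the fit window (default 20000,
#'   excluding post-mutator samples in mutator lineages); use `Inf` to fit
#'   the full series.
#' @param through_origin Logical; regress through the origin (default TRUE).
#' @return An object of class `"rate_estimate"`: `rate` (mutations per
#'   generation), `stderr` (slope standard error), `intercept` (0 when
#'   through the origin), `window_max_generation`, `through_origin`,
#'   `n_points`.
#' @examples
#' g <- c(2000, 5000, 10000)
#' estimate_rate(g, 0.001 * g)$rate  # exactly 1e-3
#' @export
estimate_rate <- function(generations, counts, max_generation = 20000,
                          through_origin = TRUE) {
  if (!is.numeric(generations) || !is.numeric(counts) ||
      length(generations) != length(counts)) {
    stop("`generations` and `counts` must be numeric vectors of equal length.",
         call. = FALSE)
  }
  keep <- generations <= max_generation
  g <- generations[keep]
  cnt <- counts[keep]
  if (length(g) < 2L) {
    stop(sprintf("insufficient data: %d points at generation <= %g; need >= 2.",
                 length(g), max_generation), call. = FALSE)
  }
  fit <- if (through_origin) stats::lm(cnt ~ g + 0) else stats::lm(cnt ~ g)
  # summary.lm warns on an exactly linear series; the zero stderr is valid
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(list(rate = unname(sm["g", "Estimate"]),
                 stderr = unname(sm["g", "Std. Error"]),
                 intercept = if (through_origin) 0 else unname(sm["(Intercept)", "Estimate"]),
                 window_max_generation = max_generation,
                 through_origin = through_origin,
                 n_points = length(g)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Mutation rate: %.4g +/- %.2g per generation (%d points, generation <= %g%s)\n",
              x$rate, x$stderr, x$n_points, x$window_max_generation,
              if (x$through_origin) ", through origin" else ""))
  invisible(x)
}

#' Expected number of mutations observable in a random clone
#'
#' Treating each polymorphic site independently, a uniformly sampled clone
#' carries every fixed mutation plus each polymorphic mutation with
#' probability equal to its population frequency, so the expected count is
#' \eqn{n_{fixed} + \sum_i f_i}. This additive expectation reconstructs the
#' "mean number of mutations in a clone" channel from fixed counts and
#' polymorphic frequencies.
#'
#' @param n_fixed Number of fixed mutations (non-negative).
#' @param polymorphic_frequencies Numeric vector of population frequencies
#'   in (0, 1), one per polymorphic site; may be empty.
#' @return Expected mutation count in a random clone.
#' @examples
#' mean_mutations_in_clone(10)                 # 10
#' mean_mutations_in_clone(0, c(0.5, 0.5))     # 1
#' @export
mean_mutations_in_clone <- function(n_fixed, polymorphic_frequencies = numeric(0)) {
  if (!is.numeric(n_fixed) || length(n_fixed) != 1L || n_fixed < 0) {
    stop("`n_fixed` must be a single non-negative number.", call. = FALSE)
  }
  f <- polymorphic_frequencies
  if (length(f) > 0 && (!is.numeric(f) || any(!is.finite(f)) ||
                        any(f <= 0) || any(f >= 1))) {
    stop("polymorphic frequencies must lie strictly within (0, 1).",
         call. = FALSE)
  }
  n_fixed + sum(f)
}

#' Split a time series at a mutator changepoint
#'
#' Partitions the sampled generations at the changepoint so mutation rates
#' can be fitted separately before and after a mutator genotype becomes
#' dominant: the pre-series holds samples at generations <= the
#' changepoint, the post-series those strictly after it.
#'
#' @param series A [mutation_series()] (or data.frame with a `generation`
#'   column).
#' @param changepoint_generation Changepoint, strictly inside the sampled
#'   generation span.
#' @return A list with elements `pre` and `post`, each the corresponding
#'   subset of `series`.
#' @export
split_by_mutator <- function(series, changepoint_generation) {
  if (!is.data.frame(series) || !"generation" %in% names(series)) {
    stop("`series` must be a data.frame with a `generation` column.",
         call. = FALSE)
  }
  g <- series$generation
  if (changepoint_generation < min(g) || changepoint_generation >= max(g)) {
    stop(sprintf("changepoint %g outside the sampled span [%g, %g).",
                 changepoint_generation, min(g), max(g)), call. = FALSE)
  }
  pre <- series[g <= changepoint_generation, , drop = FALSE]
  post <- series[g > changepoint_generation, , drop = FALSE]
  rownames(pre) <- rownames(post) <- NULL
  list(pre = pre, post = post)
}
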