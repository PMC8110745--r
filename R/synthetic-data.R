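## Study-shaped synthetic inputs: LTEE-like SNP/LR time series and
## CNV-like length catalogs with detection censoring.

#' Detection model for short mutation lengths
#'
#' Sequencing and optical pipelines under-count short rearrangements. The
#' hard mode drops every event below the detection floor; the soft mode
#' detects an event of length `l < floor` with probability
#' \eqn{(l/\mathrm{floor})^\gamma} (and always detects events at or above
#' the floor). `gamma = 0` makes the soft mode detect everything.
#'
#' @param floor Minimum reliably detected length in bp (default 5e3, the
#'   reliability limit for bacterial rearrangement calls).
#' @param mode `"hard"` or `"soft"`.
#' @param gamma Soft-mode exponent, >= 0 (default 1).
#' @return An object of class `"detection_model"`.
#' @export
detection_model <- function(floor = 5e3, mode = c("hard", "soft"), gamma = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(floor) || length(floor) != 1L || floor < 1) {
    stop("`floor` must be a single length >= 1 bp.", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    stop("`gamma` must be a single value >= 0.", call. = FALSE)
  }
  structure(list(floor = floor, mode = mode, gamma = gamma),
            class = "detection_model")
}

## apply censoring; returns a logical keep-mask (never alters lengths)
.detect_mask <- function(lengths, detection) {
  stopifnot(inherits(detection, "detection_model"))
  if (detection$mode == "hard") {
    lengths >= detection$floor
  } else {
    p <- pmin(1, (lengths / detection$floor)^detection$gamma)
    stats::runif(length(lengths)) <= p
  }
}

#' Synthetic LTEE-style mutation time series
#'
#' Simulates a lineage with [simulate_flight()] and dresses each point
#' mutation with a population frequency so that the fixed / polymorphic /
#' clone-mean channels of an evolution-experiment series can be populated.
#' A mutation is observable only if its frequency exceeds the detection
#' threshold (4% by default); it counts as fixed at or above the fixation
#' threshold (96% by default) and as polymorphic strictly in between. The
#' clone-mean channel is [mean_mutations_in_clone()] of the fixed count and
#' the polymorphic frequencies.
#'
#' The frequency model is pluggable and defaults to uniform on (0, 1); the
#' analyses here rely only on the threshold classification, not on the
#' shape of the frequency distribution.
#'
#' @param config A [flight_config()].
#' @param sample_generations Generations at which the series is sampled.
#' @param seed Optional integer seed.
#' @param freq_fun Function `n -> n` frequencies in \[0, 1\] assigned to
#'   point mutations (default [stats::runif]).
#' @param f_fix,f_detect Classification thresholds (defaults 0.96, 0.04).
#' @return A list: `series` (a [mutation_series()] with `fixed`, `mean`,
#'   `lr` channels), `polymorphic` (per-sample list of polymorphic
#'   frequencies), `catalog` (the simulated catalog, point mutations
#'   annotated with `frequency`).
#' @export
synth_ltee_timeseries <- function(config, sample_generations, seed = NULL,
                                  freq_fun = stats::runif,
                                  f_fix = 0.96, f_detect = 0.04) {
  with_seed(seed, {
    n_gen <- max(sample_generations)
    sim <- simulate_flight(config, n_gen, sample_generations)
    catalog <- sim$catalog
    is_spm <- catalog$type == "SPM"
    f <- rep(NA_real_, nrow(catalog))
    f[is_spm] <- freq_fun(sum(is_spm))
    if (any(!is.na(f) & (f < 0 | f > 1))) {
      stop("`freq_fun` must return frequencies in [0, 1].", call. = FALSE)
    }
    catalog$frequency <- f
    fixed_flag <- is_spm & f >= f_fix
    poly_flag <- is_spm & f > f_detect & f < f_fix
    sg <- sort(unique(as.integer(sample_generations)))
    fixed_counts <- vapply(sg, function(s) {
      sum(fixed_flag & catalog$generation <= s)
    }, numeric(1))
    polymorphic <- lapply(sg, function(s) {
      catalog$frequency[poly_flag & catalog$generation <= s]
    })
    names(polymorphic) <- as.character(sg)
    mean_counts <- mapply(mean_mutations_in_clone, fixed_counts, polymorphic)
    series <- mutation_series(
      generation = sg,
      fixed = fixed_counts,
      mean = unname(mean_counts),
      lr = sim$series$lr,
      f_fix = f_fix, f_detect = f_detect
    )
    list(series = series, polymorphic = polymorphic, catalog = catalog)
  })
}

#' Synthetic CNV-style length catalog
#'
#' Draws rearrangement lengths from a stable Levy law truncated to the
#' observable range (by rejection, preserving the conditional law), then
#' applies detection censoring. Both the uncensored and the observed
#' catalogs are returned so censoring effects can be tested against the
#' generating truth.
#'
#' @param model A [stable_levy_model()]; the CNV study conditions are
#'   `nu = 3/2`, `alpha = 1e-5`.
#' @param n Number of true events to draw (>= 1).
#' @param bounds Length-2 numeric `(l_min, l_max)` in bp with
#'   `1 <= l_min < l_max`; the default spans the observed CNV range, 10 bp
#'   to 2.4e8 bp.
#' @param detection A [detection_model()].
#' @param seed Optional integer seed.
#' @return A list: `true` (integer lengths of all `n` events), `observed`
#'   (lengths surviving detection), `detection` (the model used).
#' @export
synth_cnv_catalog <- function(model, n, bounds = c(10, 2.4e8),
                              detection = detection_model(), seed = NULL) {
  stopifnot(inherits(model, "stable_levy_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single integer >= 1.", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.numeric(bounds) || length(bounds) != 2L || bounds[1] < 1 ||
      bounds[1] >= bounds[2]) {
    stop("`bounds` must be c(l_min, l_max) with 1 <= l_min < l_max.",
         call. = FALSE)
  }
  ## the truncation must retain some mass or rejection cannot terminate
  keep_prob <- levy_survival(model$nu, model$alpha * bounds[1]) -
    levy_survival(model$nu, model$alpha * bounds[2])
  if (keep_prob < 1e-12) {
    stop(sprintf("infeasible bounds: the Levy model puts ~%g mass in [%g, %g].",
                 keep_prob, bounds[1], bounds[2]), call. = FALSE)
  }
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      m <- max(ceiling((n - length(out)) / max(keep_prob, 0.05)), 64L)
      cand <- pmax(1, ceiling(levy_sample(model, m)))
      out <- c(out, cand[cand >= bounds[1] & cand <= bounds[2]])
    }
    true_lengths <- as.integer(out[seq_len(n)])
    observed <- true_lengths[.detect_mask(true_lengths, detection)]
    list(true = true_lengths, observed = observed, detection = detection)
  })
}
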