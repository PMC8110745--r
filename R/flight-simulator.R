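## Forward simulation of mutation accumulation as a Levy flight:
## X_{i+1} = X_i + delta_i, with Poisson point mutations (length 1) and
## Poisson large rearrangements with stable-Levy lengths.

#' Configuration of the Levy-flight mutation simulator
#'
#' @param p_spm Single-point-mutation rate per generation (>= 0).
#' @param p_lr Large-rearrangement rate per generation (>= 0).
#' @param lr_model A [stable_levy_model()] for rearrangement lengths.
#' @param genome_length Genome size L in bp (default 5e6, the bacterial
#'   chromosome); rearrangement lengths are capped at L by rejection.
#' @param mutator_generation Optional generation after which a mutator
#'   genotype multiplies the point-mutation rate; `NULL` disables it.
#' @param mutator_factor Multiplier applied to `p_spm` for generations
#'   after the changepoint (default 100). Large rearrangements are
#'   unaffected: the two processes are mechanistically distinct.
#' @return An object of class `"flight_config"`.
#' @seealso [bacterial_preset()], [germline_preset()], [simulate_flight()]
#' @export
flight_config <- function(p_spm, p_lr, lr_model,
                          genome_length = 5e6,
                          mutator_generation = NULL,
                          mutator_factor = 100) {
  if (!is.numeric(p_spm) || length(p_spm) != 1L || p_spm < 0 ||
      !is.numeric(p_lr) || length(p_lr) != 1L || p_lr < 0) {
    stop("`p_spm` and `p_lr` must be single non-negative rates.", call. = FALSE)
  }
  if (!inherits(lr_model, "stable_levy_model")) {
    stop("`lr_model` must be a stable_levy_model.", call. = FALSE)
  }
  if (!is.numeric(genome_length) || length(genome_length) != 1L ||
      genome_length < 1) {
    stop("`genome_length` must be a single length >= 1 bp.", call. = FALSE)
  }
  if (!is.null(mutator_generation) &&
      (!is.numeric(mutator_generation) || length(mutator_generation) != 1L ||
       mutator_generation < 0)) {
    stop("`mutator_generation` must be NULL or a single non-negative generation.",
         call. = FALSE)
  }
  if (!is.numeric(mutator_factor) || length(mutator_factor) != 1L ||
      mutator_factor <= 0) {
    stop("`mutator_factor` must be a single positive multiplier.", call. = FALSE)
  }
  structure(list(p_spm = p_spm, p_lr = p_lr, lr_model = lr_model,
                 genome_length = genome_length,
                 mutator_generation = mutator_generation,
                 mutator_factor = mutator_factor),
            class = "flight_config")
}

#' @export
print.flight_config <- function(x, ...) {
  cat(sprintf("Levy-flight config: p_spm = %g, p_lr = %g per generation\n",
              x$p_spm, x$p_lr))
  cat(sprintf("  rearrangement lengths: nu = %g, alpha = %g /bp, capped at L = %g bp\n",
              x$lr_model$nu, x$lr_model$alpha, x$genome_length))
  if (!is.null(x$mutator_generation)) {
    cat(sprintf("  mutator: %g-fold p_spm after generation %g\n",
                x$mutator_factor, x$mutator_generation))
  }
  invisible(x)
}

#' Default bacterial lineage configuration
#'
#' The LTEE-like study conditions for an *E. coli* lineage: point mutations
#' at 1.8e-3 per generation, large rearrangements at 5e-4 per generation
#' (a lower bound; short rearrangements evade detection), rearrangement
#' lengths from a stable Levy law with index 1/2 and scale 1e-4 per bp, a
#' 5 Mbp genome, and a mutator genotype raising the point-mutation rate
#' 100-fold after generation 27,000.
#'
#' @return A [flight_config()].
#' @export
bacterial_preset <- function() {
  flight_config(p_spm = 1.8e-3, p_lr = 5e-4,
                lr_model = stable_levy_model(nu = 1 / 2, alpha = 1e-4),
                genome_length = 5e6,
                mutator_generation = 27000,
                mutator_factor = 100)
}

#' Human germline per-birth configuration
#'
#' Mutation rates per organism generation (birth) in human germline cells:
#' about 60 single-nucleotide variants and about 10 rearrangement events
#' per birth, with rearrangement (CNV-like) lengths following a stable
#' Levy law with index 3/2 and scale 1e-5 per bp, bounded by the largest
#' observed CNV span of 2.4e8 bp. The time unit of the returned
#' configuration is one birth, not one cell generation.
#'
#' @return A [flight_config()] with no mutator changepoint.
#' @export
germline_preset <- function() {
  flight_config(p_spm = 60, p_lr = 10,
                lr_model = stable_levy_model(nu = 3 / 2, alpha = 1e-5),
                genome_length = 2.4e8,
                mutator_generation = NULL)
}

## rearrangement lengths: continuous stable draws rounded up to >= 1 bp,
## re-drawn while they exceed the genome (rejection preserves the
## conditional law under the physical cap)
.draw_lr_lengths <- function(model, n, genome_length) {
  if (n == 0L) return(integer(0))
  out <- numeric(0)
  while (length(out) < n) {
    cand <- pmax(1, ceiling(levy_sample(model, max(2L * (n - length(out)), 16L))))
    out <- c(out, cand[cand <= genome_length])
  }
  out[seq_len(n)]
}

#' Simulate mutation accumulation along a lineage
#'
#' Forward-simulates the mutation Markov chain \eqn{X_{i+1} = X_i + \delta_i}
#' in discrete generations: per generation, the number of point mutations
#' is Poisson with the (possibly mutator-scaled) SPM rate and the number of
#' large rearrangements is Poisson with `p_lr`; each rearrangement length
#' is drawn from the configured stable Levy law, rounded up to an integer
#' number of bp and capped at the genome length by rejection. The mutator
#' changepoint scales the SPM rate only, for generations after
#' `mutator_generation`.
#'
#' @param config A [flight_config()].
#' @param n_generations Number of generations to simulate (>= 1).
#' @param sample_generations Generations at which cumulative counts are
#'   recorded; defaults to about 50 evenly spaced samples. Values must lie
#'   in \[0, n_generations\].
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `catalog` (data.frame: `generation`, `type` in
#'   `"SPM"`/`"LR"`, `length_bp`; SPM events have length 1) and `series`
#'   (a [mutation_series()] with cumulative `spm` and `lr` channels).
#' @examples
#' sim <- simulate_flight(bacterial_preset(), 5000,
#'                        sample_generations = c(1000, 5000), seed = 1)
#' @export
simulate_flight <- function(config, n_generations,
                            sample_generations = NULL, seed = NULL) {
  if (!inherits(config, "flight_config")) {
    stop("`config` must be a flight_config.", call. = FALSE)
  }
  if (!is.numeric(n_generations) || length(n_generations) != 1L ||
      n_generations < 1) {
    stop("`n_generations` must be a single integer >= 1.", call. = FALSE)
  }
  n_generations <- as.integer(n_generations)
  if (is.null(sample_generations)) {
    by <- max(1L, n_generations %/% 50L)
    sample_generations <- unique(c(seq(by, n_generations, by = by), n_generations))
  }
  sample_generations <- sort(unique(as.integer(sample_generations)))
  if (any(sample_generations < 0) || any(sample_generations > n_generations)) {
    stop("`sample_generations` must lie within [0, n_generations].",
         call. = FALSE)
  }
  with_seed(seed, {
    gen <- seq_len(n_generations)
    spm_rate <- rep(config$p_spm, n_generations)
    if (!is.null(config$mutator_generation)) {
      spm_rate[gen > config$mutator_generation] <-
        config$p_spm * config$mutator_factor
    }
    n_spm <- stats::rpois(n_generations, spm_rate)
    n_lr <- stats::rpois(n_generations, config$p_lr)
    lr_gen <- rep(gen, n_lr)
    lr_len <- .draw_lr_lengths(config$lr_model, length(lr_gen),
                               config$genome_length)
    catalog <- data.frame(
      generation = c(rep(gen, n_spm), lr_gen),
      type = c(rep("SPM", sum(n_spm)), rep("LR", length(lr_gen))),
      length_bp = c(rep(1L, sum(n_spm)), as.integer(lr_len))
    )
    catalog <- catalog[order(catalog$generation, catalog$type), , drop = FALSE]
    rownames(catalog) <- NULL
    cum_spm <- cumsum(n_spm)
    cum_lr <- cumsum(n_lr)
    at <- function(cum, g) ifelse(g == 0L, 0, cum[pmax(g, 1L)])
    series <- mutation_series(
      generation = sample_generations,
      spm = at(cum_spm, sample_generations),
      lr = at(cum_lr, sample_generations)
    )
    list(catalog = catalog, series = series)
  })
}
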