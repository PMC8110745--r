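# Frozen reference values for the standardized stable density L_nu and its
# survival function, computed with an independent stable-distribution
# implementation (scipy.stats.levy_stable: twice the symmetric stable pdf/sf
# with characteristic function exp(-|t|^nu)) before the engine was written.
ref_levy <- list(
  y = c(0, 0.5, 1, 2, 5, 10, 100),
  pdf = list(
    `0.5` = c(1.273239545, 0.3415248035, 0.1722142938, 0.0782857161,
              0.0246973608, 0.009744510767, 0.0003681074528),
    `1.5` = c(0.5747055029, 0.5245936807, 0.4040763192, 0.1690792463,
              0.0142234721, 0.00209555205, 6.00327207e-06)
  ),
  surv = list(
    `0.5` = c(1, 0.6626191, 0.5425606254, 0.4278563246, 0.2990338144,
              0.2225707794, 0.07667179947),
    `1.5` = c(1, 0.721191547, 0.4873159512, 0.2100796593, 0.04133817428,
              0.0132796184, 0.0003995797729)
  )
)

# log-log OLS slope helper used across tail checks
loglog_slope <- function(x, y) unname(coef(lm(log10(y) ~ log10(x)))[2])
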