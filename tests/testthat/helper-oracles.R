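# Independent oracles used across the suite. These re-derive quantities
# by brute force (grid search / grid scan / plain arithmetic) and are
# deliberately kept free of the package's own solvers.

# brute-force SSE minimiser over a (top, log_ec50, hillslope) grid
grid_search_4pl <- function(conc, y,
                            top_grid = seq(85, 115, by = 1),
                            logec50_grid = NULL,
                            hill_grid = seq(0.5, 4, by = 0.05)) {
  if (is.null(logec50_grid)) {
    logec50_grid <- seq(min(log10(conc)), max(log10(conc)),
                        length.out = 121)
  }
  best <- list(sse = Inf)
  for (top in top_grid) {
    for (hill in hill_grid) {
      # vectorised over the logec50 grid: residual matrix
      pred <- sapply(logec50_grid, function(le) {
        top / (1 + 10^((le - log10(conc)) * hill))
      })
      sse <- colSums((y - pred)^2)
      i <- which.min(sse)
      if (sse[i] < best$sse) {
        best <- list(sse = sse[i], top = top, log_ec50 = logec50_grid[i],
                     hillslope = hill)
      }
    }
  }
  best
}

# IA ECx by recursive grid-scan refinement of the forward effect curve
grid_scan_ia_ecx <- function(curves, design, x, depth = 10L,
                             npoints = 40L) {
  target <- x / 100
  ec50s <- vapply(curves[design$component_ids],
                  function(crv) 10^crv$coefficients[["log_ec50"]],
                  numeric(1))
  lo <- log10(min(ec50s)) - 6
  hi <- log10(max(ec50s)) + 4
  for (d in seq_len(depth)) {
    grid <- seq(lo, hi, length.out = npoints)
    eff <- ia_effect(curves, design, 10^grid)
    i <- findInterval(target, eff)
    if (i < 1L || i >= npoints) stop("grid scan failed to bracket")
    lo <- grid[i]
    hi <- grid[i + 1L]
  }
  10^((lo + hi) / 2)
}

# random valid single-compound curve, drawn from the caller's RNG stream
random_curve <- function(ec50_range = c(0.01, 10),
                         hill_range = c(0.5, 4)) {
  llog4(top = 100,
        ec50 = 10^stats::runif(1, log10(ec50_range[1]),
                               log10(ec50_range[2])),
        hillslope = stats::runif(1, hill_range[1], hill_range[2]))
}

# noiseless 4PL points spanning the effect range of a given truth
noiseless_points <- function(top, ec50, hillslope, n = 7) {
  crv <- llog4(top = top, ec50 = ec50, hillslope = hillslope)
  conc <- ecx(crv, seq(5, 95, length.out = n))
  data.frame(concentration = conc, inhibition = effect_at(crv, conc))
}
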