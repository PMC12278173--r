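# Independent brute-force oracle for the piecewise rules: classifies the
# ratio u = x/r by explicit interval membership, written directly from the
# band descriptions and kept free of the engine's tolerance machinery.
# Intended for exact grid points, so plain comparisons suffice.
oracle_points <- function(u, category, tau = 0) {
  stopifnot(u >= 0)
  if (category == "green") {
    if (u >= 1) 2L else if (u > 0) 1L else 0L
  } else if (category == "yellow") {
    if (u >= 1 - tau && u <= 1 + tau) 2L
    else if (u == 0 || u >= 2) 0L
    else 1L
  } else if (category == "red") {
    if (u <= 1) 2L else if (u < 2) 1L else 0L
  } else {
    stop("oracle: unknown category ", category)
  }
}

engine_points <- function(x, r, category, tau = 0) {
  switch(category,
         green = score_green(x, r),
         yellow = score_yellow(x, r, tolerance = tau),
         red = score_red(x, r))
}
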