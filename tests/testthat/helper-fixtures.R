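# Shared fixtures: small bundles keep the pipeline runs fast while
# preserving the full age range and both sexes.

small_bundle <- function(seed = 42L, n_diseases = 4L, ...) {
  generate_inputs(synthetic_config(seed = seed, n_diseases = n_diseases, ...))
}

# cache the default small bundle across test files
.fixture_env <- new.env(parent = emptyenv())
get_small_bundle <- function() {
  if (is.null(.fixture_env$b)) .fixture_env$b <- small_bundle()
  .fixture_env$b
}

# intensity matrix of the four-state disease model, for oracle comparisons
intensity_matrix <- function(i, r, f, m) {
  matrix(c(-(i + m), r,              0, 0,
           i,        -(r + f + m),   0, 0,
           0,        f,              0, 0,
           m,        m,              0, 0),
         4, 4, byrow = TRUE,
         dimnames = rep(list(c("S", "C", "D_dis", "D_other")), 2))
}

# fine-step forward-Euler oracle for one annual cycle
euler_step <- function(state, i, r, f, m, n_sub = 1024L) {
  dt <- 1 / n_sub
  s <- state[["S"]]; c <- state[["C"]]
  dd <- state[["D_dis"]]; do <- state[["D_other"]]
  for (k in seq_len(n_sub)) {
    ds <- (-(i + m) * s + r * c) * dt
    dc <- (i * s - (r + f + m) * c) * dt
    dd <- dd + f * c * dt
    do <- do + m * (s + c) * dt
    s <- s + ds; c <- c + dc
  }
  c(S = s, C = c, D_dis = dd, D_other = do)
}

# Riemann-sum PIF oracle: midpoint rule on a fixed fine grid
riemann_pif <- function(rr, p, p_star, bounds, n = 1e5) {
  h <- (bounds[2] - bounds[1]) / n
  x <- bounds[1] + (seq_len(n) - 0.5) * h
  num <- sum(rr_eval(rr, x) * d_exposure(x, p)) * h
  num_s <- sum(rr_eval(rr, x) * d_exposure(x, p_star)) * h
  (num - num_s) / num
}
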