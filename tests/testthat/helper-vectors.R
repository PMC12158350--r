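# Shared fixtures: seeded random vector draws and small brute-force
# oracles kept independent of the package's own code paths.

random_polar_pairs <- function(n, seed, r_max = 10) {
  set.seed(seed)
  data.frame(r1 = runif(n, 0, r_max), theta1 = runif(n, 0, 2 * pi),
             r2 = runif(n, 0, r_max), theta2 = runif(n, 0, 2 * pi))
}

# Cartesian-addition oracle, written directly rather than through
# vector_sum(), so geometry tests have an independent reference.
cartesian_sum_oracle <- function(r1, th1, r2, th2) {
  x <- r1 * cos(th1) + r2 * cos(th2)
  y <- r1 * sin(th1) + r2 * sin(th2)
  list(r = sqrt(x^2 + y^2),
       theta = if (x == 0 && y == 0) 0 else (atan2(y, x) %% (2 * pi)))
}

# All thermometer codes of length m (popcounts 0..m).
all_thermometer_codes <- function(m) {
  lapply(0:m, function(p) as.integer(seq_len(m) <= p))
}
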