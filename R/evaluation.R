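#' Configuration for a coded-addition experiment
#'
#' Bundles every knob of the error-statistics experiments. The defaults
#' are the reference study conditions: 200 vector pairs with magnitudes
#' uniform on `[0, 10]` and angles uniform on `[0, 2*pi)`, scaling
#' factor `k = 20` (200-bit codes), 360 sampling points, no noise,
#' refined peak mode, wrapped angle errors reported in degrees.
#'
#' For multi-input runs (`n_inputs > 2`) the encoder ceiling is scaled
#' to the worst-case running sum, `range_max = magnitude_range[2] *
#' n_inputs`, so cascaded half-adder folds cannot overflow.
#'
#' @param n_pairs Number of trials.
#' @param magnitude_range Two-element range for magnitude draws.
#' @param k Encoder scaling factor (bits per unit value).
#' @param n_samples Sampling points per sinusoid.
#' @param seed Integer RNG seed; every draw in the experiment flows
#'   from it.
#' @param noise_sigma Standard deviation of Gaussian noise added to
#'   each sinusoid sample before encoding (0 = clean).
#' @param n_inputs Vectors summed per trial (2 = pairwise reference
#'   experiment; 20 / 30 for the scaling runs).
#' @param peak_mode `"refined"` or `"argmax"`, see [locate_peak()].
#' @param angle_metric `"wrapped"` (circular distance) or
#'   `"unwrapped"` (plain absolute difference of normalized angles,
#'   exposing the 0/360 boundary artifact).
#' @param angle_units `"degrees"` or `"radians"` for reported angle
#'   errors.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_pairs = 200L,
                              magnitude_range = c(0, 10),
                              k = 20L,
                              n_samples = 360L,
                              seed = 1L,
                              noise_sigma = 0,
                              n_inputs = 2L,
                              peak_mode = c("refined", "argmax"),
                              angle_metric = c("wrapped", "unwrapped"),
                              angle_units = c("degrees", "radians")) {
  stopifnot(n_pairs >= 1L, length(magnitude_range) == 2L,
            magnitude_range[1] >= 0, diff(magnitude_range) >= 0,
            noise_sigma >= 0, n_inputs >= 2L)
  structure(list(n_pairs = as.integer(n_pairs),
                 magnitude_range = as.numeric(magnitude_range),
                 k = as.integer(k),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 noise_sigma = as.numeric(noise_sigma),
                 n_inputs = as.integer(n_inputs),
                 peak_mode = match.arg(peak_mode),
                 angle_metric = match.arg(angle_metric),
                 angle_units = match.arg(angle_units)),
            class = "experiment_config")
}

#' Draw the random vector batch for an experiment
#'
#' Seeded, reproducible draws: magnitudes uniform on
#' `cfg$magnitude_range`, angles uniform on `[0, 2*pi)`, independent
#' across trials and inputs. The same seed always yields the identical
#' batch.
#'
#' @param cfg An [experiment_config()].
#' @return List with matrices `r` and `theta`, each
#'   `n_pairs x n_inputs`.
#' @export
generate_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  n <- cfg$n_pairs * cfg$n_inputs
  r <- matrix(stats::runif(n, cfg$magnitude_range[1], cfg$magnitude_range[2]),
              nrow = cfg$n_pairs, ncol = cfg$n_inputs)
  theta <- matrix(stats::runif(n, 0, 2 * pi),
                  nrow = cfg$n_pairs, ncol = cfg$n_inputs)
  list(r = r, theta = theta)
}

#' Perturb a sampled sinusoid with Gaussian noise
#'
#' Adds independent zero-mean Gaussian noise of standard deviation
#' `sigma` to every sample, modelling pre-encoding input corruption.
#' `sigma = 0` returns the signal unchanged. Draws come from the
#' current RNG stream unless `seed` is given.
#'
#' @param s A `sampled_sinusoid`.
#' @param sigma Noise standard deviation, `>= 0`.
#' @param seed Optional seed set before drawing.
#' @return A `sampled_sinusoid`.
#' @export
add_noise <- function(s, sigma, seed = NULL) {
  stopifnot(inherits(s, "sampled_sinusoid"), sigma >= 0)
  if (sigma == 0) return(s)
  if (!is.null(seed)) set.seed(seed)
  new_sampled_sinusoid(s$values + stats::rnorm(length(s$values), 0, sigma),
                       s$config)
}

#' Root-mean-square error
#'
#' `sqrt(mean((pred - true)^2))`. With `angular = TRUE` the inputs are
#' treated as angles in radians and differences are wrapped circularly
#' (or left unwrapped with `wrap = FALSE`) before squaring.
#'
#' @param pred,true Numeric vectors of equal length (`n >= 1`).
#' @param angular Treat inputs as angles.
#' @param wrap Wrap angular differences circularly.
#' @return The RMSE (radians if `angular`).
#' @examples
#' rmse(c(0, 3), c(0, 0)) # 2.1213
#' @export
rmse <- function(pred, true, angular = FALSE, wrap = TRUE) {
  if (length(pred) != length(true)) stop("length mismatch")
  if (length(pred) < 1L) stop("need at least one element")
  d <- if (angular) angular_error(pred, true, wrap = wrap) else pred - true
  sqrt(mean(d^2))
}

#' Run a coded-addition error experiment
#'
#' For each trial, draws `n_inputs` random vectors, pushes them through
#' the full circuit (sample, optional noise, thermometer-encode,
#' half-adder combine or fold, peak/amplitude decode) and compares the
#' decoded sum against the exact closed-form vector sum. Per-trial
#' errors and the aggregate statistics (mean absolute errors and RMSEs
#' for magnitude and angle) are returned; aggregates are recomputed
#' from the per-trial records and verified internally on every run.
#'
#' @param cfg An [experiment_config()].
#' @return An `error_report`: `trials` (data frame with the inputs,
#'   true and decoded sums, `mag_err`, `ang_err` in `cfg$angle_units`,
#'   `clip_count`), `summary` (named list with
#'   `mean_abs_magnitude_error`, `mean_abs_angle_error`,
#'   `magnitude_rmse`, `angle_rmse`, `clip_count`, `runtime` seconds)
#'   and `config`.
#' @examples
#' \donttest{
#' rep <- run_experiment(experiment_config(n_pairs = 20, seed = 7))
#' rep$summary$magnitude_rmse
#' }
#' @export
run_experiment <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  batch <- generate_pairs(cfg)   # also seeds the stream for noise draws
  sampling <- sampling_config(cfg$n_samples)
  range_max <- cfg$magnitude_range[2] *
    (if (cfg$n_inputs > 2L) cfg$n_inputs else 1L)
  encoder <- encoder_config(range_max = range_max, k = cfg$k)

  n <- cfg$n_pairs
  r_true <- theta_true <- r_dec <- theta_dec <- numeric(n)
  clips <- integer(n)
  for (t in seq_len(n)) {
    vs <- lapply(seq_len(cfg$n_inputs), function(j)
      polar_vector(batch$r[t, j], batch$theta[t, j]))
    truth <- Reduce(vector_sum, vs)
    signals <- lapply(vs, function(v) {
      s <- sample_sinusoid(v, sampling)
      if (cfg$noise_sigma > 0) s <- add_noise(s, cfg$noise_sigma)
      encode_signal(s, encoder, amplitude = v$r)
    })
    dec <- if (cfg$n_inputs == 2L) {
      decode_signal(combine_signals(signals[[1L]], signals[[2L]]),
                    peak_mode = cfg$peak_mode)
    } else {
      decode_signal(fold_signals(signals), peak_mode = cfg$peak_mode)
    }
    r_true[t] <- truth$r
    theta_true[t] <- truth$theta
    r_dec[t] <- dec$r
    theta_dec[t] <- dec$theta
    clips[t] <- dec$clip_count
  }

  ang_scale <- if (cfg$angle_units == "degrees") 180 / pi else 1
  wrap <- cfg$angle_metric == "wrapped"
  ang_err <- angular_error(theta_dec, theta_true, wrap = wrap) * ang_scale
  trials <- data.frame(trial = seq_len(n))
  if (cfg$n_inputs == 2L) {
    trials$r1 <- batch$r[, 1L]
    trials$theta1 <- batch$theta[, 1L]
    trials$r2 <- batch$r[, 2L]
    trials$theta2 <- batch$theta[, 2L]
  }
  trials$r_true <- r_true
  trials$theta_true <- theta_true
  trials$r_decoded <- r_dec
  trials$theta_decoded <- theta_dec
  trials$mag_err <- abs(r_dec - r_true)
  trials$ang_err <- ang_err
  trials$clip_count <- clips

  summary <- list(
    mean_abs_magnitude_error = mean(trials$mag_err),
    mean_abs_angle_error = mean(trials$ang_err),
    magnitude_rmse = rmse(r_dec, r_true),
    angle_rmse = rmse(theta_dec, theta_true, angular = TRUE, wrap = wrap) *
      ang_scale,
    clip_count = sum(clips),
    runtime = proc.time()[["elapsed"]] - t0)

  # aggregates must be recomputable from the per-trial records
  stopifnot(isTRUE(all.equal(summary$magnitude_rmse,
                             sqrt(mean(trials$mag_err^2)))),
            isTRUE(all.equal(summary$angle_rmse,
                             sqrt(mean(trials$ang_err^2)))))

  structure(list(trials = trials, summary = summary, config = cfg),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  s <- x$summary
  u <- if (x$config$angle_units == "degrees") "deg" else "rad"
  cat(sprintf("<error_report> %d trials, %d inputs each, k = %d, N = %d\n",
              x$config$n_pairs, x$config$n_inputs, x$config$k,
              x$config$n_samples))
  cat(sprintf("  mean |dr|     : %.4f\n", s$mean_abs_magnitude_error))
  cat(sprintf("  mean |dtheta| : %.4f %s\n", s$mean_abs_angle_error, u))
  cat(sprintf("  magnitude RMSE: %.4f\n", s$magnitude_rmse))
  cat(sprintf("  angle RMSE    : %.4f %s\n", s$angle_rmse, u))
  if (s$clip_count > 0) cat(sprintf("  clipped samples: %d\n", s$clip_count))
  invisible(x)
}

#' Time/space complexity accounting for the circuit
#'
#' Forward-pass operation count for a three-layer shape:
#' `forward_ops = n_input * n_hidden + n_hidden * n_output`, the
#' dense-connectivity accounting used to size the model. The weight
#' count equals the same product, and the activation count is the
#' hidden plus output lanes touched per sample. For `d` coded inputs of
#' `M` bits the model scales linearly, reported as a formula string.
#'
#' @param shape A [network_shape()].
#' @return A `complexity_report` with `n_in`, `n_hidden`, `n_out`,
#'   `forward_ops`, `weight_count`, `activation_count` and `scaling`
#'   (formula strings for time and space).
#' @examples
#' complexity_report(network_shape())$forward_ops # 388800
#' @export
complexity_report <- function(shape = network_shape()) {
  stopifnot(inherits(shape, "network_shape"))
  ops <- shape$n_input * shape$n_hidden + shape$n_hidden * shape$n_output
  structure(list(n_in = shape$n_input,
                 n_hidden = shape$n_hidden,
                 n_out = shape$n_output,
                 forward_ops = ops,
                 weight_count = ops,
                 activation_count = shape$n_hidden + shape$n_output,
                 scaling = list(
                   time = "O(d*M*n_hidden + n_hidden*n_out)",
                   space = "O(d*M*n_hidden + n_hidden*n_out)")),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report> layers %d / %d / %d\n",
              x$n_in, x$n_hidden, x$n_out))
  cat(sprintf("  forward ops : %s\n", format(x$forward_ops, big.mark = ",")))
  cat(sprintf("  weights     : %s\n", format(x$weight_count, big.mark = ",")))
  cat(sprintf("  activations : %d per sample\n", x$activation_count))
  cat(sprintf("  time scaling: %s\n", x$scaling$time))
  invisible(x)
}
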