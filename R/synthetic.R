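#' Random binomial multiplicative cascade
#'
#' Builds a k-level multiplicative redistribution of unit mass: each cell
#' splits its mass into fractions `p` and `1 - p`, with the side receiving
#' `p` chosen by an independent fair coin per node. The result is a
#' positive series of length `2^k` whose multifractal spectrum is known in
#' closed form ([cascade_theory]), which makes it the validation oracle for
#' the spectrum estimator.
#'
#' @param p cascade weight, in (0, 0.5]. `p = 0.5` gives the uniform
#'   (monofractal) measure; smaller p gives wider spectra.
#' @param k number of levels (series length `2^k`).
#' @param seed RNG seed for the branch coins.
#' @return Numeric vector of length `2^k`, positive, summing to 1.
#' @export
binomial_cascade <- function(p, k, seed = NULL) {
  if (!is.numeric(p) || p <= 0 || p > 0.5) stop("p must be in (0, 0.5]")
  if (k < 1) stop("k must be >= 1")
  with_seed(seed, {
    m <- 1
    for (lvl in seq_len(k)) {
      left <- ifelse(runif(length(m)) < 0.5, p, 1 - p)
      m <- as.vector(rbind(m * left, m * (1 - left)))
    }
    m
  })
}

#' Gaussian series with a prescribed power-spectrum envelope
#'
#' Synthesises a zero-mean, unit-variance linear stochastic series by
#' inverse Fourier transform of a deterministic amplitude envelope with
#' uniformly random phases (conjugate-symmetric, so the series is real).
#' Because the envelope is fixed, two seeds give distinct series with the
#' identical periodogram; all structure is strictly linear by construction.
#'
#' @param length series length (>= 64).
#' @param spectrum_shape `"flat"` (white), `"powerlaw"` (power `~ f^-exponent`),
#'   or `"peaked"` (quasiperiodic: Gaussian spectral bump plus a broadband
#'   floor).
#' @param seed RNG seed for the phases.
#' @param sample_rate sampling rate in Hz (used to place `peak_freq`).
#' @param exponent power-law exponent beta for `"powerlaw"` (default 1).
#' @param peak_freq centre of the spectral bump in Hz for `"peaked"`
#'   (default 1).
#' @param peak_width bump width (sd) in Hz (default 0.1).
#' @param floor_level broadband amplitude floor relative to the bump peak
#'   for `"peaked"` (default 0.05).
#' @return Numeric vector: mean 0, sd 1.
#' @export
linear_null_series <- function(length, spectrum_shape = c("flat", "powerlaw", "peaked"),
                               seed = NULL, sample_rate = 50,
                               exponent = 1, peak_freq = 1, peak_width = 0.1,
                               floor_level = 0.05) {
  spectrum_shape <- match.arg(spectrum_shape)
  n <- as.integer(length)
  if (n < 64L) stop("length must be >= 64")
  freqs <- seq_len(n - 1L) * sample_rate / n       # nonzero FFT bins
  # fold to physical frequency (bins above Nyquist mirror down)
  f_phys <- pmin(freqs, sample_rate - freqs)
  amp <- switch(spectrum_shape,
    flat = rep(1, n - 1L),
    powerlaw = pmax(f_phys, sample_rate / n)^(-exponent / 2),
    peaked = exp(-(f_phys - peak_freq)^2 / (2 * peak_width^2)) + floor_level)
  A <- c(0, amp)                                    # zero DC
  with_seed(seed, {
    ph <- runif(n, 0, 2 * pi)
    half <- seq_len(n %/% 2)
    ph[1L] <- 0
    ph[n + 2L - half[-1L]] <- -ph[half[-1L]]
    if (n %% 2L == 0L) ph[n %/% 2L + 1L] <- 0
    x <- Re(fft(A * exp(1i * ph), inverse = TRUE)) / n
    (x - mean(x)) / sd(x)
  })
}

#' Specification of a synthetic postural-sway cohort
#'
#' Describes a study-shaped cohort: `n_subjects` subjects each measured in
#' two conditions (wind = 1, no wind = 0), one nonnegative displacement
#' series per subject x condition. Each series is a quasiperiodic carrier
#' riding on a baseline, with condition-dependent nonlinear structure
#' injected on top (see [synth_cohort]).
#'
#' @param n_subjects number of subjects (default 21).
#' @param series_length samples per series (default 6012; must be >= 4000
#'   so four 1000-sample blocks fit).
#' @param sample_rate Hz (default 50; 1000 samples = one 20-s block).
#' @param oscillation_period carrier period in seconds (default 2).
#' @param oscillation_amplitude carrier amplitude in arbitrary displacement
#'   units (default 1).
#' @param cascade_weight named numeric `c(wind=, nowind=)`: binomial-cascade
#'   weight driving amplitude heterogeneity in the `"widening"` mechanism
#'   (default 0.35 for both).
#' @param nonlinearity named character `c(wind=, nowind=)`: each of
#'   `"narrowing"`, `"widening"`, or `"none"` (defaults: wind narrowing,
#'   no-wind widening, the two regimes observed in sway data).
#' @param noise_scale sd of additive white measurement noise relative to
#'   the carrier amplitude (default 0.2).
#' @param baseline constant displacement offset keeping series positive,
#'   in carrier-amplitude units (default 4, about four signal sd, so the
#'   final absolute-value step almost never binds).
#' @param seed cohort RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 21L, series_length = 6012L,
                        sample_rate = 50, oscillation_period = 2,
                        oscillation_amplitude = 1,
                        cascade_weight = c(wind = 0.35, nowind = 0.35),
                        nonlinearity = c(wind = "narrowing", nowind = "widening"),
                        noise_scale = 0.2, baseline = 4, seed = 1L) {
  if (series_length < 4000L) {
    stop("series_length must be >= 4000 (four 1000-sample blocks)")
  }
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  stopifnot(all(c("wind", "nowind") %in% names(cascade_weight)),
            all(c("wind", "nowind") %in% names(nonlinearity)))
  ok <- c("narrowing", "widening", "none")
  if (!all(nonlinearity %in% ok)) {
    stop("nonlinearity must be one of: ", paste(ok, collapse = ", "))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         series_length = as.integer(series_length),
         sample_rate = sample_rate,
         oscillation_period = oscillation_period,
         oscillation_amplitude = oscillation_amplitude,
         cascade_weight = cascade_weight,
         nonlinearity = nonlinearity,
         noise_scale = noise_scale, baseline = baseline,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# Resample a cascade of length 2^k onto n samples by even subsampling,
# normalised to mean 1 so it acts as a pure amplitude envelope.
cascade_envelope <- function(p, n, seed) {
  k <- ceiling(log2(n))
  cas <- binomial_cascade(p, k, seed = seed)
  idx <- ceiling(seq_len(n) * length(cas) / n)
  e <- cas[idx]
  e / mean(e)
}

# One synthetic displacement series. Each series is a quasiperiodic
# oscillation riding on a positive baseline; nonlinearity is injected as:
#  widening  - multiplicative amplitude coupling: the whole displacement
#              magnitude (baseline + carrier) is multiplied by a cascade
#              envelope, so bin masses inherit the cascade's heterogeneity
#              in a phase-coherent way that phase randomisation destroys
#              (surrogates narrower, t > 0),
#  narrowing - amplitude-stabilised frequency modulation: sin() (a bounded,
#              saturating function) of a linear phase-drift series. The
#              oscillation's envelope is flat while linear surrogates with
#              the same broadened spectrum beat, so the original is more
#              homogeneous than its linear null (t < 0),
#  none      - the untouched linear carrier (a valid linear null).
synth_series <- function(spec, condition, seed) {
  n <- spec$series_length
  cond_name <- if (condition == 1L) "wind" else "nowind"
  mech <- spec$nonlinearity[[cond_name]]
  a <- spec$oscillation_amplitude
  f0 <- 1 / spec$oscillation_period
  noise <- with_seed(seed + 1L, rnorm(n, sd = spec$noise_scale * a))
  if (mech == "narrowing") {
    # slow phase drift: steep-power-law linear series, ~3 rad excursions
    drift <- 3 * linear_null_series(n, "powerlaw", seed = seed,
                                    sample_rate = spec$sample_rate,
                                    exponent = 3)
    x <- a * sin(2 * pi * f0 * seq_len(n) / spec$sample_rate + drift) + noise
    return(abs(spec$baseline * a + x))
  }
  carrier <- a * linear_null_series(
    n, "peaked", seed = seed, sample_rate = spec$sample_rate,
    peak_freq = f0, peak_width = 0.1)
  u <- spec$baseline * a + carrier + noise
  if (mech == "widening") {
    env <- cascade_envelope(spec$cascade_weight[[cond_name]], n, seed + 2L)
    u <- u * env
  }
  abs(u)
}

#' Generate a synthetic study-shaped cohort
#'
#' Produces one nonnegative displacement series per subject x condition
#' (so `2 * n_subjects` series), each with the nonlinearity mechanism the
#' spec assigns to its condition, plus a truth table recording every
#' series' generating parameters. Fully reproducible from the spec seed.
#'
#' @param spec a [cohort_spec].
#' @return Object of class `mf_cohort`: list with `series` (named list of
#'   [displacement_series]), `truth` (data frame: subject_id, condition,
#'   nonlinearity, cascade_weight, seed), and the `spec`.
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- expand.grid(subject = seq_len(spec$n_subjects), condition = c(0L, 1L))
  rows <- rows[order(rows$subject, rows$condition), ]
  series <- vector("list", nrow(rows))
  truth <- data.frame(subject_id = sprintf("S%02d", rows$subject),
                      condition = rows$condition)
  truth$nonlinearity <- ifelse(truth$condition == 1L,
                               spec$nonlinearity[["wind"]],
                               spec$nonlinearity[["nowind"]])
  truth$cascade_weight <- ifelse(truth$condition == 1L,
                                 spec$cascade_weight[["wind"]],
                                 spec$cascade_weight[["nowind"]])
  truth$seed <- spec$seed + 7919L * seq_len(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    u <- synth_series(spec, truth$condition[i], truth$seed[i])
    series[[i]] <- displacement_series(
      u, sample_rate = spec$sample_rate,
      subject_id = truth$subject_id[i], condition = truth$condition[i])
  }
  names(series) <- paste0(truth$subject_id, "_c", truth$condition)
  structure(list(series = series, truth = truth, spec = spec),
            class = "mf_cohort")
}

#' @export
print.mf_cohort <- function(x, ...) {
  cat(sprintf("<mf_cohort> %d series (%d subjects x 2 conditions), %d samples each\n",
              length(x$series), x$spec$n_subjects, x$spec$series_length))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One delimited file per series (`sample_index`, `displacement`), a
#' manifest table (`subject_id`, `condition`, `file`, `onset_index`, truth
#' parameters), and the generating spec echoed as YAML.
#'
#' @param cohort an `mf_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_c%d.tsv", cohort$truth$subject_id, cohort$truth$condition)
  for (i in seq_along(cohort$series)) {
    write_displacement_series(cohort$series[[i]], file.path(dir, files[i]))
  }
  man <- cbind(cohort$truth[, c("subject_id", "condition")],
               file = files, onset_index = 0L,
               cohort$truth[, c("nonlinearity", "cascade_weight", "seed")])
  man_path <- file.path(dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cohort$spec), file.path(dir, "cohort_spec.yaml"))
  invisible(man_path)
}
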