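#' Scaling configuration for direct multifractal estimation
#'
#' Bundles the tuning parameters of the direct (Chhabra-Jensen) spectrum
#' estimator: the q sweep, the scaling region, the number of bin sizes, and
#' the regression-fidelity floor used to retain a q.
#'
#' @param q_values ordered numeric vector of distortion exponents q.
#'   Default: integers -200..200. Positive q emphasise large bin
#'   proportions, negative q small ones.
#' @param l_min smallest bin size, in samples (default 4).
#' @param l_max largest bin size, in samples. `NULL` (default) means one
#'   quarter of the series length, resolved when the series is seen.
#' @param n_scales number of bin sizes, log-spaced between `l_min` and
#'   `l_max` then rounded and deduplicated (default 16). Ignored when
#'   `scales` is given.
#' @param scales optional explicit integer vector of bin sizes. Dyadic
#'   scales ([dyadic_scales]) are the natural choice for cascade inputs.
#' @param r_threshold correlation floor: a q enters the spectrum only when
#'   both of its log-log regressions have `|r|` above this (default .995).
#' @return An object of class `scaling_config`.
#' @export
scaling_config <- function(q_values = -200:200, l_min = 4L, l_max = NULL,
                           n_scales = 16L, scales = NULL, r_threshold = 0.995) {
  if (length(q_values) < 1L) stop("q_values must be nonempty")
  if (l_min < 2L) stop("l_min must be >= 2")
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must be in (0, 1)")
  structure(
    list(q_values = sort(unique(as.numeric(q_values))),
         l_min = as.integer(l_min),
         l_max = if (!is.null(l_max)) as.integer(l_max),
         n_scales = as.integer(n_scales),
         scales = if (!is.null(scales)) sort(unique(as.integer(scales))),
         r_threshold = r_threshold),
    class = "scaling_config")
}

#' Dyadic scale set
#'
#' Powers of two between `l_min` and `l_max`. For binomial-cascade inputs
#' (length 2^k) dyadic bins align exactly with cascade cells, so the
#' log-log scaling is exact and the closed-form spectrum is recovered.
#'
#' @inheritParams scaling_config
#' @return Integer vector of bin sizes.
#' @export
dyadic_scales <- function(l_min = 4L, l_max) {
  2L^(ceiling(log2(l_min)):floor(log2(l_max)))
}

# Resolve the concrete scale set for a series of `n` samples.
resolve_scales <- function(cfg, n) {
  l_max <- if (!is.null(cfg$l_max)) cfg$l_max else max(cfg$l_min, n %/% 4L)
  if (l_max > n %/% 2L) l_max <- n %/% 2L
  if (!is.null(cfg$scales)) {
    sc <- cfg$scales[cfg$scales >= 2L & cfg$scales <= l_max]
  } else {
    sc <- unique(round(exp(seq(log(cfg$l_min), log(l_max),
                               length.out = cfg$n_scales))))
  }
  sc <- sort(unique(as.integer(sc)))
  if (length(sc) < 3L) {
    stop(sprintf("fewer than 3 usable scales between %d and %d for a %d-sample series",
                 cfg$l_min, l_max, n))
  }
  sc
}

#' Bin proportions at one scale
#'
#' The proportion of total displacement falling in each non-overlapping
#' bin of `L` consecutive samples. Only complete bins count: the trailing
#' partial bin is discarded and the normalisation runs over complete bins,
#' so the proportions always sum to 1.
#'
#' @param u nonnegative numeric vector (or a [displacement_series]).
#' @param L bin size in samples; must satisfy `L <= length(u) / 2`.
#' @return Numeric vector of proportions, one per complete bin.
#' @export
bin_proportions <- function(u, L) {
  if (inherits(u, "displacement_series")) u <- u$u
  n <- length(u)
  L <- as.integer(L)
  if (L < 1L || L > n %/% 2L) stop("bin size L must be in [1, length/2]")
  if (any(u < 0)) stop("u must be nonnegative")
  n_bins <- n %/% L
  kept <- u[seq_len(n_bins * L)]
  sums <- colSums(matrix(kept, nrow = L))
  tot <- sum(sums)
  if (tot <= 0) stop("series has zero total mass over complete bins")
  sums / tot
}

#' q-distorted mass
#'
#' Converts bin proportions into the normalised q-mass
#' `mu_i = P_i^q / sum_j P_j^q`. Computed in the log domain with
#' max-subtraction so that exponents as extreme as |q| = 200 neither
#' overflow nor underflow the normalisation.
#'
#' Bins with zero proportion carry zero mass for `q > 0` and are excluded;
#' for `q <= 0` a zero proportion makes the mass undefined and the function
#' returns all `NA` (callers drop that scale rather than flooring zeros).
#'
#' @param P numeric vector of proportions summing to 1.
#' @param q distortion exponent.
#' @return Numeric vector of masses summing to 1 (or all `NA`).
#' @export
q_mass <- function(P, q) {
  zero <- P == 0
  if (q <= 0 && any(zero)) return(rep(NA_real_, length(P)))
  lw <- rep(-Inf, length(P))
  lw[!zero] <- q * log(P[!zero])
  m <- max(lw)
  w <- exp(lw - m)
  w / sum(w)
}

# Per-scale building block: the two q-weighted sums whose scaling slopes
# give f(q) and alpha(q). Returns an n_q x 2 matrix (columns: sum mu ln mu,
# sum mu ln P); rows are NA where the scale is unusable for that q.
# Plain-R reference for the compiled cj_scale_sums() used by
# estimate_spectrum(); retained for diagnostics and cross-checks.
scale_sums <- function(u, L, q_values) {
  P <- bin_proportions(u, L)
  logP <- ifelse(P > 0, log(P), -Inf)
  pos <- logP[is.finite(logP)]
  has_zero <- length(pos) < length(P)
  # log-domain q-mass for all q at once: n_q x n_bins
  lw <- outer(q_values, pos)
  mx <- apply(lw, 1L, max)
  w <- exp(lw - mx)
  tot <- rowSums(w)
  mu <- w / tot
  logmu <- lw - mx - log(tot)
  f_num <- rowSums(ifelse(mu > 0, mu * logmu, 0))
  a_num <- rowSums(ifelse(mu > 0, mu * matrix(pos, nrow = length(q_values),
                                              ncol = length(pos), byrow = TRUE), 0))
  if (has_zero) {
    drop <- q_values <= 0
    f_num[drop] <- NA_real_
    a_num[drop] <- NA_real_
  }
  cbind(f_num, a_num)
}

# Slope and Pearson correlation of y against x, NA-safe.
slope_r <- function(x, y) {
  ok <- is.finite(y)
  if (sum(ok) < 3L) return(c(NA_real_, NA_real_, sum(ok)))
  x <- x[ok]; y <- y[ok]
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx == 0 || vy == 0) return(c(NA_real_, NA_real_, length(x)))
  slope <- sum(sx * sy) / vx
  r <- sum(sx * sy) / sqrt(vx * vy)
  c(slope, r, length(x))
}

#' Estimate the multifractal spectrum of a displacement series
#'
#' Direct (Chhabra-Jensen) estimation. For each distortion exponent q, the
#' q-mass `mu(q, L)` is formed over bins of size L and two quantities are
#' regressed on `ln L` across the scale set: the negative Shannon entropy
#' `sum(mu ln mu)`, whose slope is the dimension `f(q)`, and the
#' cross-entropy `sum(mu ln P)`, whose slope is the singularity strength
#' `alpha(q)`. A q is retained in the spectrum only when both regressions
#' are convincingly linear (`|r|` above `r_threshold`); the spectrum width
#' is `W = max(alpha) - min(alpha)` over retained q.
#'
#' @param u a [displacement_series] or nonnegative numeric vector.
#' @param cfg a [scaling_config].
#' @return Object of class `mf_spectrum`: a list with `spectrum` (data frame
#'   of q, alpha, f, r_alpha, r_f, n_scales_used, retained), `W`,
#'   `n_retained`, `alpha_range`, `scales`, `dropped_scales` (scales where
#'   zero-proportion bins invalidated q <= 0), and the config.
#' @export
estimate_spectrum <- function(u, cfg = scaling_config()) {
  if (inherits(u, "displacement_series")) u <- u$u
  if (any(u < 0)) stop("u must be nonnegative")
  if (sum(u) <= 0) stop("degenerate series: zero total mass")
  n <- length(u)
  scales <- resolve_scales(cfg, n)
  if (n < 4L * min(scales)) stop("series too short for the requested scaling region")
  q <- cfg$q_values
  sums <- cj_scale_sums(u, as.integer(scales), q)
  f_mat <- sums$f_num
  a_mat <- sums$a_num
  lnL <- log(scales)
  f_fit <- t(vapply(seq_along(q), function(i) slope_r(lnL, f_mat[i, ]), numeric(3)))
  a_fit <- t(vapply(seq_along(q), function(i) slope_r(lnL, a_mat[i, ]), numeric(3)))
  retained <- !is.na(f_fit[, 2L]) & !is.na(a_fit[, 2L]) &
    abs(f_fit[, 2L]) > cfg$r_threshold & abs(a_fit[, 2L]) > cfg$r_threshold
  spec <- data.frame(q = q,
                     alpha = a_fit[, 1L], f = f_fit[, 1L],
                     r_alpha = a_fit[, 2L], r_f = f_fit[, 2L],
                     n_scales_used = as.integer(pmin(f_fit[, 3L], a_fit[, 3L])),
                     retained = retained)
  if (any(retained)) {
    a_ret <- spec$alpha[retained]
    W <- max(a_ret) - min(a_ret)
    alpha_range <- range(a_ret)
  } else {
    warning("no q retained: all scaling regressions fell below the fidelity threshold")
    W <- NA_real_
    alpha_range <- c(NA_real_, NA_real_)
  }
  dropped <- scales[vapply(seq_along(scales),
                           function(j) anyNA(f_mat[, j]), logical(1))]
  structure(
    list(spectrum = spec, W = W, n_retained = sum(retained),
         alpha_range = alpha_range, scales = scales,
         dropped_scales = dropped, config = cfg,
         series_length = n),
    class = "mf_spectrum")
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat(sprintf("<mf_spectrum> %d-sample series, scales %d..%d (%d sizes)\n",
              x$series_length, min(x$scales), max(x$scales), length(x$scales)))
  cat(sprintf("  retained q: %d of %d; W = %s (alpha in [%s, %s])\n",
              x$n_retained, nrow(x$spectrum),
              format(x$W, digits = 4),
              format(x$alpha_range[1], digits = 4),
              format(x$alpha_range[2], digits = 4)))
  invisible(x)
}

#' Write a spectrum as a delimited table
#'
#' One row per q (q, alpha, f, r_alpha, r_f, retained) followed by a
#' commented summary line carrying W and the retained-q count.
#'
#' @param x an `mf_spectrum`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "mf_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# W=%.17g n_retained=%d", x$W, x$n_retained), con)
  write.table(x$spectrum, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retention profile across a set of spectra
#'
#' Less multifractal series tolerate a wider sweep of the distortion
#' exponent q before their log-log scaling degrades, so the number of
#' retained q should fall as spectrum width grows. This diagnostic tabulates
#' (n_retained, W) per series and their Spearman rank correlation.
#'
#' @param spectra list of `mf_spectrum` objects (names used as series ids).
#' @return List with `table` (data frame: series, n_retained, W) and
#'   `rank_correlation` (Spearman; `NA` with a flag when < 2 usable spectra).
#' @export
q_retention_profile <- function(spectra) {
  if (length(spectra) < 1L) stop("need at least one spectrum")
  stopifnot(all(vapply(spectra, inherits, logical(1), "mf_spectrum")))
  ids <- names(spectra)
  if (is.null(ids)) ids <- as.character(seq_along(spectra))
  tab <- data.frame(series = ids,
                    n_retained = vapply(spectra, function(s) s$n_retained, integer(1)),
                    W = vapply(spectra, function(s) s$W, numeric(1)))
  ok <- !is.na(tab$W)
  rc <- if (sum(ok) >= 2L && sd(tab$n_retained[ok]) > 0 && sd(tab$W[ok]) > 0) {
    cor(tab$n_retained[ok], tab$W[ok], method = "spearman")
  } else NA_real_
  list(table = tab, rank_correlation = rc,
       degenerate = is.na(rc))
}

#' Diagnostic scaling plot
#'
#' Plots the negative Shannon entropy of the q-mass against log bin size
#' for a handful of q, the linearity of which is what the fidelity filter
#' screens. One line per q; retained-q regressions should look straight.
#'
#' @param u series or [displacement_series].
#' @param cfg a [scaling_config].
#' @param q_show q values to display (default 7 spread over the sweep).
#' @return Invisibly, the matrix of plotted entropy sums.
#' @export
plot_scaling <- function(u, cfg = scaling_config(), q_show = NULL) {
  if (inherits(u, "displacement_series")) u <- u$u
  scales <- resolve_scales(cfg, length(u))
  if (is.null(q_show)) {
    q_show <- unique(quantile(cfg$q_values, probs = seq(0, 1, length.out = 7),
                              type = 1))
  }
  ent <- vapply(scales, function(L) scale_sums(u, L, q_show)[, 1L],
                numeric(length(q_show)))
  if (length(q_show) == 1L) ent <- matrix(ent, nrow = 1L)
  graphics::matplot(log(scales), t(ent), type = "b", pch = 16, lty = 1,
                    xlab = "ln L (samples)",
                    ylab = expression(sum(mu ~ ln ~ mu)),
                    main = "Scaling of negative Shannon entropy")
  graphics::legend("bottomright", legend = paste0("q=", signif(q_show, 3)),
                   col = seq_along(q_show), lty = 1, cex = 0.7)
  invisible(ent)
}

#' Closed-form binomial-cascade spectrum
#'
#' The singularity strength of a two-weight multiplicative cascade with
#' weights `p` and `1 - p`:
#' `alpha(q) = -(p^q ln p + (1-p)^q ln(1-p)) / ((p^q + (1-p)^q) ln 2)`.
#' Its limits give the theoretical spectrum width
#' `W = log2((1-p)/p)`, the oracle the estimator is validated against.
#'
#' @param p cascade weight in (0, 0.5].
#' @param q numeric vector of exponents.
#' @return List with `alpha` (per q) and `width` (the q -> +/-Inf limit).
#' @export
cascade_theory <- function(p, q = -200:200) {
  stopifnot(p > 0, p <= 0.5)
  # stabilised: divide through by max(p,1-p)^q to avoid overflow at large |q|
  lp <- log(p); lq <- log1p(-p)
  a <- vapply(q, function(qi) {
    m <- max(qi * lp, qi * lq)
    wp <- exp(qi * lp - m); wq <- exp(qi * lq - m)
    -(wp * lp + wq * lq) / ((wp + wq) * log(2))
  }, numeric(1))
  list(alpha = a, width = log2((1 - p) / p))
}
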