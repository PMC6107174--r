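#' Whole-series and block-wise multifractal measures for one series
#'
#' Computes the study's per-series measures: spectrum width and surrogate
#' t for the whole series (`W_ALL`, `t_ALL`, scaling region up to one
#' quarter of the series length) and for each contiguous block (`W_BLOCK`,
#' `t_BLOCK`, scaling region up to `block_l_max` within each block). Each
#' unit's t is computed against IAAFT surrogates of that same unit, so the
#' null is the best-fitting linear model of the unit itself; set
#' `block_surrogates = "series"` to instead derive block nulls from
#' whole-series surrogates.
#'
#' Whole-series measures use the entire stored series; block partitioning
#' starts at the series' `onset_index`.
#'
#' @param d a [displacement_series].
#' @param cfg a [scaling_config]; its `l_max` (default: length/4) applies
#'   to the whole-series measures.
#' @param block_length samples per block (default 1000).
#' @param n_blocks blocks to analyse (default 4).
#' @param block_l_max largest bin size for block spectra (default 250).
#' @param n_surrogates surrogate ensemble size (default 50).
#' @param n_iterations IAAFT iterations (default 1000).
#' @param seed base seed for the surrogate ensembles.
#' @param se_method passed to [t_mf].
#' @param block_surrogates `"block"` (default) or `"series"`.
#' @return Data frame with one row per unit (`block` = `"ALL"`, `"1"`..):
#'   columns `block`, `W`, `t`, `n_retained_q`. If the series cannot supply
#'   `n_blocks` full blocks, only the ALL row is returned, with a warning.
#' @export
analyze_series <- function(d, cfg = scaling_config(), block_length = 1000L,
                           n_blocks = 4L, block_l_max = 250L,
                           n_surrogates = 50L, n_iterations = 1000L,
                           seed = 1L, se_method = "sd_over_sqrt_n",
                           block_surrogates = c("block", "series")) {
  stopifnot(inherits(d, "displacement_series"))
  block_surrogates <- match.arg(block_surrogates)

  unit_measures <- function(u, unit_cfg, unit_seed) {
    sp <- suppressWarnings(estimate_spectrum(u, unit_cfg))
    ens <- surrogate_widths(u, unit_cfg, n_surrogates = n_surrogates,
                            n_iterations = n_iterations, seed = unit_seed)
    tt <- t_mf(sp$W, ens, se_method = se_method)
    data.frame(W = sp$W, t = tt$t, n_retained_q = sp$n_retained)
  }

  all_row <- cbind(block = "ALL", unit_measures(d$u, cfg, seed))

  blocks <- tryCatch(partition_blocks(d, block_length, n_blocks),
                     error = function(e) {
                       warning("block measures skipped: ", conditionMessage(e))
                       NULL
                     })
  if (is.null(blocks)) return(all_row)

  bcfg <- cfg
  bcfg$l_max <- as.integer(min(block_l_max, block_length %/% 2L))

  if (block_surrogates == "block") {
    block_rows <- lapply(seq_along(blocks), function(b) {
      cbind(block = as.character(b),
            unit_measures(blocks[[b]]$u, bcfg, seed + 131L * b))
    })
  } else {
    # alternative null: blocks cut from whole-series surrogates
    W_blk <- vapply(blocks, function(bl) {
      suppressWarnings(estimate_spectrum(bl$u, bcfg))$W
    }, numeric(1))
    surr_blk <- vapply(seq_len(n_surrogates), function(i) {
      s <- iaaft(d$u, n_iterations = n_iterations, seed = seed + i)
      sd_ <- displacement_series(abs(s), sample_rate = d$sample_rate,
                                 onset_index = d$onset_index)
      bls <- partition_blocks(sd_, block_length, n_blocks)
      vapply(bls, function(bl) {
        suppressWarnings(estimate_spectrum(bl$u, bcfg))$W
      }, numeric(1))
    }, numeric(n_blocks))
    block_rows <- lapply(seq_len(n_blocks), function(b) {
      tt <- t_mf(W_blk[b], surr_blk[b, ], se_method = se_method)
      sp <- suppressWarnings(estimate_spectrum(blocks[[b]]$u, bcfg))
      data.frame(block = as.character(b), W = W_blk[b], t = tt$t,
                 n_retained_q = sp$n_retained)
    })
  }
  rbind(all_row, do.call(rbind, block_rows))
}

#' Assemble the cohort modeling table
#'
#' Runs [analyze_series] over every series of a cohort and assembles the
#' table the mixed models consume: one ALL row and one row per block for
#' each subject x condition, with the subject x condition's whole-series
#' `W_ALL` and `t_ALL` joined onto its block rows.
#'
#' @param x a cohort: an `mf_cohort` from [synth_cohort], a manifest file
#'   path, or a manifest data frame (columns `subject_id`, `condition`,
#'   `file`, optional `onset_index`; paths resolved by [read_manifest] when
#'   a path is given).
#' @inheritParams analyze_series
#' @param sample_rate sampling rate assumed for series read from files.
#' @return Data frame of class `cohort_table`: `subject_id`, `condition`,
#'   `block` (`"ALL"`, `"1"`..), `W`, `t`, `n_retained_q`, `W_ALL`,
#'   `t_ALL`, ordered by subject, condition, block. Unreadable files are
#'   skipped with a warning; duplicated subject x condition is an error.
#' @export
build_cohort_table <- function(x, cfg = scaling_config(), block_length = 1000L,
                               n_blocks = 4L, block_l_max = 250L,
                               n_surrogates = 50L, n_iterations = 1000L,
                               seed = 1L, se_method = "sd_over_sqrt_n",
                               block_surrogates = "block", sample_rate = 50) {
  if (inherits(x, "mf_cohort")) {
    series <- x$series
  } else {
    man <- if (is.character(x)) read_manifest(x) else as.data.frame(x)
    if (is.null(man$onset_index)) man$onset_index <- rep(0L, nrow(man))
    series <- vector("list", nrow(man))
    keep <- logical(nrow(man))
    for (i in seq_len(nrow(man))) {
      s <- tryCatch(
        suppressWarnings(
          read_displacement_series(man$file[i], sample_rate = sample_rate,
                                   subject_id = man$subject_id[i],
                                   condition = man$condition[i],
                                   onset_index = man$onset_index[i])),
        error = function(e) {
          warning(sprintf("skipping %s (subject %s): %s", man$file[i],
                          man$subject_id[i], conditionMessage(e)))
          NULL
        })
      if (!is.null(s)) { series[[i]] <- s; keep[i] <- TRUE }
    }
    series <- series[keep]
  }
  if (length(series) == 0L) {
    warning("empty cohort: returning empty table")
    out <- data.frame(subject_id = character(), condition = integer(),
                      block = character(), W = numeric(), t = numeric(),
                      n_retained_q = integer(), W_ALL = numeric(),
                      t_ALL = numeric())
    class(out) <- c("cohort_table", class(out))
    return(out)
  }
  key <- paste(vapply(series, function(s) s$subject_id, character(1)),
               vapply(series, function(s) s$condition, numeric(1)))
  if (anyDuplicated(key)) {
    stop("duplicate subject x condition in cohort: ", key[duplicated(key)][1])
  }
  rows <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    m <- analyze_series(s, cfg = cfg, block_length = block_length,
                        n_blocks = n_blocks, block_l_max = block_l_max,
                        n_surrogates = n_surrogates,
                        n_iterations = n_iterations,
                        seed = seed + 1009L * i, se_method = se_method,
                        block_surrogates = block_surrogates)
    all_i <- m$block == "ALL"
    cbind(subject_id = s$subject_id, condition = s$condition, m,
          W_ALL = m$W[all_i], t_ALL = m$t[all_i])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$condition,
                   match(out$block, c("ALL", as.character(1:99)))), ]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", class(out))
  out
}

#' Per-condition cohort summary
#'
#' Mean and SD of whole-series spectrum width and nonlinearity t per
#' condition, with counts of series whose `t_ALL` exceeds +1.96 or falls
#' below -1.96 (the two-sided 5% cut used when tallying significantly
#' wider/narrower-than-linear series).
#'
#' @param tab a `cohort_table` from [build_cohort_table].
#' @return Data frame with one row per condition.
#' @export
cohort_summary <- function(tab) {
  all_rows <- tab[tab$block == "ALL", ]
  do.call(rbind, lapply(split(all_rows, all_rows$condition), function(g) {
    data.frame(condition = g$condition[1], n = nrow(g),
               W_ALL_mean = mean(g$W, na.rm = TRUE),
               W_ALL_sd = sd(g$W, na.rm = TRUE),
               t_ALL_mean = mean(g$t, na.rm = TRUE),
               t_ALL_sd = sd(g$t, na.rm = TRUE),
               n_t_above = sum(g$t > 1.96, na.rm = TRUE),
               n_t_below = sum(g$t < -1.96, na.rm = TRUE))
  }))
}

#' Write a cohort table with its run configuration
#'
#' @param tab a `cohort_table`.
#' @param path output table path (tab-delimited).
#' @param config optional list of run parameters echoed as YAML next to
#'   the table (same path with extension `.yaml`).
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(tab, path, config = NULL) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    yaml::write_yaml(config, paste0(sub("\\.[^.]+$", "", path), ".yaml"))
  }
  invisible(path)
}
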