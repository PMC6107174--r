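# Shared scaffolding for the two block-wise mixed models: both have the
# full Condition x Block-terms x covariate fixed structure (16 terms) and
# a random intercept per subject, fitted by REML with Satterthwaite
# degrees of freedom via lmerTest.

prepare_block_data <- function(tab, covariate) {
  d <- tab[tab$block != "ALL", , drop = FALSE]
  if (nrow(d) == 0L) stop("cohort table has no block rows")
  if (anyNA(d[[covariate]])) stop("missing ", covariate, " on block rows")
  d$block_num <- as.integer(d$block)
  d$condition <- as.numeric(d$condition)
  d
}

fit_block_model <- function(d, formula, labels, response, block_coding) {
  fit <- lmerTest::lmer(formula, data = d, REML = TRUE)
  co <- summary(fit)$coefficients
  if (nrow(co) != length(labels)) {
    aliased <- setdiff(names(lme4::fixef(fit, add.dropped = TRUE)),
                       rownames(co))
    stop("rank-deficient fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  tab <- data.frame(Predictor = labels,
                    B = co[, "Estimate"], SE = co[, "Std. Error"],
                    df = co[, "df"], t = co[, "t value"],
                    p = co[, "Pr(>|t|)"], row.names = NULL)
  structure(list(table = tab, model = fit,
                 response = response, block_coding = block_coding,
                 random_intercept_var = as.data.frame(lme4::VarCorr(fit))$vcov[1],
                 residual_var = attr(lme4::VarCorr(fit), "sc")^2,
                 df_method = "Satterthwaite", reml = TRUE),
            class = "mf_model_fit")
}

#' Mixed model of block-wise spectrum width (smooth change over blocks)
#'
#' Fits `W_BLOCK ~ Condition * Block(poly 1-3) * W_ALL` with a random
#' intercept per subject: Block enters as orthogonal linear, quadratic and
#' cubic polynomials (orthonormal over the observed blocks), so the model
#' describes smooth directional change of spectrum width over the four
#' 20-s blocks, moderated by condition and by the whole-series width.
#' REML estimation; Satterthwaite p-values. Covariates enter uncentered.
#'
#' @param tab a `cohort_table` from [build_cohort_table].
#' @return Object of class `mf_model_fit`: `table` (Predictor, B, SE, df,
#'   t, p; 16 rows), the underlying `lmerModLmerTest` in `model`, variance
#'   components, and the df method.
#' @export
fit_w_block <- function(tab) {
  d <- prepare_block_data(tab, "W_ALL")
  pb <- poly(d$block_num, 3)
  d$block_lin <- pb[, 1]; d$block_quad <- pb[, 2]; d$block_cub <- pb[, 3]
  labels <- c("Intercept", "Condition",
              "Block(Linear)", "Block(Quadratic)", "Block(Cubic)", "W_ALL",
              "Condition:Block(Linear)", "Condition:Block(Quadratic)",
              "Condition:Block(Cubic)", "Condition:W_ALL",
              "Block(Linear):W_ALL", "Block(Quadratic):W_ALL",
              "Block(Cubic):W_ALL",
              "Condition:Block(Linear):W_ALL",
              "Condition:Block(Quadratic):W_ALL",
              "Condition:Block(Cubic):W_ALL")
  fit_block_model(
    d, W ~ condition * (block_lin + block_quad + block_cub) * W_ALL +
      (1 | subject_id),
    labels, response = "W_BLOCK", block_coding = "orthogonal_poly_3")
}

#' Mixed model of block-wise nonlinearity t (categorical block effects)
#'
#' Fits `t_BLOCK ~ Condition * Block(factor) * t_ALL` with a random
#' intercept per subject: Block is a class variable with Block 1 as the
#' reference, so Blocks 2-4 each get their own intercept shift. This is
#' the generic representation of time, appropriate when change over blocks
#' is discontinuous rather than smooth. REML; Satterthwaite p-values;
#' covariate uncentered.
#'
#' @inheritParams fit_w_block
#' @return An `mf_model_fit` (16 fixed terms).
#' @export
fit_t_block <- function(tab) {
  d <- prepare_block_data(tab, "t_ALL")
  d$block_f <- factor(d$block_num)
  labels <- c("Intercept", "Condition", "Block2", "Block3", "Block4",
              "t_ALL", "Condition:Block2", "Condition:Block3",
              "Condition:Block4", "Condition:t_ALL",
              "Block2:t_ALL", "Block3:t_ALL", "Block4:t_ALL",
              "Condition:Block2:t_ALL", "Condition:Block3:t_ALL",
              "Condition:Block4:t_ALL")
  fit_block_model(d, t ~ condition * block_f * t_ALL + (1 | subject_id),
                  labels, response = "t_BLOCK", block_coding = "categorical")
}

#' @export
print.mf_model_fit <- function(x, ...) {
  cat(sprintf("<mf_model_fit> %d fixed terms, REML, %s df\n",
              nrow(x$table), x$df_method))
  tt <- x$table
  tt$B <- signif(tt$B, 4); tt$SE <- signif(tt$SE, 4)
  tt$df <- round(tt$df, 1); tt$t <- signif(tt$t, 4)
  tt$p <- format.pval(tt$p, digits = 3, eps = 1e-4)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Write a model fit as a delimited table
#'
#' Mirrors the standard report layout (Predictor, B, SE, p), with df and t
#' included, plus a YAML sidecar recording the estimation choices.
#'
#' @param x an `mf_model_fit`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_model_fit <- function(x, path) {
  stopifnot(inherits(x, "mf_model_fit"))
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    list(response = x$response, block_coding = x$block_coding,
         df_method = x$df_method, reml = x$reml,
         random_intercept_var = x$random_intercept_var,
         residual_var = x$residual_var),
    paste0(sub("\\.[^.]+$", "", path), ".yaml"))
  invisible(path)
}
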