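#' Best linear unbiased estimates (BLUEs) across environments
#'
#' Reduces plot-level observations of one stage to per-line adjusted means
#' from the two-way fixed-effects model `y ~ line + environment`, fitted by
#' least squares with sum-to-zero environment effects (so each BLUE is the
#' line mean at the average environment). With balanced data this equals the
#' plain line mean across environments. The line factor is absorbed
#' analytically, so the fit costs one small regression regardless of
#' population size.
#'
#' @param phenotypes Plot-level tibble with columns `line`, `family`, `env`
#'   and one column per stage.
#' @param stage Name of the stage column to reduce (e.g. `"DS1"`).
#'
#' @return Tibble `line`, `family`, `blue`, one row per line with at least
#'   one observation; attributes `stage`, `n_env`, `r_bar` (harmonic-mean
#'   replicates per line-environment cell) and `dropped` (lines without
#'   observations).
#' @export
compute_blues <- function(phenotypes, stage) {
  if (!stage %in% names(phenotypes)) {
    abort(sprintf("Stage '%s' not found in the phenotype table.", stage))
  }
  dat <- phenotypes |>
    select(all_of(c("line", "family", "env", stage))) |>
    filter(!is.na(.data[[stage]]))
  if (nrow(dat) == 0) abort("No observations for this stage.")
  all_lines <- unique(phenotypes$line)
  dropped <- setdiff(all_lines, dat$line)

  y <- dat[[stage]]
  line <- factor(dat$line)
  env <- factor(dat$env)
  n_env <- nlevels(env)

  if (n_env == 1) {
    adj <- rep(0, length(y))
    mean_c <- 0
  } else {
    # absorb the line factor: regress line-centered y on line-centered
    # environment dummies; exact OLS for the connected two-way layout
    d <- stats::model.matrix(~ env)[, -1, drop = FALSE]
    line_idx <- as.integer(line)
    y_c <- y - stats::ave(y, line_idx)
    d_c <- apply(d, 2, function(col) col - stats::ave(col, line_idx))
    fit <- ls_fit(d_c, y_c)
    cvec <- c(0, ifelse(is.na(fit$coef), 0, fit$coef))
    mean_c <- mean(cvec)
    adj <- cvec[as.integer(env)]
  }

  blue <- tapply(y - adj, line, mean) + mean_c
  fam <- dat$family[!duplicated(dat$line)]
  names(fam) <- dat$line[!duplicated(dat$line)]
  out <- tibble(line = names(blue),
                family = unname(fam[names(blue)]),
                blue = as.numeric(blue)) |>
    arrange(match(.data$line, all_lines))

  cells <- table(dat$line, dat$env)
  cells <- cells[cells > 0]
  attr(out, "stage") <- stage
  attr(out, "n_env") <- n_env
  attr(out, "r_bar") <- length(cells) / sum(1 / cells)
  attr(out, "dropped") <- dropped
  out
}

#' BLUEs for several stages, wide
#'
#' @param phenotypes Plot-level phenotype tibble.
#' @param stages Stage column names.
#' @return Tibble `line`, `family` and one BLUE column per stage.
#' @export
compute_blues_wide <- function(phenotypes,
                               stages = intersect(c("DS1", "DS2", "DS3"),
                                                  names(phenotypes))) {
  out <- NULL
  for (s in stages) {
    b <- compute_blues(phenotypes, s)
    names(b)[names(b) == "blue"] <- s
    out <- if (is.null(out)) b else left_join(out, b[, c("line", s)], by = "line")
  }
  out
}

#' Variance components and entry-mean heritability for one stage
#'
#' Fits the random model `y = mu + env + line + line:env + error`
#' (environment fixed, line and line-by-environment random) by REML and
#' returns the genotypic variance, the genotype-by-environment interaction
#' variance and the plot error variance (negative solutions are clamped to
#' zero by the fitter). Entry-mean heritability is
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G \times E}/E +
#'   \sigma^2_\varepsilon/(E \bar r)),}
#' with E environments and harmonic-mean replication \eqn{\bar r} per
#' line-environment cell. Significance of each random term is assessed by a
#' REML likelihood-ratio test against the model without it, with the p-value
#' halved for the boundary constraint.
#'
#' @param phenotypes Plot-level phenotype tibble.
#' @param stage Stage column name.
#' @param lrt Compute likelihood-ratio tests for the random terms (two extra
#'   model fits)? Default `TRUE`.
#'
#' @return One-row tibble: `stage`, `sigma2_G`, `sigma2_GxE`, `sigma2_eps`,
#'   `n_env`, `r_bar`, `h2`, `p_sigma2_G`, `p_sigma2_GxE`.
#' @export
estimate_variance_components <- function(phenotypes, stage, lrt = TRUE) {
  if (!stage %in% names(phenotypes)) {
    abort(sprintf("Stage '%s' not found in the phenotype table.", stage))
  }
  dat <- phenotypes |>
    select(all_of(c("line", "env", stage))) |>
    filter(!is.na(.data[[stage]]))
  names(dat)[3] <- "y"
  if (length(unique(dat$line)) < 2) abort("Need at least two lines.")
  dat$line <- factor(dat$line)
  dat$env <- factor(dat$env)
  n_env <- nlevels(dat$env)
  cells <- table(dat$line, dat$env)
  cells <- cells[cells > 0]
  r_bar <- length(cells) / sum(1 / cells)

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  if (n_env == 1) {
    fit <- lme4::lmer(y ~ 1 + (1 | line), data = dat, REML = TRUE,
                      control = ctrl)
    vc <- as.data.frame(lme4::VarCorr(fit))
    s_g <- vc$vcov[vc$grp == "line"]
    s_ge <- NA_real_
    s_e <- vc$vcov[vc$grp == "Residual"]
    h2 <- s_g / (s_g + s_e / r_bar)
    p_g <- if (lrt) {
      # ML fits here: the reduced model is a plain lm, so REML log-likelihoods
      # would not be comparable
      fit_ml <- lme4::lmer(y ~ 1 + (1 | line), data = dat, REML = FALSE,
                           control = ctrl)
      lrt_halved(fit_ml, stats::lm(y ~ 1, data = dat))
    } else NA_real_
    p_ge <- NA_real_
  } else {
    fit <- lme4::lmer(y ~ env + (1 | line) + (1 | line:env), data = dat,
                      REML = TRUE, control = ctrl)
    vc <- as.data.frame(lme4::VarCorr(fit))
    s_g <- vc$vcov[vc$grp == "line"]
    s_ge <- vc$vcov[vc$grp == "line:env"]
    s_e <- vc$vcov[vc$grp == "Residual"]
    h2 <- s_g / (s_g + s_ge / n_env + s_e / (n_env * r_bar))
    if (lrt) {
      no_g <- lme4::lmer(y ~ env + (1 | line:env), data = dat, REML = TRUE,
                         control = ctrl)
      no_ge <- lme4::lmer(y ~ env + (1 | line), data = dat, REML = TRUE,
                          control = ctrl)
      p_g <- lrt_halved(fit, no_g)
      p_ge <- lrt_halved(fit, no_ge)
    } else {
      p_g <- NA_real_
      p_ge <- NA_real_
    }
  }
  tibble(stage = stage, sigma2_G = s_g, sigma2_GxE = s_ge, sigma2_eps = s_e,
         n_env = n_env, r_bar = r_bar, h2 = h2,
         p_sigma2_G = p_g, p_sigma2_GxE = p_ge)
}

# boundary-corrected likelihood-ratio test (p halved because the null value
# sigma^2 = 0 lies on the parameter-space boundary)
lrt_halved <- function(full, reduced) {
  ll_full <- as.numeric(stats::logLik(full))
  ll_red <- as.numeric(stats::logLik(reduced))
  stat <- max(0, 2 * (ll_full - ll_red))
  stats::pchisq(stat, df = 1, lower.tail = FALSE) / 2
}

#' Variance components for all stages
#'
#' @param phenotypes Plot-level phenotype tibble.
#' @param stages Stage column names.
#' @param lrt Compute likelihood-ratio tests?
#' @return Tibble, one row per stage (see
#'   [estimate_variance_components()]).
#' @export
variance_components_table <- function(phenotypes,
                                      stages = intersect(
                                        c("DS1", "DS2", "DS3"),
                                        names(phenotypes)),
                                      lrt = TRUE) {
  purrr::map_dfr(stages, function(s) {
    estimate_variance_components(phenotypes, s, lrt = lrt)
  })
}

#' Pearson correlations between stage BLUEs
#'
#' @param blues Wide BLUE tibble from [compute_blues_wide()].
#' @param stages Stage columns to correlate.
#' @return Tibble `stage_a`, `stage_b`, `n`, `r`, `p` (two-sided t-test),
#'   one row per unordered stage pair.
#' @export
stage_correlations <- function(blues,
                               stages = intersect(c("DS1", "DS2", "DS3"),
                                                  names(blues))) {
  if (length(stages) < 2) abort("Need at least two stages.")
  pairs <- utils::combn(stages, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- blues[[pairs[1, k]]]
    b <- blues[[pairs[2, k]]]
    keep <- !is.na(a) & !is.na(b)
    n <- sum(keep)
    if (n < 3) {
      abort(sprintf("Fewer than 3 shared lines for %s-%s.",
                    pairs[1, k], pairs[2, k]))
    }
    ct <- stats::cor.test(a[keep], b[keep])
    tibble(stage_a = pairs[1, k], stage_b = pairs[2, k], n = n,
           r = unname(ct$estimate), p = ct$p.value)
  })
}
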