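#' Define a time-indexed trait architecture
#'
#' Describes how a quantitative trait is generated at each developmental
#' stage: stage means, family mean deviations, QTL with per-stage
#' allele-substitution effects (classified as persistent, stage-specific or
#' sign-switching), epistatic marker pairs, a polygenic background, and the
#' non-genetic variance components of a multi-environment trial.
#'
#' All cross-stage dependence is explicit: the polygenic term, the
#' genotype-by-environment (GxE) deviations and the plot errors are each
#' drawn from a multivariate normal across stages with their own correlation
#' matrix, reflecting that the same lines and the same plots are scored
#' repeatedly as the crop develops.
#'
#' @param stages Stage labels, e.g. `c("DS1","DS2","DS3")`.
#' @param stage_means Population mean score per stage (BBCH-like units).
#' @param qtl Tibble with columns `marker`, `class` (one of `"persistent"`,
#'   `"stage_specific"`, `"sign_switching"`) and one effect column per stage.
#' @param epistasis Tibble with columns `marker_a`, `marker_b` and one
#'   interaction-effect column per stage (product coding of 0/1 genotypes).
#'   May have zero rows.
#' @param family_means Matrix (families x stages) of family mean deviations,
#'   or `NULL` for none.
#' @param sigma2_poly Per-stage polygenic variances (>= 0).
#' @param rho_poly Cross-stage correlation matrix of the polygenic term.
#' @param sigma2_gxe Per-stage GxE variances (>= 0).
#' @param rho_gxe Cross-stage correlation matrix of GxE deviations.
#' @param sigma2_eps Per-stage plot-error variances (>= 0).
#' @param rho_eps Cross-stage correlation matrix of plot errors.
#' @param n_env Number of environments (location-year combinations).
#' @param rep2_fraction Fraction of lines grown on a second plot per
#'   environment (partial replication).
#'
#' @return List of class `trait_architecture`.
#' @export
trait_architecture <- function(stages = c("DS1", "DS2", "DS3"),
                               stage_means = c(49, 69, 81),
                               qtl = NULL,
                               epistasis = NULL,
                               family_means = NULL,
                               sigma2_poly = rep(1, length(stages)),
                               rho_poly = diag(length(stages)),
                               sigma2_gxe = rep(0.5, length(stages)),
                               rho_gxe = diag(length(stages)),
                               sigma2_eps = rep(0.5, length(stages)),
                               rho_eps = diag(length(stages)),
                               n_env = 4,
                               rep2_fraction = 0.2) {
  t_n <- length(stages)
  if (length(stage_means) != t_n) abort("One stage mean per stage required.")
  for (v in list(sigma2_poly = sigma2_poly, sigma2_gxe = sigma2_gxe,
                 sigma2_eps = sigma2_eps)) {
    if (length(v) != t_n || any(v < 0)) {
      abort("Variance components must be non-negative, one per stage.")
    }
  }
  assert_number(n_env, "n_env", lower = 1, integer = TRUE)
  assert_number(rep2_fraction, "rep2_fraction", lower = 0, upper = 1)
  if (is.null(qtl)) {
    qtl <- tibble(marker = character(), class = character())
    for (s in stages) qtl[[s]] <- numeric()
  }
  qtl <- as_tibble(qtl)
  if (!all(c("marker", "class", stages) %in% names(qtl))) {
    abort("`qtl` needs columns marker, class and one effect column per stage.")
  }
  validate_qtl_classes(qtl, stages)
  if (is.null(epistasis)) {
    epistasis <- tibble(marker_a = character(), marker_b = character())
    for (s in stages) epistasis[[s]] <- numeric()
  }
  epistasis <- as_tibble(epistasis)
  if (!all(c("marker_a", "marker_b", stages) %in% names(epistasis))) {
    abort("`epistasis` needs marker_a, marker_b and per-stage effect columns.")
  }
  structure(
    list(stages = stages, stage_means = setNames(stage_means, stages),
         qtl = qtl, epistasis = epistasis, family_means = family_means,
         sigma2_poly = setNames(sigma2_poly, stages), rho_poly = rho_poly,
         sigma2_gxe = setNames(sigma2_gxe, stages), rho_gxe = rho_gxe,
         sigma2_eps = setNames(sigma2_eps, stages), rho_eps = rho_eps,
         n_env = as.integer(n_env), rep2_fraction = rep2_fraction),
    class = "trait_architecture"
  )
}

validate_qtl_classes <- function(qtl, stages) {
  if (nrow(qtl) == 0) return(invisible(qtl))
  eff <- as.matrix(qtl[, stages, drop = FALSE])
  for (i in seq_len(nrow(qtl))) {
    b <- eff[i, ]
    ok <- switch(
      qtl$class[i],
      persistent = all(b != 0),
      stage_specific = any(b == 0) && any(b != 0),
      sign_switching = any(b > 0) && any(b < 0),
      abort(sprintf("Unknown QTL class '%s'.", qtl$class[i]))
    )
    if (!ok) {
      abort(sprintf(
        "QTL '%s' effects (%s) are inconsistent with class '%s'.",
        qtl$marker[i], paste(b, collapse = ", "), qtl$class[i]
      ))
    }
  }
  invisible(qtl)
}

# covariance from per-stage variances and a correlation matrix
cov_from <- function(sigma2, rho) {
  d <- sqrt(sigma2)
  sig <- diag(d, length(d)) %*% rho %*% diag(d, length(d))
  (sig + t(sig)) / 2
}

# multivariate normal sampler tolerant of semi-definite covariance
rmvn <- function(n, sigma) {
  t_n <- ncol(sigma)
  if (all(sigma == 0)) return(matrix(0, n, t_n))
  ev <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  z <- matrix(stats::rnorm(n * t_n), n, t_n)
  z %*% (t(ev$vectors) * sqrt(vals))
}

#' Simulate plot-level phenotypes from genotypes and an architecture
#'
#' Generates a plot-level phenotype table for a multi-environment trial with
#' partial replication. For line i, environment j and stage t the observation
#' is
#' \deqn{y_{ijt} = m_t + f_{(i)t} + \sum_q x_{iq} b_q(t) +
#'   \sum_{(q,q')} x_{iq} x_{iq'} b_{qq'}(t) + u_{i}(t) + g_{ij}(t) +
#'   e_{ijt},}
#' with stage mean \eqn{m_t}, family deviation \eqn{f}, QTL and epistatic
#' effects, polygenic term \eqn{u}, GxE deviation \eqn{g} and plot error
#' \eqn{e}, the last three multivariate normal across stages.
#'
#' @param genotypes Genotype tibble (no missing calls at architecture
#'   markers).
#' @param arch A [trait_architecture()].
#' @param seed Integer seed.
#' @param round_scores Round observations to whole BBCH-like codes
#'   (default off: the scan models assume a continuous response).
#'
#' @return Tibble with columns `line`, `family`, `env`, `rep` and one column
#'   per stage. The per-line true genetic values (stage mean + family + QTL +
#'   epistasis + polygenic) are attached as attribute `"genetic_values"`,
#'   retrievable with [genetic_values()].
#' @export
sim_phenotypes <- function(genotypes, arch, seed = 1, round_scores = FALSE) {
  stopifnot(inherits(arch, "trait_architecture"))
  stages <- arch$stages
  mk <- marker_cols(genotypes)
  need <- unique(c(arch$qtl$marker, arch$epistasis$marker_a,
                   arch$epistasis$marker_b))
  missing_mk <- setdiff(need, mk)
  if (length(missing_mk) > 0) {
    abort(sprintf("Architecture markers absent from genotypes: %s.",
                  paste(missing_mk, collapse = ", ")))
  }
  n <- nrow(genotypes)
  t_n <- length(stages)

  seeds <- derive_seeds(seed, 4, c("poly", "gxe", "eps", "design"))
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  # genetic values per line x stage
  g <- matrix(rep(arch$stage_means, each = n), n, t_n,
              dimnames = list(genotypes$line, stages))
  if (!is.null(arch$family_means)) {
    fm <- arch$family_means
    fam_idx <- match(genotypes$family, rownames(fm))
    if (anyNA(fam_idx)) abort("family_means rows must cover all families.")
    g <- g + fm[fam_idx, , drop = FALSE]
  }
  if (nrow(arch$qtl) > 0) {
    x <- genotype_matrix(genotypes, arch$qtl$marker)
    if (anyNA(x)) abort("Missing genotype calls at QTL markers.")
    g <- g + x %*% as.matrix(arch$qtl[, stages, drop = FALSE])
  }
  if (nrow(arch$epistasis) > 0) {
    xa <- genotype_matrix(genotypes, arch$epistasis$marker_a)
    xb <- genotype_matrix(genotypes, arch$epistasis$marker_b)
    if (anyNA(xa) || anyNA(xb)) abort("Missing genotype calls at QTL markers.")
    g <- g + (xa * xb) %*% as.matrix(arch$epistasis[, stages, drop = FALSE])
  }
  set.seed(seeds[["poly"]])
  g <- g + rmvn(n, cov_from(arch$sigma2_poly, arch$rho_poly))

  # trial layout: one plot per line and environment, plus a second plot for a
  # random fraction of lines (partial replication)
  set.seed(seeds[["design"]])
  envs <- sprintf("E%d", seq_len(arch$n_env))
  n2 <- round(arch$rep2_fraction * n)
  layout <- purrr::map_dfr(envs, function(e) {
    twice <- if (n2 > 0) sample.int(n, n2) else integer()
    tibble(idx = c(seq_len(n), twice), env = e,
           rep = c(rep(1L, n), rep(2L, length(twice))))
  })

  set.seed(seeds[["gxe"]])
  ge <- rmvn(n * arch$n_env, cov_from(arch$sigma2_gxe, arch$rho_gxe))
  cell <- (match(layout$env, envs) - 1L) * n + layout$idx

  set.seed(seeds[["eps"]])
  eps <- rmvn(nrow(layout), cov_from(arch$sigma2_eps, arch$rho_eps))

  y <- g[layout$idx, , drop = FALSE] + ge[cell, , drop = FALSE] + eps
  if (round_scores) y <- round(y)
  colnames(y) <- stages

  out <- bind_cols(
    tibble(line = genotypes$line[layout$idx],
           family = genotypes$family[layout$idx],
           env = layout$env, rep = layout$rep),
    as_tibble(y)
  ) |>
    arrange(.data$env, .data$line, .data$rep)
  gv <- bind_cols(tibble(line = genotypes$line, family = genotypes$family),
                  as_tibble(g))
  attr(out, "genetic_values") <- gv
  out
}

#' True genetic values attached to a simulated phenotype table
#'
#' @param phenotypes Result of [sim_phenotypes()].
#' @return Tibble `line`, `family`, one column of true genetic values per
#'   stage.
#' @export
genetic_values <- function(phenotypes) {
  gv <- attr(phenotypes, "genetic_values")
  if (is.null(gv)) abort("No genetic values attached to this table.")
  gv
}
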