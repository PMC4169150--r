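#' Proportion of genotypic variance explained by detected QTL
#'
#' Fits `Y = mu + family + all markers` simultaneously on complete cases and
#' reports the adjusted coefficient of determination of the marker terms
#' beyond the family-only baseline,
#' \deqn{R^2_{adj} = 1 - (1 - R^2_\Delta) (n - F) / (n - F - k),}
#' where \eqn{R^2_\Delta = (RSS_{family} - RSS_{full}) / RSS_{family}}, F is
#' the number of families and k the number of markers fitted. The proportion
#' of genotypic variance is \eqn{p_G = 100 R^2_{adj} / h^2} (percent).
#' Values above 100 are flagged with a warning, not clamped: the upward bias
#' of in-sample \eqn{p_G} is exactly what cross-validation (see [run_cv()])
#' quantifies. Collinear markers are dropped in fit order and recorded.
#'
#' @param blues BLUE tibble (`line`, `family`, response column).
#' @param genotypes Genotype tibble.
#' @param markers Markers to fit (fit order = given order).
#' @param h2 Entry-mean heritability in (0, 1] for this stage (estimated
#'   upstream, never re-estimated here).
#' @param response Name of the response column.
#'
#' @return One-row tibble: `n`, `n_families`, `k` (markers fitted),
#'   `r2_delta`, `r2_adj`, `h2`, `p_G` (percent); attribute `dropped`
#'   (collinear markers excluded from the fit).
#' @export
proportion_genotypic_variance <- function(blues, genotypes, markers, h2,
                                          response = "blue") {
  assert_number(h2, "h2", lower = 1e-12, upper = 1)
  if (length(markers) == 0) abort("Marker set must be non-empty.")
  al <- align_genotypes(blues, genotypes, response)
  miss <- setdiff(markers, colnames(al$x))
  if (length(miss) > 0) {
    abort(sprintf("Markers absent from genotypes: %s.",
                  paste(miss, collapse = ", ")))
  }
  xm <- al$x[, markers, drop = FALSE]
  cc <- stats::complete.cases(xm)
  y <- al$y[cc]
  xm <- xm[cc, , drop = FALSE]
  base <- family_design(droplevels(al$family[cc]))
  n <- length(y)
  n_fam <- ncol(base)

  # drop collinear markers in fit order
  kept <- character()
  x_cur <- base
  rank_cur <- qr(x_cur)$rank
  dropped <- character()
  for (mk in markers) {
    x_try <- cbind(x_cur, xm[, mk])
    r_try <- qr(x_try)$rank
    if (r_try > rank_cur) {
      kept <- c(kept, mk)
      x_cur <- x_try
      rank_cur <- r_try
    } else {
      dropped <- c(dropped, mk)
    }
  }
  k <- length(kept)
  if (n - n_fam - k < 1) abort("Too few complete-case lines for this fit.")
  rss_fam <- ls_fit(base, y)$rss
  rss_full <- ls_fit(x_cur, y)$rss
  r2_delta <- if (rss_fam > 0) (rss_fam - rss_full) / rss_fam else 0
  r2_adj <- 1 - (1 - r2_delta) * (n - n_fam) / (n - n_fam - k)
  p_g <- 100 * r2_adj / h2
  if (p_g > 100) {
    warn(sprintf("p_G = %.1f%% exceeds 100%% (R2adj > h2); reported unclamped.",
                 p_g))
  }
  structure(
    tibble(n = n, n_families = n_fam, k = k, r2_delta = r2_delta,
           r2_adj = r2_adj, h2 = h2, p_G = p_g),
    dropped = dropped
  )
}

#' Sequential partial R-squared of detected QTL
#'
#' Enters markers into the model `Y = mu + family + markers` one at a time in
#' the order of the strength of their association (smallest scan p-value
#' first; ties broken by map order) and reports each marker's sequential
#' share \eqn{(RSS_{i-1} - RSS_i) / RSS_{family}} of the family-adjusted
#' variation, so that collinearity among detected QTL is credited to the more
#' strongly associated marker. The unadjusted shares sum to the simultaneous
#' fit's \eqn{R^2_\Delta}; each share is also converted to p_G units by
#' scaling proportionally with the adjusted-R2/heritability factor of
#' [proportion_genotypic_variance()].
#'
#' @param blues BLUE tibble.
#' @param genotypes Genotype tibble.
#' @param marker_p Tibble with columns `marker` and `p` (scan p-values).
#' @param h2 Entry-mean heritability in (0, 1].
#' @param map Optional map for the tie-break order (defaults to the order of
#'   `marker_p`).
#' @param response Name of the response column.
#'
#' @return Tibble, one row per fitted marker in fit order: `marker`, `p`,
#'   `beta` (effect in the simultaneous fit), `seq_r2` (unadjusted share),
#'   `pg_share` (percent of genotypic variance); attribute `account` = the
#'   [proportion_genotypic_variance()] row.
#' @export
sequential_partial_r2 <- function(blues, genotypes, marker_p, h2, map = NULL,
                                  response = "blue") {
  marker_p <- as_tibble(marker_p)
  if (!all(c("marker", "p") %in% names(marker_p))) {
    abort("`marker_p` needs columns marker and p.")
  }
  ord <- if (!is.null(map)) match(marker_p$marker, map$marker)
         else seq_len(nrow(marker_p))
  marker_p <- marker_p[order(marker_p$p, ord), ]
  markers <- marker_p$marker

  account <- proportion_genotypic_variance(blues, genotypes, markers, h2,
                                           response = response)
  al <- align_genotypes(blues, genotypes, response)
  xm <- al$x[, markers, drop = FALSE]
  cc <- stats::complete.cases(xm)
  y <- al$y[cc]
  xm <- xm[cc, , drop = FALSE]
  base <- family_design(droplevels(al$family[cc]))

  rss_fam <- ls_fit(base, y)$rss
  rss_prev <- rss_fam
  x_cur <- base
  seq_r2 <- numeric(length(markers))
  for (i in seq_along(markers)) {
    x_cur <- cbind(x_cur, xm[, i])
    rss_i <- ls_fit(x_cur, y)$rss
    seq_r2[i] <- if (rss_fam > 0) (rss_prev - rss_i) / rss_fam else 0
    rss_prev <- rss_i
  }
  fit_full <- ls_fit(x_cur, y)
  betas <- fit_full$coef[ncol(base) + seq_along(markers)]
  scale <- if (account$r2_delta > 0) account$r2_adj / account$r2_delta else 0
  structure(
    tibble(marker = markers, p = marker_p$p, beta = betas,
           seq_r2 = seq_r2, pg_share = 100 * seq_r2 * scale / h2),
    account = account
  )
}

#' Temporal profile of per-region explained genotypic variance
#'
#' For the union of QTL regions detected at any stage, computes each region's
#' sequential p_G share at every stage, yielding the temporal trajectory of
#' its contribution to the genotypic variance. At each stage a region is
#' represented by its member marker with the smallest scan p-value at that
#' stage; regions whose representative is monomorphic or untested at a stage
#' get share 0 (flagged in `estimable`).
#'
#' @param matches Region match table from [match_regions()].
#' @param scans Named list of `qtl_scan` results, one per stage (all tested
#'   markers, not only significant ones).
#' @param blues_wide Wide BLUE tibble with one column per stage.
#' @param genotypes Genotype tibble.
#' @param h2 Named vector of heritabilities per stage.
#'
#' @return Long tibble: `region`, `stage`, `marker`, `p`, `pg_share`,
#'   `estimable`.
#' @export
temporal_pg_profile <- function(matches, scans, blues_wide, genotypes, h2) {
  stages <- names(scans)
  if (is.null(stages) || !all(stages %in% names(blues_wide))) {
    abort("`scans` must be a named list with stages matching `blues_wide`.")
  }
  if (!all(stages %in% names(h2))) abort("`h2` must be named by stage.")
  members <- attr(matches, "members")
  if (is.null(members)) abort("`matches` must come from match_regions().")

  purrr::map_dfr(stages, function(s) {
    sc <- scans[[s]]
    # one representative per region: the member with the smallest p at this
    # stage (regions untested at this stage keep a placeholder with p = NA)
    reps <- members |>
      select(all_of(c("region", "marker"))) |>
      distinct() |>
      left_join(sc[, c("marker", "p")], by = "marker") |>
      group_by(.data$region) |>
      arrange(.data$p, .by_group = TRUE) |>
      filter(row_number() == 1) |>
      ungroup()
    testable <- reps |> filter(!is.na(.data$p))
    blues_s <- blues_wide[, c("line", "family", s)]
    names(blues_s)[3] <- "blue"
    if (nrow(testable) > 0) {
      shares <- sequential_partial_r2(
        blues_s, genotypes,
        marker_p = testable[, c("marker", "p")], h2 = unname(h2[s])
      )
      reps <- left_join(reps, shares[, c("marker", "pg_share")],
                        by = "marker")
    } else {
      reps$pg_share <- NA_real_
    }
    reps |>
      mutate(stage = s,
             estimable = !is.na(.data$pg_share) & !is.na(.data$p),
             pg_share = ifelse(is.na(.data$pg_share), 0, .data$pg_share)) |>
      select(all_of(c("region", "stage", "marker", "p", "pg_share",
                      "estimable")))
  })
}
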