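#' Region-pair Bonferroni threshold for epistasis scans
#'
#' Divides the significance level by the number of possible independent
#' pairwise interactions between chromosome regions, assuming two separate
#' regions per linkage group: `alpha / choose(2 L, 2)`. With L = 22 groups
#' and alpha = 0.05 this gives 0.05 / 946 = 5.3e-5 (2 significant digits).
#'
#' @param n_groups Number of linkage groups L (>= 1).
#' @param alpha Genome-wide significance level.
#' @return The per-pair significance threshold.
#' @export
#' @examples
#' epistasis_threshold(22)        # ~5.3e-5
#' epistasis_threshold(1)         # 0.05: a single region pair
epistasis_threshold <- function(n_groups, alpha = 0.05) {
  assert_number(n_groups, "n_groups", lower = 1, integer = TRUE)
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  alpha / choose(2 * n_groups, 2)
}

# thin a map to at most one marker per `thin_cM` bin per group (bin
# representative = first marker in the bin)
thin_markers <- function(map, thin_cM) {
  if (thin_cM <= 0) return(map$marker)
  keep <- map |>
    group_by(.data$group) |>
    mutate(bin = floor(.data$pos_cM / thin_cM)) |>
    filter(!duplicated(.data$bin)) |>
    ungroup()
  keep$marker
}

#' Two-dimensional scan for epistatic (marker-pair interaction) QTL
#'
#' For every unordered pair of polymorphic markers, fits
#' `Y = mu + family + b_q x_q + b_q' x_q' + b_qq' (x_q x_q')` against the
#' same model without the interaction term and tests the interaction with a
#' 1-df F test on complete-case lines. Pairs for which fewer than all four
#' two-locus genotype classes are observed, or whose interaction column is
#' collinear with the main effects, are inestimable and skipped (counted in
#' the metadata). Cofactors are not included by default; pass markers in
#' `cofactors` to add them to both models.
#'
#' @param blues BLUE tibble (`line`, `family`, response column).
#' @param genotypes Genotype tibble.
#' @param map Genetic map.
#' @param threshold Per-pair significance threshold; defaults to
#'   [epistasis_threshold()] with L taken from the map.
#' @param alpha Genome-wide level used when `threshold` is `NULL`.
#' @param thin_cM Optional thinning: test only one marker per `thin_cM`
#'   bin per group (0 = all markers).
#' @param cofactors Optional cofactor markers added to both models (excluding
#'   any identical to a tested marker of the pair).
#' @param keep When `"significant"` (default) the result holds only pairs
#'   below the threshold; `"all"` returns every tested pair.
#' @param response Name of the response column.
#' @param stage Optional stage label stored in the result.
#'
#' @return An `epi_scan` tibble: `marker_a`, `marker_b`, their groups and
#'   positions, `n`, main-effect estimates `beta_a`, `beta_b`, interaction
#'   effect `beta_ab`, `f`, `p`, `significant`; attributes `threshold`,
#'   `n_groups`, `n_pairs_tested`, `n_pairs_skipped`, `stage`.
#' @export
scan_pairs <- function(blues, genotypes, map, threshold = NULL, alpha = 0.05,
                       thin_cM = 0, cofactors = character(),
                       keep = c("significant", "all"),
                       response = "blue", stage = NULL) {
  keep <- match.arg(keep)
  validate_map(map)
  n_groups <- length(unique(map$group))
  threshold <- threshold %||% epistasis_threshold(n_groups, alpha)
  al <- align_genotypes(blues, genotypes, response)
  y <- al$y
  markers <- intersect(thin_markers(map, thin_cM), colnames(al$x))
  x <- al$x[, markers, drop = FALSE]
  # polymorphic markers only
  poly <- apply(x, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) > 1
  })
  markers <- markers[poly]
  if (length(markers) < 2) abort("Need at least two polymorphic markers.")
  x <- x[, markers, drop = FALSE]
  base <- family_design(al$family)
  xc <- if (length(cofactors) > 0) al$x[, cofactors, drop = FALSE] else NULL

  pairs <- utils::combn(length(markers), 2)
  n_pairs <- ncol(pairs)
  out <- vector("list", n_pairs)
  n_skipped <- 0L
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    xa <- x[, i]
    xb <- x[, j]
    cof_k <- character()
    if (!is.null(xc)) {
      cof_k <- setdiff(cofactors, c(markers[i], markers[j]))
    }
    cc <- !is.na(xa) & !is.na(xb)
    if (length(cof_k) > 0) {
      cc <- cc & stats::complete.cases(xc[, cof_k, drop = FALSE])
    }
    n_cc <- sum(cc)
    if (n_cc < 6 ||
        nrow(unique(cbind(xa[cc], xb[cc]))) < 4) {
      n_skipped <- n_skipped + 1L
      next
    }
    x_red <- cbind(base[cc, , drop = FALSE], xa = xa[cc], xb = xb[cc])
    if (length(cof_k) > 0) x_red <- cbind(x_red, xc[cc, cof_k, drop = FALSE])
    x_full <- cbind(x_red, xab = xa[cc] * xb[cc])
    fit_red <- ls_fit(x_red, y[cc])
    fit_full <- ls_fit(x_full, y[cc])
    if (fit_full$rank != fit_red$rank + 1L ||
        n_cc - fit_full$rank < 1) {
      n_skipped <- n_skipped + 1L
      next
    }
    yc <- y[cc]
    ft <- nested_f_test(fit_red$rss, fit_full$rss, 1, n_cc - fit_full$rank,
                        tss = sum((yc - mean(yc))^2))
    cf <- fit_full$coef
    nb <- ncol(base)
    out[[k]] <- tibble(
      marker_a = markers[i], marker_b = markers[j], n = n_cc,
      beta_a = cf[nb + 1], beta_b = cf[nb + 2],
      beta_ab = cf[length(cf)], f = ft$f, p = ft$p
    )
  }
  res <- bind_rows(out)
  n_tested <- nrow(res)
  if (n_tested > 0) {
    res$significant <- res$p < threshold
    res <- res |>
      mutate(
        group_a = map$group[match(.data$marker_a, map$marker)],
        pos_a = map$pos_cM[match(.data$marker_a, map$marker)],
        group_b = map$group[match(.data$marker_b, map$marker)],
        pos_b = map$pos_cM[match(.data$marker_b, map$marker)]
      ) |>
      select(all_of(c("marker_a", "group_a", "pos_a",
                      "marker_b", "group_b", "pos_b", "n",
                      "beta_a", "beta_b", "beta_ab", "f", "p",
                      "significant")))
    if (keep == "significant") res <- filter(res, .data$significant)
  } else {
    res <- tibble(marker_a = character(), group_a = character(),
                  pos_a = numeric(), marker_b = character(),
                  group_b = character(), pos_b = numeric(), n = integer(),
                  beta_a = numeric(), beta_b = numeric(),
                  beta_ab = numeric(), f = numeric(), p = numeric(),
                  significant = logical())
  }
  structure(res, threshold = threshold, n_groups = n_groups,
            n_pairs_tested = n_tested, n_pairs_skipped = n_skipped,
            stage = stage %||% attr(blues, "stage"),
            class = c("epi_scan", class(res)))
}
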