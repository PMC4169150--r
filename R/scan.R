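#' Bonferroni-Holm step-down correction
#'
#' Flags hypotheses significant at family-wise level `alpha` by the Holm
#' step-down rule: p-values are sorted ascending and the i-th smallest is
#' rejected while \eqn{p_{(i)} \le \alpha / (m - i + 1)}; the procedure stops
#' at the first failure. Rejections are always a superset of the plain
#' Bonferroni rule at the same level.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param alpha Family-wise error level.
#' @return Logical vector of rejection flags in the original order (empty
#'   input gives an empty output). `NA` p-values are never rejected and do
#'   not count towards m.
#' @export
#' @examples
#' holm_correct(c(0.001, 0.02, 0.04), alpha = 0.05)  # all TRUE
#' holm_correct(c(0.001, 0.03, 0.04), alpha = 0.05)  # only the first
holm_correct <- function(p, alpha = 0.05) {
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  if (length(p) == 0) return(logical(0))
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) abort("p-values must be in (0, 1].")
  m <- sum(ok)
  flags <- rep(FALSE, length(p))
  if (m == 0) return(flags)
  idx <- which(ok)[order(p[ok])]
  ps <- p[idx]
  thresh <- alpha / (m - seq_len(m) + 1)
  fail <- which(ps > thresh)
  n_rej <- if (length(fail) == 0) m else fail[1] - 1
  if (n_rej > 0) flags[idx[seq_len(n_rej)]] <- TRUE
  flags
}

# Align a genotype tibble to the lines of a BLUE tibble and return the
# numeric marker matrix plus the family factor.
align_genotypes <- function(blues, genotypes, response = "blue") {
  if (!response %in% names(blues)) {
    abort(sprintf("Response column '%s' not found.", response))
  }
  idx <- match(blues$line, genotypes$line)
  if (anyNA(idx)) {
    abort(sprintf("Lines missing from genotypes: %s.",
                  paste(head(blues$line[is.na(idx)], 5), collapse = ", ")))
  }
  g <- genotypes[idx, , drop = FALSE]
  keep <- !is.na(blues[[response]])
  list(
    y = blues[[response]][keep],
    family = factor(blues$family[keep]),
    x = genotype_matrix(g)[keep, , drop = FALSE]
  )
}

# intercept + family treatment contrasts (rank F); single-family data reduce
# to the intercept
family_design <- function(family) {
  f <- factor(family)
  if (nlevels(f) < 2) {
    matrix(1, length(f), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ f)
  }
}

sbc_value <- function(rss, n, k) n * log(rss / n) + k * log(n)

#' Stepwise cofactor selection by the Schwarz Bayesian Criterion
#'
#' Forward-backward stepwise multiple linear regression over markers,
#' minimising \eqn{SBC = n \ln(RSS/n) + k \ln(n)} (k = fitted parameters
#' including intercept and family effects). Family effects are always in the
#' model. The search is deterministic: at each forward step the candidate
#' with the lowest SBC enters (ties broken by smaller p-value, then map
#' order); after every insertion, backward elimination removes cofactors
#' whose deletion lowers the SBC. An empty set is a valid result when no
#' marker improves the criterion.
#'
#' Missing genotype calls are replaced by the family-mean allele dose for
#' the selection only (the scan itself refits complete-case per marker), so
#' the criterion compares all candidates on identical observations.
#'
#' @param blues BLUE tibble (`line`, `family`, response column).
#' @param genotypes Genotype tibble.
#' @param response Name of the response column (default `"blue"`).
#' @param max_cofactors Hard cap on the number of selected cofactors.
#' @return Character vector of selected markers in selection order, with the
#'   SBC trace as attribute `"trace"`.
#' @export
select_cofactors <- function(blues, genotypes, response = "blue",
                             max_cofactors = 100) {
  al <- align_genotypes(blues, genotypes, response)
  y <- al$y
  n <- length(y)
  n_fam <- nlevels(al$family)
  if (n <= n_fam + 2) abort("Too few lines for cofactor selection.")

  x <- al$x
  # family-mean imputation (selection only)
  if (anyNA(x)) {
    for (f in levels(al$family)) {
      rows <- al$family == f
      mu <- colMeans(x[rows, , drop = FALSE], na.rm = TRUE)
      xi <- x[rows, , drop = FALSE]
      na_at <- which(is.na(xi), arr.ind = TRUE)
      if (nrow(na_at) > 0) xi[na_at] <- mu[na_at[, 2]]
      x[rows, ] <- xi
    }
    x[is.na(x)] <- 0  # markers entirely missing within a family
  }
  # drop monomorphic markers
  poly <- apply(x, 2, function(col) length(unique(col)) > 1)
  x <- x[, poly, drop = FALSE]

  base <- family_design(al$family)
  selected <- character()
  trace <- list()

  current_sbc <- function(sel) {
    fit <- ls_fit(cbind(base, x[, sel, drop = FALSE]), y)
    sbc_value(fit$rss, n, fit$rank)
  }
  sbc_now <- current_sbc(selected)

  repeat {
    if (length(selected) >= max_cofactors) break
    xm <- cbind(base, x[, selected, drop = FALSE])
    qr_m <- qr(xm)
    k_now <- qr_m$rank
    r <- qr.resid(qr_m, y)
    rss0 <- sum(r * r)
    cand <- setdiff(colnames(x), selected)
    if (length(cand) == 0) break
    e <- qr.resid(qr_m, x[, cand, drop = FALSE])
    ete <- colSums(e * e)
    etr <- colSums(e * r)
    drop_rss <- ifelse(ete > 1e-10, etr^2 / ete, 0)
    rss_new <- pmax(rss0 - drop_rss, 0)
    sbc_new <- sbc_value(pmax(rss_new, 1e-300), n, k_now + 1)
    best <- min(sbc_new)
    if (best >= sbc_now - 1e-9) break
    # ties: largest RSS drop (= smallest p at equal df), then map order
    tied <- which(sbc_new <= best + 1e-9)
    pick <- tied[order(-drop_rss[tied])][1]
    selected <- c(selected, cand[pick])
    sbc_now <- current_sbc(selected)
    trace[[length(trace) + 1]] <-
      tibble(step = length(trace) + 1L, action = "add",
             marker = cand[pick], sbc = sbc_now)

    # backward elimination
    repeat {
      if (length(selected) <= 1) break
      sbc_minus <- vapply(seq_along(selected), function(i) {
        current_sbc(selected[-i])
      }, numeric(1))
      if (min(sbc_minus) >= sbc_now - 1e-9) break
      i_drop <- which.min(sbc_minus)
      dropped <- selected[i_drop]
      selected <- selected[-i_drop]
      sbc_now <- sbc_minus[i_drop]
      trace[[length(trace) + 1]] <-
        tibble(step = length(trace) + 1L, action = "drop",
               marker = dropped, sbc = sbc_now)
    }
  }
  structure(selected, trace = bind_rows(trace))
}

#' Multi-family association scan for main-effect QTL
#'
#' For each polymorphic marker q, tests the allele-substitution effect with
#' an F test of the full model
#' `Y = mu + family + cofactors + b_q x_q` against the reduced model without
#' the marker term, on the lines complete for q and the active cofactors.
#' Cofactors are excluded from a marker's fit when they are the marker
#' itself, genotypically identical to it, or within `cofactor_window_cM` of
#' it on the same linkage group (window 0 reproduces the literal c != q
#' rule). Markers with identical genotype columns are collapsed to one
#' representative whose statistics the duplicates inherit. Significance is
#' declared by the Bonferroni-Holm procedure over the markers actually
#' tested.
#'
#' @param blues BLUE tibble (`line`, `family`, response column).
#' @param genotypes Genotype tibble.
#' @param map Genetic map tibble (`marker`, `group`, `pos_cM`).
#' @param cofactors Character vector from [select_cofactors()] (may be
#'   empty).
#' @param alpha Family-wise error level for the Holm correction.
#' @param cofactor_window_cM Exclusion window around the tested marker.
#' @param response Name of the response column.
#' @param stage Optional stage label stored in the result.
#'
#' @return A `qtl_scan` tibble: `marker`, `group`, `pos_cM`, `n`, `beta`
#'   (allele-substitution effect on the 0/1 coding, reference allele 0),
#'   `f`, `p`, `significant`, `duplicate_of`; attributes `alpha`, `m`
#'   (markers tested), `cofactors`, `stage`, `skipped`.
#' @export
scan_markers <- function(blues, genotypes, map, cofactors = character(),
                         alpha = 0.05, cofactor_window_cM = 10,
                         response = "blue", stage = NULL) {
  validate_map(map)
  assert_number(cofactor_window_cM, "cofactor_window_cM", lower = 0)
  al <- align_genotypes(blues, genotypes, response)
  y <- al$y
  x <- al$x
  markers <- intersect(map$marker, colnames(x))
  if (length(markers) == 0) abort("No mapped markers in the genotypes.")
  x <- x[, markers, drop = FALSE]
  map_i <- map[match(markers, map$marker), ]
  base <- family_design(al$family)
  missing_cof <- setdiff(cofactors, markers)
  if (length(missing_cof) > 0) {
    abort(sprintf("Cofactors absent from mapped genotypes: %s.",
                  paste(missing_cof, collapse = ", ")))
  }

  # collapse duplicate genotype columns (incl. NA pattern)
  sig <- apply(x, 2, paste, collapse = "\r")
  rep_of <- markers[match(sig, sig)]
  is_rep <- rep_of == markers

  cof_group <- map$group[match(cofactors, map$marker)]
  cof_pos <- map$pos_cM[match(cofactors, map$marker)]

  res <- vector("list", length(markers))
  skipped <- character()
  for (i in seq_along(markers)) {
    if (!is_rep[i]) next
    q <- markers[i]
    xq <- x[, i]
    active <- cofactors
    if (length(active) > 0) {
      same_window <- cof_group == map_i$group[i] &
        abs(cof_pos - map_i$pos_cM[i]) <= cofactor_window_cM
      identical_col <- rep_of[match(active, markers)] == rep_of[i]
      active <- active[!(active == q | same_window | identical_col)]
    }
    cc <- !is.na(xq)
    if (length(active) > 0) {
      cc <- cc & stats::complete.cases(x[, active, drop = FALSE])
    }
    n_i <- sum(cc)
    xq_cc <- xq[cc]
    if (n_i < 3 || length(unique(xq_cc)) < 2) {
      skipped <- c(skipped, q)
      next
    }
    x_red <- cbind(base[cc, , drop = FALSE],
                   x[cc, active, drop = FALSE])
    fit_red <- ls_fit(x_red, y[cc])
    fit_full <- ls_fit(cbind(x_red, xq = xq_cc), y[cc])
    df_den <- n_i - fit_full$rank
    if (df_den < 1) {
      warn(sprintf("Marker '%s' skipped: no residual degrees of freedom.", q))
      skipped <- c(skipped, q)
      next
    }
    yc <- y[cc]
    ft <- nested_f_test(fit_red$rss, fit_full$rss,
                        df_num = 1, df_den = df_den,
                        tss = sum((yc - mean(yc))^2))
    beta <- fit_full$coef[length(fit_full$coef)]
    res[[i]] <- tibble(marker = q, n = n_i, beta = beta,
                       f = ft$f, p = ft$p)
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) abort("No testable markers.")
  out$significant <- holm_correct(out$p, alpha)
  m_tested <- nrow(out)

  # duplicates inherit the representative's statistics
  dup <- tibble(marker = markers[!is_rep],
                duplicate_of = rep_of[!is_rep]) |>
    filter(.data$duplicate_of %in% out$marker)
  if (nrow(dup) > 0) {
    inherited <- out[match(dup$duplicate_of, out$marker),
                     c("n", "beta", "f", "p", "significant")]
    dup <- bind_cols(dup, inherited)
    out$duplicate_of <- NA_character_
    out <- bind_rows(out, dup)
  } else {
    out$duplicate_of <- NA_character_
  }
  out <- out |>
    left_join(map_i, by = "marker") |>
    select(all_of(c("marker", "group", "pos_cM", "n", "beta", "f", "p",
                    "significant", "duplicate_of"))) |>
    arrange(match(.data$marker, map$marker))

  structure(out, alpha = alpha, m = m_tested, cofactors = cofactors,
            stage = stage %||% attr(blues, "stage"),
            skipped = skipped,
            class = c("qtl_scan", class(out)))
}

#' One-call association scan (cofactor selection + marker scan)
#'
#' Convenience wrapper running [select_cofactors()] then [scan_markers()].
#'
#' @inheritParams scan_markers
#' @return A `qtl_scan` tibble (see [scan_markers()]).
#' @export
association_scan <- function(blues, genotypes, map, alpha = 0.05,
                             cofactor_window_cM = 10, response = "blue",
                             stage = NULL) {
  cof <- select_cofactors(blues, genotypes, response = response)
  scan_markers(blues, genotypes, map, cofactors = as.character(cof),
               alpha = alpha, cofactor_window_cM = cofactor_window_cM,
               response = response, stage = stage)
}
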