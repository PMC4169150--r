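#' Fivefold cross-validation of the QTL detection pipeline
#'
#' Quantifies the model-selection optimism of in-sample explained-variance
#' estimates. Per run, lines are split into `folds` subsets stratified by
#' family; for each fold the remaining lines form the estimation set (ES),
#' which undergoes the full detection pipeline (cofactor selection, marker
#' scan, Holm correction) and yields an in-sample p_G (via
#' [proportion_genotypic_variance()] with ES-estimated effects). The held-out
#' test set (TS) p_G is the adjusted squared correlation between the
#' ES-model predictions (family mean + sum of marker effects) and the
#' observed TS BLUEs, divided by the same h2; negative values are clamped to
#' zero. Folds whose ES scan finds no QTL contribute zeros (counted, not
#' dropped). The relative bias, 100 (p_G-ES - p_G-TS) / p_G-ES, is computed
#' from the aggregated means.
#'
#' The heritability is estimated once on the full data and reused in every
#' fold, so the cross-validation isolates the genotypic model selection.
#'
#' @param blues BLUE tibble (`line`, `family`, response column).
#' @param genotypes Genotype tibble.
#' @param map Genetic map.
#' @param h2 Entry-mean heritability for this stage.
#' @param runs Number of independent fold assignments.
#' @param folds Number of folds (>= 2); every family must have at least
#'   `folds` lines.
#' @param seed Integer seed; same seed, same splits, same summaries.
#' @param alpha Family-wise level of the Holm correction.
#' @param cofactor_window_cM Cofactor exclusion window for the scans.
#' @param ts_estimator `"adjusted_cor"` (default): squared
#'   prediction-observation correlation adjusted for the single predictor;
#'   `"squared_cor"`: unadjusted.
#' @param response Name of the response column.
#'
#' @return Object of class `qtl_cv`: list with `summary` (one-row tibble:
#'   `stage`, `qtl_ds`, `pg_ds`, `qtl_es`, `pg_es`, `pg_ts`,
#'   `relative_bias`, `runs`, `folds`), `detections` (per-marker count of ES
#'   scans declaring it significant), `fold_results` (per run x fold),
#'   `scan_full` (the full-data scan).
#' @export
run_cv <- function(blues, genotypes, map, h2, runs = 20, folds = 5, seed = 1,
                   alpha = 0.05, cofactor_window_cM = 10,
                   ts_estimator = c("adjusted_cor", "squared_cor"),
                   response = "blue") {
  ts_estimator <- match.arg(ts_estimator)
  assert_number(folds, "folds", lower = 2, integer = TRUE)
  assert_number(runs, "runs", lower = 1, integer = TRUE)
  assert_number(h2, "h2", lower = 1e-12, upper = 1)
  fam_sizes <- table(blues$family)
  if (any(fam_sizes < folds)) {
    abort("Every family needs at least `folds` lines.")
  }

  # full-data pipeline
  scan_full <- association_scan(blues, genotypes, map, alpha = alpha,
                                cofactor_window_cM = cofactor_window_cM,
                                response = response)
  sig_full <- scan_full$marker[scan_full$significant &
                                 is.na(scan_full$duplicate_of)]
  qtl_ds <- length(sig_full)
  pg_ds <- if (qtl_ds > 0) {
    proportion_genotypic_variance(blues, genotypes, sig_full, h2,
                                  response = response)$p_G
  } else 0

  run_seeds <- derive_seeds(seed, runs)
  fold_results <- list()
  detect_counts <- setNames(rep(0L, nrow(map)), map$marker)

  for (r in seq_len(runs)) {
    fold_id <- stratified_folds(blues$family, folds, run_seeds[r])
    for (k in seq_len(folds)) {
      es <- blues[fold_id != k, , drop = FALSE]
      ts <- blues[fold_id == k, , drop = FALSE]
      scan_es <- association_scan(es, genotypes, map, alpha = alpha,
                                  cofactor_window_cM = cofactor_window_cM,
                                  response = response)
      sig <- scan_es$marker[scan_es$significant &
                              is.na(scan_es$duplicate_of)]
      detect_counts[sig] <- detect_counts[sig] + 1L
      if (length(sig) == 0) {
        fold_results[[length(fold_results) + 1]] <-
          tibble(run = r, fold = k, qtl_es = 0L, pg_es = 0, pg_ts = 0,
                 n_ts = nrow(ts))
        next
      }
      acc <- proportion_genotypic_variance(es, genotypes, sig, h2,
                                           response = response)
      pred <- predict_marker_model(es, ts, genotypes, sig,
                                   response = response)
      pg_ts <- ts_pg(pred$pred, pred$obs, h2, ts_estimator)
      fold_results[[length(fold_results) + 1]] <-
        tibble(run = r, fold = k, qtl_es = length(sig), pg_es = acc$p_G,
               pg_ts = pg_ts, n_ts = nrow(ts))
    }
  }
  fr <- bind_rows(fold_results)
  pg_es_mean <- mean(fr$pg_es)
  pg_ts_mean <- mean(fr$pg_ts)
  rel_bias <- relative_bias(pg_es_mean, pg_ts_mean)
  summary <- tibble(
    stage = attr(blues, "stage") %||% response,
    qtl_ds = qtl_ds, pg_ds = pg_ds,
    qtl_es = mean(fr$qtl_es), pg_es = pg_es_mean, pg_ts = pg_ts_mean,
    relative_bias = rel_bias, runs = runs, folds = folds
  )
  structure(
    list(summary = summary,
         detections = tibble(marker = names(detect_counts),
                             n_detected = as.integer(detect_counts),
                             n_scans = runs * folds),
         fold_results = fr,
         scan_full = scan_full),
    class = "qtl_cv"
  )
}

#' Relative bias of in-sample explained variance
#'
#' `100 * (pg_es - pg_ts) / pg_es`: the percentage by which the
#' estimation-set p_G overstates the cross-validated (test-set) p_G.
#'
#' @param pg_es Estimation-set p_G (percent).
#' @param pg_ts Test-set p_G (percent).
#' @return Relative bias in percent (NA when `pg_es` is 0).
#' @export
#' @examples
#' relative_bias(68.4, 42.9)  # 37.3
relative_bias <- function(pg_es, pg_ts) {
  ifelse(pg_es == 0, NA_real_, 100 * (pg_es - pg_ts) / pg_es)
}

# family-stratified fold assignment: within each family the (shuffled) lines
# are dealt round-robin, so per-fold family proportions are within one line
# of exact stratification
stratified_folds <- function(family, folds, seed) {
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  fold_id <- integer(length(family))
  for (f in unique(family)) {
    rows <- which(family == f)
    fold_id[rows[sample.int(length(rows))]] <-
      rep(seq_len(folds), length.out = length(rows))
  }
  fold_id
}

# Fit mu + family + markers on the estimation set and predict the test set.
# Test lines missing a model marker are dropped (complete-case prediction).
predict_marker_model <- function(es, ts, genotypes, markers,
                                 response = "blue") {
  al_es <- align_genotypes(es, genotypes, response)
  xm <- al_es$x[, markers, drop = FALSE]
  cc <- stats::complete.cases(xm)
  fam_levels <- levels(al_es$family)
  x_es <- cbind(family_incidence(factor(al_es$family[cc],
                                        levels = fam_levels)),
                xm[cc, , drop = FALSE])
  fit <- ls_fit(x_es, al_es$y[cc])
  beta <- ifelse(is.na(fit$coef), 0, fit$coef)

  al_ts <- align_genotypes(ts, genotypes, response)
  xm_ts <- al_ts$x[, markers, drop = FALSE]
  cc_ts <- stats::complete.cases(xm_ts)
  x_ts <- cbind(family_incidence(factor(al_ts$family[cc_ts],
                                        levels = fam_levels)),
                xm_ts[cc_ts, , drop = FALSE])
  pred <- as.numeric(x_ts %*% beta)
  obs <- al_ts$y[cc_ts]
  # centre both within test-set families: the explained-variance accounting
  # treats family means as design structure, so the test-set agreement must
  # measure the marker contribution beyond family as well
  fam_ts <- al_ts$family[cc_ts]
  pred <- pred - stats::ave(pred, fam_ts)
  obs <- obs - stats::ave(obs, fam_ts)
  list(pred = pred, obs = obs)
}

# test-set p_G from prediction-observation agreement
ts_pg <- function(pred, obs, h2, estimator) {
  n <- length(obs)
  if (n < 3 || stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  r2 <- stats::cor(pred, obs)^2
  if (estimator == "adjusted_cor") {
    r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  }
  max(0, 100 * r2 / h2)
}

#' Per-marker detection frequency over cross-validation scans
#'
#' Counts, for each marker, in how many estimation-set scans it was declared
#' significant, and collapses markers into QTL regions with the same
#' single-linkage window as the dynamic layer.
#'
#' @param cv A `qtl_cv` object from [run_cv()].
#' @param map Genetic map.
#' @param window_cM Region-matching window (see [match_regions()]).
#' @return Tibble `marker`, `group`, `pos_cM`, `n_detected`, `n_scans`,
#'   `frequency`, `region` (NA for never-detected markers).
#' @export
detection_frequency <- function(cv, map, window_cM = 5) {
  stopifnot(inherits(cv, "qtl_cv"))
  det <- cv$detections
  if (nrow(det) == 0 || det$n_scans[1] == 0) {
    abort("No completed cross-validation runs.")
  }
  out <- det |>
    left_join(map, by = "marker") |>
    mutate(frequency = .data$n_detected / .data$n_scans)
  hits <- out |> filter(.data$n_detected > 0)
  out$region <- NA_character_
  if (nrow(hits) > 0) {
    regions <- cluster_markers(hits$group, hits$pos_cM, window_cM)
    out$region[match(hits$marker, out$marker)] <- regions
  }
  select(out, all_of(c("marker", "group", "pos_cM", "n_detected",
                       "n_scans", "frequency", "region")))
}
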