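#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join n row_number across all_of distinct
#' @importFrom stats pf pt cor var sd rnorm rbinom setNames complete.cases
#' @importFrom utils combn head
NULL

# Derive k reproducible sub-seeds (< 2^31) from one master seed, so that
# independent stochastic stages (parents, meiosis, noise, folds) have named
# streams instead of sharing one global state.
derive_seeds <- function(seed, n, labels = NULL) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(labels)) names(out) <- labels
  out
}

# Column names of a genotype tibble that are markers (everything except
# the identifier columns).
marker_cols <- function(genotypes) {
  setdiff(names(genotypes), c("line", "family"))
}

# Extract the lines x markers numeric matrix from a genotype tibble.
genotype_matrix <- function(genotypes, markers = NULL) {
  markers <- markers %||% marker_cols(genotypes)
  x <- as.matrix(genotypes[, markers, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- genotypes$line
  x
}

# 0/1 family incidence model matrix (one column per family, rows sum to 1).
family_incidence <- function(family) {
  f <- factor(family)
  x <- stats::model.matrix(~ 0 + f)
  colnames(x) <- levels(f)
  x
}

# Least-squares fit via pivoted QR (.lm.fit); returns rss, rank and
# coefficients in original column order (NA for aliased columns). Workhorse
# behind all scan F tests.
ls_fit <- function(x, y) {
  z <- .lm.fit(x, y)
  coefs <- rep(NA_real_, ncol(x))
  coefs[z$pivot[seq_len(z$rank)]] <- z$coefficients[seq_len(z$rank)]
  list(rss = sum(z$residuals^2), rank = z$rank, coef = coefs,
       resid = z$residuals)
}

# F test of nested least-squares models fitted on the same observations.
# `tss` (total sum of squares of the response) sets the scale below which an
# RSS counts as an exact fit, so noiseless constructions behave sensibly.
nested_f_test <- function(rss_reduced, rss_full, df_num, df_den, tss = NULL) {
  if (df_num < 1 || df_den < 1) {
    return(list(f = NA_real_, p = NA_real_))
  }
  tiny <- 1e-12 * max(tss %||% 1, 1e-300)
  if (rss_reduced < tiny) {
    # the reduced model already reproduces the response exactly
    return(list(f = 0, p = 1))
  }
  if (rss_full < tiny) {
    # only the full model fits exactly: infinitely significant
    return(list(f = Inf, p = 1e-300))
  }
  msr <- (rss_reduced - rss_full) / df_num
  mse <- rss_full / df_den
  f <- max(msr / mse, 0)
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  # keep p strictly positive so downstream multiplicity corrections, which
  # contract p in (0, 1], accept saturated fits
  list(f = f, p = max(p, 1e-300))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}
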