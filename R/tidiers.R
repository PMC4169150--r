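#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a QTL scan: the significant markers
#'
#' @param x A `qtl_scan`.
#' @param all Return all tested markers instead of only significant ones.
#' @param ... Unused.
#' @return Tibble of scan rows.
#' @export
tidy.qtl_scan <- function(x, all = FALSE, ...) {
  out <- as_tibble(x)
  if (!all) out <- filter(out, .data$significant)
  out
}

#' One-row summary of a QTL scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return Tibble: `stage`, `m_tested`, `n_significant`, `n_cofactors`,
#'   `alpha`.
#' @export
glance.qtl_scan <- function(x, ...) {
  tibble(
    stage = attr(x, "stage") %||% NA_character_,
    m_tested = attr(x, "m"),
    n_significant = sum(x$significant & is.na(x$duplicate_of), na.rm = TRUE),
    n_cofactors = length(attr(x, "cofactors")),
    alpha = attr(x, "alpha")
  )
}

#' Tidy an epistasis scan: retained pairs
#'
#' @param x An `epi_scan`.
#' @param ... Unused.
#' @return Tibble of pair rows.
#' @export
tidy.epi_scan <- function(x, ...) as_tibble(x)

#' One-row summary of an epistasis scan
#'
#' @param x An `epi_scan`.
#' @param ... Unused.
#' @return Tibble: `stage`, `n_pairs_tested`, `n_pairs_skipped`,
#'   `n_significant`, `threshold`, `n_groups`.
#' @export
glance.epi_scan <- function(x, ...) {
  tibble(
    stage = attr(x, "stage") %||% NA_character_,
    n_pairs_tested = attr(x, "n_pairs_tested"),
    n_pairs_skipped = attr(x, "n_pairs_skipped"),
    n_significant = sum(x$significant, na.rm = TRUE),
    threshold = attr(x, "threshold"),
    n_groups = attr(x, "n_groups")
  )
}

#' Tidy a cross-validation result: per-fold rows
#'
#' @param x A `qtl_cv`.
#' @param ... Unused.
#' @return Tibble `run`, `fold`, `qtl_es`, `pg_es`, `pg_ts`, `n_ts`.
#' @export
tidy.qtl_cv <- function(x, ...) x$fold_results

#' One-row summary of a cross-validation (Table-1-shaped)
#'
#' @param x A `qtl_cv`.
#' @param ... Unused.
#' @return The `summary` tibble: QTL counts and p_G on the full data,
#'   estimation sets and test sets, plus the relative bias.
#' @export
glance.qtl_cv <- function(x, ...) x$summary

#' @export
print.qtl_cv <- function(x, ...) {
  cat("Cross-validated QTL detection (", x$summary$runs, " runs x ",
      x$summary$folds, " folds)\n", sep = "")
  print(x$summary)
  invisible(x)
}
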