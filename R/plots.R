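#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_line geom_col
#'   facet_wrap labs theme_minimal autoplot scale_x_continuous
#' @export
ggplot2::autoplot

#' Manhattan plot of a QTL scan
#'
#' Markers are laid out by cumulative map position; the dashed line marks the
#' smallest -log10(p) among significant markers (the realised Holm cutoff).
#'
#' @param object A `qtl_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qtl_scan <- function(object, ...) {
  dat <- as_tibble(object) |> filter(!is.na(.data$p))
  groups <- unique(dat$group)
  offs <- c(0, cumsum(vapply(groups, function(g) {
    max(dat$pos_cM[dat$group == g]) + 10
  }, numeric(1))))
  names(offs) <- c(groups, "_end")
  dat <- dat |>
    mutate(x = .data$pos_cM + offs[.data$group],
           logp = -log10(.data$p),
           odd = match(.data$group, groups) %% 2 == 1)
  cut <- if (any(dat$significant)) min(dat$logp[dat$significant]) else NA
  p <- ggplot(dat, aes(x = .data$x, y = .data$logp, colour = .data$odd)) +
    geom_point(size = 0.8, show.legend = FALSE) +
    labs(x = "map position", y = expression(-log[10](p)),
         title = attr(object, "stage")) +
    theme_minimal()
  if (!is.na(cut)) p <- p + geom_hline(yintercept = cut, linetype = "dashed")
  p
}

#' Plot the temporal profile of per-region explained genotypic variance
#'
#' @param profile Long tibble from [temporal_pg_profile()].
#' @return A ggplot: one line per region across stages.
#' @export
plot_pg_profile <- function(profile) {
  ggplot(profile,
         aes(x = .data$stage, y = .data$pg_share, group = .data$region,
             colour = .data$region)) +
    geom_line() +
    geom_point() +
    labs(x = "developmental stage", y = "p_G share (%)",
         colour = "QTL region") +
    theme_minimal()
}

#' Bar chart of Venn-class counts
#'
#' @param counts Tibble from [venn_counts()] or [marker_venn_counts()].
#' @return A ggplot.
#' @export
plot_venn_counts <- function(counts) {
  counts$venn_class <- factor(counts$venn_class, levels = counts$venn_class)
  ggplot(counts, aes(x = .data$venn_class, y = .data$n)) +
    geom_col() +
    labs(x = "stage membership", y = "QTL regions") +
    theme_minimal()
}

#' Detection-frequency plot over cross-validation scans
#'
#' @param object A `qtl_cv`.
#' @param map Genetic map (for positions).
#' @param ... Unused.
#' @return A ggplot of per-marker detection frequency.
#' @export
autoplot.qtl_cv <- function(object, map, ...) {
  det <- detection_frequency(object, map) |> filter(.data$n_detected > 0)
  ggplot(det, aes(x = .data$pos_cM, y = .data$frequency)) +
    geom_col(width = 1) +
    facet_wrap(~group) +
    labs(x = "position (cM)", y = "detection frequency") +
    theme_minimal()
}
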