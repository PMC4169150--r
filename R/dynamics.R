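# Single-linkage clustering of markers within linkage groups: markers on the
# same group join one cluster when adjacent members are at most `window_cM`
# apart (chains merge). Returns a region label per input marker.
cluster_markers <- function(group, pos, window_cM) {
  region <- character(length(group))
  for (g in unique(group)) {
    idx <- which(group == g)
    ord <- idx[order(pos[idx])]
    cl <- cumsum(c(1, diff(pos[ord]) > window_cM))
    for (k in unique(cl)) {
      members <- ord[cl == k]
      region[members] <- sprintf("%s@%.1f", g, min(pos[members]))
    }
  }
  region
}

#' Match QTL across developmental stages into regions
#'
#' Significant markers from the per-stage scans are clustered into QTL
#' regions by single linkage within each linkage group: two QTL share a
#' region iff they lie on the same group within `window_cM` of each other
#' (chains merge, so overlapping windows behave like overlapping intervals).
#' Each region is assigned a Venn class from the set of stages at which any
#' member is significant, and carries the per-stage effect sign of its
#' stage-wise best member.
#'
#' The default window of 5 cM interprets a "10-cM interval surrounding the
#' QTL" as +/- 5 cM of total width 10 cM.
#'
#' @param scans Named list of `qtl_scan` tibbles, one per stage.
#' @param window_cM Matching window (half-width of the overlap interval).
#'
#' @return Tibble of class `qtl_regions`, one row per region: `region`,
#'   `group`, `pos_cM` (of the overall best member), `marker` (best member),
#'   `venn_class`, one logical column and one `sign_<stage>` column per
#'   stage. Attribute `members` holds the marker-level table (`region`,
#'   `marker`, `group`, `pos_cM`, `stage`, `p`, `beta`).
#' @export
match_regions <- function(scans, window_cM = 5) {
  stages <- names(scans)
  if (is.null(stages)) abort("`scans` must be a named list (stage labels).")
  assert_number(window_cM, "window_cM", lower = 0)
  sig <- purrr::map_dfr(stages, function(s) {
    sc <- scans[[s]]
    rows <- sc[sc$significant, , drop = FALSE]
    if (any(is.na(rows$group)) || any(is.na(rows$pos_cM))) {
      abort(sprintf(
        "QTL without a map position at stage %s: %s.", s,
        paste(rows$marker[is.na(rows$group) | is.na(rows$pos_cM)],
              collapse = ", ")
      ))
    }
    tibble(stage = s, marker = rows$marker, group = rows$group,
           pos_cM = rows$pos_cM, p = rows$p, beta = rows$beta)
  })
  if (nrow(sig) == 0) {
    out <- tibble(region = character(), group = character(),
                  pos_cM = numeric(), marker = character(),
                  venn_class = character())
    for (s in stages) {
      out[[s]] <- logical()
      out[[paste0("sign_", s)]] <- character()
    }
    attr(out, "members") <- sig
    attr(out, "window_cM") <- window_cM
    attr(out, "stages") <- stages
    class(out) <- c("qtl_regions", class(out))
    return(out)
  }
  # cluster distinct markers (a marker significant at several stages counts
  # once for the geometry)
  mk <- sig |> distinct(.data$marker, .keep_all = TRUE)
  mk$region <- cluster_markers(mk$group, mk$pos_cM, window_cM)
  members <- left_join(sig, mk[, c("marker", "region")], by = "marker",
                       relationship = "many-to-one")

  out <- purrr::map_dfr(split(members, members$region), function(mm) {
    best <- mm[which.min(mm$p), ]
    present <- stages %in% mm$stage
    row <- tibble(region = mm$region[1], group = best$group,
                  pos_cM = best$pos_cM, marker = best$marker,
                  venn_class = venn_class_label(stages[present]))
    for (s in stages) {
      row[[s]] <- s %in% mm$stage
      ms <- mm[mm$stage == s, ]
      row[[paste0("sign_", s)]] <- if (nrow(ms) == 0) NA_character_ else {
        b <- ms$beta[which.min(ms$p)]
        if (is.na(b)) NA_character_ else if (b > 0) "+" else if (b < 0) "-" else "0"
      }
    }
    row
  }) |>
    arrange(.data$group, .data$pos_cM)
  attr(out, "members") <- members
  attr(out, "window_cM") <- window_cM
  attr(out, "stages") <- stages
  class(out) <- c("qtl_regions", class(out))
  out
}

venn_class_label <- function(stages_present) {
  paste(stages_present, collapse = "&")
}

#' Venn partition of QTL regions by stage membership
#'
#' Counts QTL regions per Venn class (every non-empty combination of
#' stages). All classes are reported, including empty ones, and the per-stage
#' totals reconcile with the number of regions significant at each stage.
#'
#' @param matches A `qtl_regions` table from [match_regions()].
#' @return Tibble `venn_class`, `n`.
#' @export
venn_counts <- function(matches) {
  stages <- attr(matches, "stages")
  if (is.null(stages)) abort("`matches` must come from match_regions().")
  combos <- unlist(lapply(seq_along(stages), function(k) {
    apply(utils::combn(stages, k), 2, paste, collapse = "&")
  }))
  counts <- table(factor(matches$venn_class, levels = combos))
  tibble(venn_class = combos, n = as.integer(counts))
}

#' Venn partition of individual markers by stage membership
#'
#' Marker-level companion of [venn_counts()]: markers (not regions) are
#' classified by the set of stages at which they are significant. Linked
#' markers tagging the same QTL are counted separately here, so marker-level
#' and region-level partitions need not agree.
#'
#' @param scans Named list of `qtl_scan` tibbles, one per stage.
#' @return Tibble `venn_class`, `n`.
#' @export
marker_venn_counts <- function(scans) {
  stages <- names(scans)
  if (is.null(stages)) abort("`scans` must be a named list (stage labels).")
  sig <- purrr::map(scans, function(sc) sc$marker[sc$significant])
  all_mk <- unique(unlist(sig))
  combos <- unlist(lapply(seq_along(stages), function(k) {
    apply(utils::combn(stages, k), 2, paste, collapse = "&")
  }))
  cls <- vapply(all_mk, function(m) {
    venn_class_label(stages[vapply(stages, function(s) m %in% sig[[s]],
                                   logical(1))])
  }, character(1))
  counts <- table(factor(cls, levels = combos))
  tibble(venn_class = combos, n = as.integer(counts))
}

#' Scan for QTL of developmental progression between two stages
#'
#' Forms the progression trait \eqn{\Delta = BLUE(t_2) - BLUE(t_1)} per line
#' and runs the full association pipeline on it (own cofactor selection, own
#' Holm correction). A QTL whose effect flips sign between the stages shows
#' up with roughly twice its effect magnitude; a QTL with equal effects at
#' both stages cancels out.
#'
#' @param blues_wide Wide BLUE tibble with columns for both stages.
#' @param stage_from,stage_to Stage column names (\eqn{t_1}, \eqn{t_2}).
#' @param genotypes Genotype tibble.
#' @param map Genetic map.
#' @param alpha Family-wise level for the Holm correction.
#' @param cofactor_window_cM Cofactor exclusion window.
#'
#' @return A `qtl_scan` tibble for the progression trait, with stage label
#'   `"<stage_to>-<stage_from>"`.
#' @export
progression_scan <- function(blues_wide, stage_from, stage_to, genotypes,
                             map, alpha = 0.05, cofactor_window_cM = 10) {
  for (s in c(stage_from, stage_to)) {
    if (!s %in% names(blues_wide)) {
      abort(sprintf("Stage '%s' not in `blues_wide`.", s))
    }
  }
  delta <- blues_wide[[stage_to]] - blues_wide[[stage_from]]
  keep <- !is.na(delta)
  if (sum(keep) < 10) abort("Too few shared lines for a progression scan.")
  rng <- diff(range(delta[keep]))
  if (rng <= 1e-8 * max(1, abs(mean(delta[keep])))) {
    abort("Progression trait is constant; stages are identical up to a shift.")
  }
  blues <- tibble(line = blues_wide$line[keep],
                  family = blues_wide$family[keep],
                  blue = delta[keep])
  attr(blues, "stage") <- paste0(stage_to, "-", stage_from)
  association_scan(blues, genotypes, map, alpha = alpha,
                   cofactor_window_cM = cofactor_window_cM)
}

#' Report QTL regions whose effect sign changes over development
#'
#' Lists regions significant at two or more stages whose estimated
#' allele-substitution effect has opposite signs at some pair of those
#' stages, with the stage pair and effect magnitudes.
#'
#' @param matches A `qtl_regions` table from [match_regions()].
#' @return Tibble `region`, `group`, `pos_cM`, `stage_a`, `stage_b`,
#'   `beta_a`, `beta_b` (one row per sign-discordant stage pair).
#' @export
sign_change_report <- function(matches) {
  stages <- attr(matches, "stages")
  members <- attr(matches, "members")
  if (is.null(stages) || is.null(members)) {
    abort("`matches` must come from match_regions().")
  }
  empty <- tibble(region = character(), group = character(),
                  pos_cM = numeric(), stage_a = character(),
                  stage_b = character(), beta_a = numeric(),
                  beta_b = numeric())
  if (nrow(matches) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(matches))) {
    sig_stages <- stages[vapply(stages, function(s) isTRUE(matches[[s]][i]),
                                logical(1))]
    if (length(sig_stages) < 2) next
    mm <- members[members$region == matches$region[i], ]
    betas <- vapply(sig_stages, function(s) {
      ms <- mm[mm$stage == s, ]
      ms$beta[which.min(ms$p)]
    }, numeric(1))
    prs <- utils::combn(length(sig_stages), 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      if (!is.na(betas[a]) && !is.na(betas[b]) &&
          sign(betas[a]) * sign(betas[b]) < 0) {
        out[[length(out) + 1]] <- tibble(
          region = matches$region[i], group = matches$group[i],
          pos_cM = matches$pos_cM[i],
          stage_a = sig_stages[a], stage_b = sig_stages[b],
          beta_a = unname(betas[a]), beta_b = unname(betas[b])
        )
      }
    }
  }
  if (length(out) == 0) empty else bind_rows(out)
}
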