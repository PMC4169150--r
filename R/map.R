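#' Simulate a multi-linkage-group genetic map
#'
#' Generates a marker map in centiMorgan on a set of linkage groups, the
#' backbone for population simulation, cofactor exclusion windows and QTL
#' region matching. Markers are placed uniformly at random along each group
#' and sorted, so marker density is approximately even across groups of equal
#' length.
#'
#' @param n_markers Total number of markers across the whole map.
#' @param groups Character vector of linkage-group labels. The default models
#'   a hexaploid small-grain genome (A, B and R subgenomes, 7 chromosomes
#'   each) with one chromosome split into two linkage groups, giving 22
#'   groups in total.
#' @param group_length_cM Length of each linkage group in cM (recycled).
#' @param seed Integer seed; the map is fully reproducible.
#'
#' @return A tibble with columns `marker`, `group`, `pos_cM`, ordered by
#'   group then position. Marker labels are unique across the map.
#' @export
#' @examples
#' map <- sim_genetic_map(n_markers = 50, groups = c("1A", "2A"), seed = 1)
#' head(map)
sim_genetic_map <- function(n_markers = 1000,
                            groups = triticale_linkage_groups(),
                            group_length_cM = 120,
                            seed = 1) {
  assert_number(n_markers, "n_markers", lower = length(groups), integer = TRUE)
  if (anyDuplicated(groups)) abort("Linkage-group labels must be unique.")
  if (length(groups) < 1) abort("Need at least one linkage group.")
  lens <- rep_len(group_length_cM, length(groups))
  if (any(lens <= 0)) abort("Group lengths must be positive.")

  # allocate markers proportional to group length, remainder to the longest
  raw <- n_markers * lens / sum(lens)
  n_per <- floor(raw)
  short <- n_markers - sum(n_per)
  if (short > 0) {
    top <- order(raw - n_per, decreasing = TRUE)[seq_len(short)]
    n_per[top] <- n_per[top] + 1L
  }
  n_per <- pmax(n_per, 1L)
  while (sum(n_per) > n_markers) {
    i <- which.max(n_per)
    n_per[i] <- n_per[i] - 1L
  }

  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  purrr::map2_dfr(seq_along(groups), n_per, function(i, k) {
    pos <- sort(round(stats::runif(k, 0, lens[i]), 2))
    tibble(
      marker = sprintf("%s_%03d", groups[i], seq_len(k)),
      group = groups[i],
      pos_cM = pos
    )
  })
}

#' Linkage-group labels of the default hexaploid map
#'
#' 21 nominal chromosomes (1A-7A, 1B-7B, 1R-7R) with chromosome 2R
#' represented as two linkage groups (`2R.1`, `2R.2`), for 22 groups. With
#' two independent regions assumed per group, 22 groups give
#' choose(44, 2) = 946 region pairs, the divisor behind the default
#' epistasis significance threshold.
#'
#' @return Character vector of 22 labels.
#' @export
triticale_linkage_groups <- function() {
  chrs <- c(paste0(1:7, "A"), paste0(1:7, "B"), paste0(1:7, "R"))
  sort(c(setdiff(chrs, "2R"), "2R.1", "2R.2"))
}

# Validate map invariants; used by readers and simulators.
validate_map <- function(map) {
  need <- c("marker", "group", "pos_cM")
  if (!all(need %in% names(map))) {
    abort(sprintf("Map must have columns %s.", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(map$marker)) {
    abort("Marker labels must be unique across the map.")
  }
  if (any(!is.finite(map$pos_cM)) || any(map$pos_cM < 0)) {
    abort("Map positions must be finite and non-negative.")
  }
  bad <- map |>
    group_by(.data$group) |>
    summarise(ok = !is.unsorted(.data$pos_cM), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Positions must be non-decreasing within groups: %s.",
      paste(bad$group, collapse = ", ")
    ))
  }
  invisible(map)
}
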