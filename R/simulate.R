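#' Define a multi-family crossing design
#'
#' A crossing design lists the biparental families of a multi-parent
#' population. Parents may appear in more than one family ("partially
#' connected" designs), which links allele effects across families.
#'
#' @param parents Character vector of parent labels.
#' @param families Tibble/data frame with columns `family`, `parent_a`,
#'   `parent_b`, `n_lines`.
#'
#' @return A validated tibble of class `crossing_design`.
#' @export
crossing_design <- function(parents, families) {
  families <- as_tibble(families)
  need <- c("family", "parent_a", "parent_b", "n_lines")
  if (!all(need %in% names(families))) {
    abort(sprintf("`families` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(families$family)) abort("Family labels must be unique.")
  used <- c(families$parent_a, families$parent_b)
  if (!all(used %in% parents)) {
    abort(sprintf(
      "Unknown parents in design: %s.",
      paste(setdiff(used, parents), collapse = ", ")
    ))
  }
  if (any(families$parent_a == families$parent_b)) {
    abort("Each family must have two distinct parents.")
  }
  if (any(families$n_lines < 1)) abort("`n_lines` must be >= 1.")
  structure(families, parents = parents,
            class = c("crossing_design", class(families)))
}

#' Simulate fully homozygous parent haplotypes
#'
#' Draws biallelic (0/1) haplotypes for inbred/DH parents. Every marker is
#' guaranteed to segregate in at least one family of `design` (or, without a
#' design, to be polymorphic among all parents): monomorphic columns are
#' redrawn up to `max_retries` times.
#'
#' @param map Genetic map tibble (see [sim_genetic_map()]).
#' @param n_parents Number of parents (>= 2). Ignored if `design` is given
#'   (its parent list is used).
#' @param design Optional [crossing_design()]; enforces per-family
#'   polymorphism.
#' @param seed Integer seed.
#' @param max_retries Retry cap for the polymorphism constraint.
#' @param force_polymorphic Markers that must segregate in *every* family of
#'   `design` (used for the preset's QTL markers, which model major loci
#'   segregating throughout the elite material).
#'
#' @return Tibble with column `parent` plus one 0/1 column per marker.
#' @export
sim_parents <- function(map, n_parents = 6, design = NULL, seed = 1,
                        max_retries = 1000, force_polymorphic = character()) {
  validate_map(map)
  if (!is.null(design)) {
    parents <- attr(design, "parents")
  } else {
    assert_number(n_parents, "n_parents", lower = 2, integer = TRUE)
    parents <- paste0("P", seq_len(n_parents))
  }
  m <- nrow(map)
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  hap <- matrix(stats::rbinom(length(parents) * m, 1, 0.5),
                nrow = length(parents), ncol = m,
                dimnames = list(parents, map$marker))

  if (length(force_polymorphic) > 0 && is.null(design)) {
    abort("`force_polymorphic` requires a crossing design.")
  }
  force_idx <- match(force_polymorphic, map$marker)
  if (anyNA(force_idx)) {
    abort(sprintf("Unknown markers in `force_polymorphic`: %s.",
                  paste(force_polymorphic[is.na(force_idx)], collapse = ", ")))
  }
  segregates <- function(h) {
    if (is.null(design)) {
      return(apply(h, 2, function(col) length(unique(col)) > 1))
    }
    per_fam <- matrix(vapply(seq_len(nrow(design)), function(i) {
      h[design$parent_a[i], ] != h[design$parent_b[i], ]
    }, logical(ncol(h))), nrow = ncol(h))
    ok <- rowSums(per_fam) > 0
    ok[force_idx] <- rowSums(per_fam)[force_idx] == nrow(design)
    ok
  }

  tries <- 0
  bad <- which(!segregates(hap))
  while (length(bad) > 0 && tries < max_retries) {
    hap[, bad] <- stats::rbinom(length(parents) * length(bad), 1, 0.5)
    bad <- which(!segregates(hap))
    tries <- tries + 1
  }
  if (length(bad) > 0) {
    abort(sprintf(
      "Could not make markers polymorphic after %d retries: %s.",
      max_retries, paste(map$marker[bad], collapse = ", ")
    ))
  }
  bind_cols(tibble(parent = parents), as_tibble(hap))
}

# Haldane recombination fractions between adjacent markers of one ordered
# map; independent linkage groups recombine freely (r = 0.5).
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

adjacent_recomb <- function(map) {
  d <- diff(map$pos_cM)
  r <- haldane_r(d)
  new_group <- map$group[-1] != map$group[-nrow(map)]
  r[new_group] <- 0.5
  r
}

#' Simulate one doubled-haploid family
#'
#' Each DH line is a single recombinant gamete of the F1 between two
#' homozygous parents, with its genome doubled: lines are homozygous at every
#' marker and carry only parental alleles. Crossovers between adjacent
#' markers at distance d cM occur with the Haldane probability
#' r = 0.5 (1 - exp(-2 d / 100)), independently across intervals and lines
#' (no interference); markers on different linkage groups assort freely.
#'
#' @param parents Parent haplotype tibble from [sim_parents()].
#' @param parent_a,parent_b Labels of the two (distinct, homozygous) parents.
#' @param n_lines Number of DH lines to produce.
#' @param map Genetic map; its marker order defines the crossover process.
#' @param seed Integer seed.
#' @param family Family label stored with the lines.
#' @param line_prefix Prefix for generated line names.
#'
#' @return Genotype tibble: columns `line`, `family`, then one 0/1 column per
#'   marker in map order.
#' @export
sim_dh_family <- function(parents, parent_a, parent_b, n_lines, map, seed = 1,
                          family = paste0(parent_a, "x", parent_b),
                          line_prefix = family) {
  validate_map(map)
  assert_number(n_lines, "n_lines", lower = 1, integer = TRUE)
  for (p in c(parent_a, parent_b)) {
    if (!p %in% parents$parent) abort(sprintf("Unknown parent '%s'.", p))
  }
  if (parent_a == parent_b) abort("Parents must be distinct.")
  missing_mk <- setdiff(map$marker, names(parents))
  if (length(missing_mk) > 0) {
    abort(sprintf(
      "Markers absent from parent haplotypes: %s.",
      paste(head(missing_mk, 5), collapse = ", ")
    ))
  }
  hap_a <- as.numeric(parents[parents$parent == parent_a, map$marker])
  hap_b <- as.numeric(parents[parents$parent == parent_b, map$marker])
  m <- nrow(map)
  r <- adjacent_recomb(map)

  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  # crossover indicators per interval; cumulative parity picks the parent
  start <- stats::rbinom(n_lines, 1, 0.5)
  if (m == 1) {
    parity <- matrix(start, n_lines, 1)
  } else {
    xo <- matrix(stats::rbinom(n_lines * (m - 1), 1, rep(r, each = n_lines)),
                 nrow = n_lines)
    cs <- if (ncol(xo) > 1) t(apply(xo, 1, cumsum)) else xo
    parity <- (matrix(start, n_lines, m) + cbind(0, cs)) %% 2
  }
  geno <- t(t(parity) * hap_b) + t(t(1 - parity) * hap_a)
  colnames(geno) <- map$marker
  bind_cols(
    tibble(line = sprintf("%s_%03d", line_prefix, seq_len(n_lines)),
           family = family),
    as_tibble(geno)
  )
}

#' Simulate all families of a crossing design
#'
#' @param design A [crossing_design()].
#' @param parents Parent haplotypes from [sim_parents()].
#' @param map Genetic map.
#' @param seed Integer seed (one sub-seed per family).
#'
#' @return Genotype tibble of all families stacked.
#' @export
sim_genotypes <- function(design, parents, map, seed = 1) {
  seeds <- derive_seeds(seed, nrow(design))
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    sim_dh_family(parents,
                  parent_a = design$parent_a[i],
                  parent_b = design$parent_b[i],
                  n_lines = design$n_lines[i],
                  map = map, seed = seeds[i],
                  family = design$family[i])
  })
}

#' Inject missing genotype calls
#'
#' Masks a fraction of genotype calls at random as `NA`, emulating failed
#' marker assays, so missing-data handling downstream is exercised.
#'
#' @param genotypes Genotype tibble.
#' @param rate Missing rate in \[0, 1\].
#' @param seed Integer seed.
#' @return Genotype tibble with `NA`s.
#' @export
inject_missing <- function(genotypes, rate = 0.02, seed = 1) {
  assert_number(rate, "rate", lower = 0, upper = 1)
  if (rate == 0) return(genotypes)
  mk <- marker_cols(genotypes)
  x <- genotype_matrix(genotypes, mk)
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(length(x)) < rate, nrow = nrow(x))
  x[mask] <- NA_real_
  bind_cols(genotypes[, c("line", "family")], as_tibble(x))
}
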