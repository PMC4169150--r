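#' Default multi-family study preset
#'
#' Returns the map, crossing design and trait architecture of the package's
#' reference simulation: a winter-triticale-style mapping population of 647
#' DH lines in four partially connected families (131/120/200/196 lines) from
#' six elite parents, genotyped with ~1000 dominant-scored biallelic markers
#' on a 22-linkage-group cM map, and scored for developmental stage (BBCH-like
#' codes near 49/69/81) at three time points (DS1-DS3) in 4 environments with
#' partial replication.
#'
#' The QTL architecture contains all three temporal QTL classes - three
#' persistent QTL, two DS1-specific QTL, one sign-switching QTL (on group 6A)
#' - plus one epistatic marker pair (groups 1B x 3B). Variance components are
#' calibrated so that the simulated entry-mean heritabilities are close to
#' 0.90/0.85/0.72 and the inter-stage BLUE correlations close to
#' 0.84/0.74/0.69 (DS1-DS2, DS2-DS3, DS1-DS3). The calibration is analytic
#' (from the genetic covariance implied by the design and effect sizes) and
#' verified by simulation; see the package vignette.
#'
#' @param n_markers Number of markers on the simulated map.
#' @param n_lines Family sizes (length 4); defaults sum to 647.
#'
#' @return List of class `study_preset` with elements `map`
#'   ([sim_genetic_map()] result), `design` ([crossing_design()]) and `arch`
#'   ([trait_architecture()]).
#' @export
#' @examples
#' preset <- default_study_preset(n_markers = 200)
#' sum(preset$design$n_lines)
default_study_preset <- function(n_markers = 1000,
                                 n_lines = c(131, 120, 200, 196)) {
  if (length(n_lines) != 4) abort("`n_lines` must have length 4.")
  # fixed internal seed: the default map is a constant of the preset
  map <- sim_genetic_map(n_markers = n_markers,
                         groups = triticale_linkage_groups(),
                         group_length_cM = 120, seed = 20140901)

  parents <- paste0("P", 1:6)
  design <- crossing_design(
    parents = parents,
    families = tibble(
      family = c("FAM1", "FAM2", "FAM3", "FAM4"),
      parent_a = c("P1", "P1", "P4", "P4"),
      parent_b = c("P2", "P3", "P5", "P6"),
      n_lines = n_lines
    )
  )

  # QTL markers: the marker nearest 60 cM on each chosen group
  qtl_marker <- function(group, at = 60) {
    sub <- map[map$group == group, ]
    sub$marker[which.min(abs(sub$pos_cM - at))]
  }
  qtl <- tibble(
    marker = c(qtl_marker("1A"), qtl_marker("5R"), qtl_marker("6R"),
               qtl_marker("2B"), qtl_marker("4R"), qtl_marker("6A")),
    class = c("persistent", "persistent", "persistent",
              "stage_specific", "stage_specific", "sign_switching"),
    DS1 = c(1.00, 0.90, 0.85, 1.00, 0.90, 0.90),
    DS2 = c(1.00, 0.85, 0.90, 0.00, 0.00, -0.35),
    DS3 = c(1.00, 0.90, 0.85, 0.00, 0.00, -0.90)
  )
  epistasis <- tibble(
    marker_a = qtl_marker("1B"),
    marker_b = qtl_marker("3B"),
    DS1 = 1.70, DS2 = 1.70, DS3 = 1.70
  )
  family_means <- matrix(
    rep(c(0.2, -0.2, 0.1, -0.1), 3), nrow = 4,
    dimnames = list(design$family, c("DS1", "DS2", "DS3"))
  )

  arch <- trait_architecture(
    stages = c("DS1", "DS2", "DS3"),
    stage_means = c(49, 69, 81),
    qtl = qtl,
    epistasis = epistasis,
    family_means = family_means,
    sigma2_poly = .preset_calibration$sigma2_poly,
    rho_poly = .preset_calibration$rho_poly,
    sigma2_gxe = .preset_calibration$sigma2_gxe,
    rho_gxe = .preset_calibration$rho_noise,
    sigma2_eps = .preset_calibration$sigma2_eps,
    rho_eps = .preset_calibration$rho_noise,
    n_env = 4,
    rep2_fraction = 0.2
  )

  structure(list(map = map, design = design, arch = arch),
            class = "study_preset")
}

# Calibrated variance components of the default preset (see vignette for the
# derivation): total genotypic variance is held at 3.3 per stage; polygenic
# variances absorb what the QTL do not contribute; GxE and plot-error
# variances are solved from the entry-mean heritability targets
# (0.90/0.85/0.72 with E = 4 environments and harmonic-mean replication
# 1/0.9); cross-stage polygenic and noise correlations are solved from the
# BLUE correlation targets (0.84/0.74/0.69).
.preset_calibration <- list(
  sigma2_poly = c(DS1 = 1.4632, DS2 = 2.0755, DS3 = 1.9024),
  rho_poly = matrix(c(1, 0.9500, 0.8006,
                      0.9500, 1, 0.6648,
                      0.8006, 0.6648, 1), 3, 3),
  sigma2_gxe = c(DS1 = 0.792, DS2 = 1.32, DS3 = 2.904),
  sigma2_eps = c(DS1 = 0.7496, DS2 = 1.1216, DS3 = 2.477),
  rho_noise = matrix(c(1, 0.8724, 0.7352,
                       0.8724, 1, 0.6106,
                       0.7352, 0.6106, 1), 3, 3)
)

#' Simulate a complete study from a preset
#'
#' Runs the whole generative pipeline: parent haplotypes, DH families by
#' simulated meiosis, plot-level phenotypes, and missing-call injection into
#' the released genotype table (phenotypes are generated from the complete
#' genotypes; missingness is an observation process).
#'
#' @param preset A `study_preset` (default [default_study_preset()]).
#' @param seed Integer master seed; all stochastic stages derive named
#'   sub-seeds from it, so results are fully reproducible.
#' @param missing_rate Fraction of genotype calls masked as `NA`.
#'
#' @return List of class `study_simulation`: `map`, `design`, `parents`,
#'   `genotypes` (with missing calls), `phenotypes` (plot level), and
#'   `truth` (list with the architecture and true genetic values).
#' @export
#' @examples
#' sim <- simulate_study(default_study_preset(n_markers = 60), seed = 7)
#' dim(sim$genotypes)
simulate_study <- function(preset = default_study_preset(), seed = 1,
                           missing_rate = 0.02) {
  stopifnot(inherits(preset, "study_preset"))
  seeds <- derive_seeds(seed, 4, c("parents", "meiosis", "pheno", "missing"))
  arch_markers <- unique(c(preset$arch$qtl$marker,
                           preset$arch$epistasis$marker_a,
                           preset$arch$epistasis$marker_b))
  parents <- sim_parents(preset$map, design = preset$design,
                         seed = seeds[["parents"]],
                         force_polymorphic = arch_markers)
  geno <- sim_genotypes(preset$design, parents, preset$map,
                        seed = seeds[["meiosis"]])
  pheno <- sim_phenotypes(geno, preset$arch, seed = seeds[["pheno"]])
  geno_rel <- inject_missing(geno, rate = missing_rate,
                             seed = seeds[["missing"]])
  structure(
    list(map = preset$map, design = preset$design, parents = parents,
         genotypes = geno_rel, phenotypes = pheno,
         truth = list(arch = preset$arch,
                      genetic_values = genetic_values(pheno),
                      genotypes_complete = geno)),
    class = "study_simulation"
  )
}
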