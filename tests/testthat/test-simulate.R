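test_that("parents are homozygous, polymorphic where required, reproducible", {
  map <- sim_genetic_map(n_markers = 40, groups = c("1A", "2A"), seed = 3)
  p1 <- sim_parents(map, n_parents = 6, seed = 9)
  p2 <- sim_parents(map, n_parents = 6, seed = 9)
  expect_identical(p1, p2)
  x <- as.matrix(p1[, map$marker])
  expect_true(all(x %in% c(0, 1)))
  # without a design every marker segregates among the parents
  expect_true(all(apply(x, 2, function(col) length(unique(col)) > 1)))

  # one-marker map with two parents: the parents must differ
  map1 <- toy_map(pos = 0)
  p <- sim_parents(map1, n_parents = 2, seed = 1)
  expect_equal(length(unique(p[[map1$marker]])), 2)

  # with a design, each marker segregates in at least one family
  design <- crossing_design(
    parents = paste0("P", 1:4),
    families = tibble::tibble(family = c("F1", "F2"),
                              parent_a = c("P1", "P3"),
                              parent_b = c("P2", "P4"),
                              n_lines = c(5, 5))
  )
  pd <- sim_parents(map, design = design, seed = 2)
  xa <- as.matrix(pd[, map$marker])
  rownames(xa) <- pd$parent
  seg <- (xa["P1", ] != xa["P2", ]) | (xa["P3", ] != xa["P4", ])
  expect_true(all(seg))
})

test_that("DH lines are doubled gametes carrying only parental alleles", {
  map <- sim_genetic_map(n_markers = 30, groups = c("1A", "3B"), seed = 5)
  p <- sim_parents(map, n_parents = 2, seed = 7)
  fam <- sim_dh_family(p, "P1", "P2", n_lines = 131, map = map, seed = 11)
  expect_equal(nrow(fam), 131)
  x <- as.matrix(fam[, map$marker])
  expect_true(all(x %in% c(0, 1)))
  hap <- as.matrix(p[, map$marker])
  for (j in seq_len(ncol(x))) {
    expect_true(all(x[, j] %in% hap[, j]))
  }
  expect_error(sim_dh_family(p, "P1", "P1", 5, map),
               "distinct")
})

test_that("zero map distance gives perfect cosegregation", {
  map <- toy_map(pos = c(5, 5))
  p <- tibble::tibble(parent = c("A", "B"), M01 = c(0, 1), M02 = c(0, 1))
  fam <- sim_dh_family(p, "A", "B", n_lines = 500, map = map, seed = 3)
  expect_true(all(fam$M01 == fam$M02))
})

test_that("realized recombination matches the Haldane fraction", {
  d <- 50
  map <- toy_map(pos = c(0, d))
  p <- tibble::tibble(parent = c("A", "B"), M01 = c(0, 1), M02 = c(0, 1))
  n <- 2000
  fam <- sim_dh_family(p, "A", "B", n_lines = n, map = map, seed = 17)
  r_hat <- mean(fam$M01 != fam$M02)
  r_true <- 0.5 * (1 - exp(-2 * d / 100))
  expect_equal(r_true, 0.3161, tolerance = 1e-3)
  se <- sqrt(r_true * (1 - r_true) / n)
  expect_lt(abs(r_hat - r_true), 3 * se)
  # and a binomial test does not reject at alpha = 0.01
  bt <- binom.test(sum(fam$M01 != fam$M02), n, p = r_true)
  expect_gt(bt$p.value, 0.01)
})

test_that("genotype and phenotype simulation is bitwise reproducible", {
  preset <- small_preset(n_markers = 60)
  s1 <- simulate_study(preset, seed = 4)
  s2 <- simulate_study(preset, seed = 4)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  s3 <- simulate_study(preset, seed = 5)
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("degenerate architectures produce exact phenotypes", {
  map <- toy_map(pos = c(0, 30))
  p <- tibble::tibble(parent = c("A", "B"), M01 = c(0, 1), M02 = c(0, 1))
  fam <- sim_dh_family(p, "A", "B", n_lines = 40, map = map, seed = 2)
  zero3 <- matrix(0, 3, 3); diag(zero3) <- 1
  arch0 <- trait_architecture(
    sigma2_poly = rep(0, 3), sigma2_gxe = rep(0, 3), sigma2_eps = rep(0, 3),
    n_env = 2, rep2_fraction = 0
  )
  ph <- sim_phenotypes(fam, arch0, seed = 1)
  expect_true(all(ph$DS1 == 49) && all(ph$DS2 == 69) && all(ph$DS3 == 81))

  # single QTL, no noise: exactly two values per stage, |difference| = |b|
  arch1 <- trait_architecture(
    qtl = tibble::tibble(marker = "M01", class = "persistent",
                         DS1 = 0.7, DS2 = 0.7, DS3 = -0.4),
    sigma2_poly = rep(0, 3), sigma2_gxe = rep(0, 3), sigma2_eps = rep(0, 3),
    n_env = 2, rep2_fraction = 0
  )
  ph1 <- sim_phenotypes(fam, arch1, seed = 1)
  vals <- sort(unique(ph1$DS1))
  expect_equal(length(vals), 2)
  expect_equal(diff(vals), 0.7)
  expect_equal(diff(range(ph1$DS3)), 0.4)
})

test_that("architecture validation catches inconsistent classes and variances", {
  expect_error(trait_architecture(sigma2_eps = c(-1, 0, 0)), "non-negative")
  expect_error(trait_architecture(
    qtl = tibble::tibble(marker = "M01", class = "persistent",
                         DS1 = 1, DS2 = 0, DS3 = 1)
  ), "inconsistent")
  expect_error(trait_architecture(
    qtl = tibble::tibble(marker = "M01", class = "sign_switching",
                         DS1 = 1, DS2 = 0.5, DS3 = 0.2)
  ), "inconsistent")
  # missing marker caught at simulation time
  map <- toy_map(pos = c(0, 10))
  p <- tibble::tibble(parent = c("A", "B"), M01 = c(0, 1), M02 = c(0, 1))
  fam <- sim_dh_family(p, "A", "B", 10, map, seed = 1)
  arch <- trait_architecture(
    qtl = tibble::tibble(marker = "ZZZ", class = "persistent",
                         DS1 = 1, DS2 = 1, DS3 = 1)
  )
  expect_error(sim_phenotypes(fam, arch, seed = 1), "ZZZ")
})

test_that("default preset reproduces the study design constants", {
  preset <- default_study_preset()
  expect_equal(sum(preset$design$n_lines), 647)
  expect_equal(preset$design$n_lines, c(131, 120, 200, 196))
  # partially connected: exactly 2 parents in two families, 4 in one
  deg <- table(c(preset$design$parent_a, preset$design$parent_b))
  expect_equal(sort(as.integer(deg)), c(1, 1, 1, 1, 2, 2))
  # 22 linkage groups so the epistasis threshold prints as 5.3e-5
  expect_equal(length(unique(preset$map$group)), 22)
  expect_equal(signif(epistasis_threshold(22, 0.05), 2), 5.3e-5)
  expect_equal(nrow(preset$map), 1000)
  # all three QTL classes plus an epistatic pair are present
  expect_setequal(unique(preset$arch$qtl$class),
                  c("persistent", "stage_specific", "sign_switching"))
  expect_gte(nrow(preset$arch$epistasis), 1)
})
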