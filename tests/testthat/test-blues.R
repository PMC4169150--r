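make_pheno <- function(lines, envs, y, family = "F1", rep = 1) {
  tibble::tibble(line = lines, family = family, env = envs, rep = rep,
                 DS1 = y)
}

test_that("BLUE equals the raw value with a single environment", {
  ph <- make_pheno(c("L1", "L2", "L3"), "E1", c(5, 7, 9))
  b <- compute_blues(ph, "DS1")
  expect_equal(b$blue, c(5, 7, 9))
  expect_equal(attr(b, "n_env"), 1)
})

test_that("balanced two-environment BLUEs equal per-line means", {
  lines <- rep(c("L1", "L2", "L3", "L4"), 2)
  envs <- rep(c("E1", "E2"), each = 4)
  base <- c(10, 12, 14, 16)
  y <- c(base + 1, base - 1)  # environment offsets +1 / -1
  ph <- make_pheno(lines, envs, y)
  b <- compute_blues(ph, "DS1")
  expect_equal(b$blue, base, tolerance = 1e-12)
})

test_that("BLUEs match lm() with sum-to-zero environment contrasts", {
  set.seed(42)
  n_lines <- 25
  lines <- sprintf("L%02d", seq_len(n_lines))
  ph <- tidyr::expand_grid(line = lines, env = c("E1", "E2", "E3"))
  # unbalanced: drop some cells, duplicate others
  ph <- ph[-sample(nrow(ph), 10), ]
  ph <- dplyr::bind_rows(ph, ph[sample(nrow(ph), 8), ])
  ph$family <- "F1"
  ph$rep <- 1
  ph$DS1 <- rnorm(nrow(ph), 50, 2)
  b <- compute_blues(ph, "DS1")
  fit <- lm(DS1 ~ 0 + line + env, data = ph,
            contrasts = list(env = contr.sum(3)))
  expect_equal(b$blue, unname(coef(fit)[seq_len(n_lines)]), tolerance = 1e-10)
})

test_that("adding a constant to one environment shifts all BLUEs equally", {
  set.seed(7)
  lines <- rep(sprintf("L%02d", 1:12), 2)
  envs <- rep(c("E1", "E2"), each = 12)
  y <- rnorm(24, 60, 1)
  ph <- make_pheno(lines, envs, y)
  b0 <- compute_blues(ph, "DS1")
  ph2 <- ph
  ph2$DS1[ph2$env == "E2"] <- ph2$DS1[ph2$env == "E2"] + 5
  b1 <- compute_blues(ph2, "DS1")
  shift <- b1$blue - b0$blue
  expect_equal(shift, rep(5 / 2, 12), tolerance = 1e-10)
})

test_that("heritability follows the entry-mean formula exactly as stored", {
  # sigma_G=1, sigma_GxE=1, sigma_eps=1, E=4, r_bar=1.25 -> 1/(1+0.25+0.2)
  h2 <- 1 / (1 + 1 / 4 + 1 / (4 * 1.25))
  expect_equal(round(h2, 4), 0.6897)
  # and the estimator stores exactly that functional form
  preset <- small_preset(n_markers = 40)
  sim <- simulate_study(preset, seed = 3)
  vc <- estimate_variance_components(sim$phenotypes, "DS1", lrt = FALSE)
  expect_equal(
    vc$h2,
    vc$sigma2_G / (vc$sigma2_G + vc$sigma2_GxE / vc$n_env +
                     vc$sigma2_eps / (vc$n_env * vc$r_bar)),
    tolerance = 1e-12
  )
  expect_true(vc$h2 >= 0 && vc$h2 <= 1)
  expect_true(all(c(vc$sigma2_G, vc$sigma2_GxE, vc$sigma2_eps) >= 0))
})

test_that("noiseless monogenic data recover sigma_eps = 0 and the analytic sigma_G", {
  map <- toy_map(pos = c(0, 40))
  p <- tibble::tibble(parent = c("A", "B"), M01 = c(0, 1), M02 = c(1, 0))
  fam <- sim_dh_family(p, "A", "B", n_lines = 200, map = map, seed = 8)
  # a whisper of plot error keeps the REML problem well-posed; the genetic
  # signal is otherwise exactly monogenic
  arch <- trait_architecture(
    qtl = tibble::tibble(marker = "M01", class = "persistent",
                         DS1 = 1.5, DS2 = 1.5, DS3 = 1.5),
    sigma2_poly = rep(0, 3), sigma2_gxe = rep(0, 3),
    sigma2_eps = rep(1e-4, 3),
    n_env = 2, rep2_fraction = 0.5
  )
  ph <- sim_phenotypes(fam, arch, seed = 2)
  vc <- suppressWarnings(estimate_variance_components(ph, "DS1", lrt = TRUE))
  expect_lt(vc$sigma2_eps, 1e-3)
  p_hat <- mean(fam$M01)
  analytic <- p_hat * (1 - p_hat) * 1.5^2 * 200 / 199
  expect_equal(vc$sigma2_G, analytic, tolerance = 0.02 * analytic)
  expect_equal(vc$h2, 1, tolerance = 1e-3)
  expect_lt(vc$p_sigma2_G, 0.01)
})

test_that("variance component LRT p-values are small when variance is real", {
  preset <- small_preset(n_markers = 40)
  sim <- simulate_study(preset, seed = 11)
  vc <- estimate_variance_components(sim$phenotypes, "DS1", lrt = TRUE)
  expect_lt(vc$p_sigma2_G, 0.01)
  expect_lt(vc$p_sigma2_GxE, 0.05)
})

test_that("stage correlations behave at the boundaries", {
  preset <- small_preset(n_markers = 40)
  sim <- simulate_study(preset, seed = 5)
  b <- compute_blues_wide(sim$phenotypes)
  # self-correlation
  b2 <- b
  b2$DS9 <- b2$DS1
  sc <- stage_correlations(b2, c("DS1", "DS9"))
  expect_equal(sc$r, 1, tolerance = 1e-12)
  # error with fewer than 3 shared lines
  b3 <- b
  b3$DS2[-(1:2)] <- NA
  expect_error(stage_correlations(b3, c("DS1", "DS2")), "3 shared")
})

test_that("stages driven by disjoint QTL with no shared background are uncorrelated", {
  map <- toy_map(pos = c(0, 20, 0, 20), groups = c("1A", "1A", "2A", "2A"))
  p <- tibble::tibble(parent = c("A", "B"), M01 = c(0, 1), M02 = c(1, 0),
                      M03 = c(0, 1), M04 = c(1, 0))
  fam <- sim_dh_family(p, "A", "B", n_lines = 400, map = map, seed = 21)
  arch <- trait_architecture(
    qtl = tibble::tibble(
      marker = c("M01", "M03"),
      class = c("stage_specific", "stage_specific"),
      DS1 = c(1, 0), DS2 = c(0, 1), DS3 = c(0, 0)
    ),
    sigma2_poly = rep(0, 3), sigma2_gxe = rep(0, 3),
    sigma2_eps = rep(1e-4, 3), n_env = 2, rep2_fraction = 0
  )
  ph <- sim_phenotypes(fam, arch, seed = 3)
  b <- compute_blues_wide(ph, c("DS1", "DS2"))
  sc <- stage_correlations(b, c("DS1", "DS2"))
  se <- 1 / sqrt(400 - 3)
  expect_lt(abs(sc$r), 3 * se)
})

test_that("BLUEs track true genetic values at the accuracy sqrt(h2) predicts", {
  preset <- small_preset()
  acc <- sapply(1:5, function(i) {
    sim <- simulate_study(preset, seed = 300 + i)
    b <- compute_blues(sim$phenotypes, "DS1")
    gv <- sim$truth$genetic_values
    vc <- estimate_variance_components(sim$phenotypes, "DS1", lrt = FALSE)
    c(cor(b$blue, gv$DS1[match(b$line, gv$line)]), vc$h2)
  })
  expect_gte(mean(acc[1, ]), mean(sqrt(acc[2, ])) - 0.05)
})
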