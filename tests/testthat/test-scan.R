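test_that("Holm step-down follows the hand-executed rule", {
  expect_equal(holm_correct(rep(1, 5)), rep(FALSE, 5))
  expect_equal(holm_correct(c(0.001, 0.02, 0.04), 0.05), rep(TRUE, 3))
  expect_equal(holm_correct(c(0.001, 0.03, 0.04), 0.05),
               c(TRUE, FALSE, FALSE))
  # original order preserved
  expect_equal(holm_correct(c(0.04, 0.001, 0.03), 0.05),
               c(FALSE, TRUE, FALSE))
  expect_equal(holm_correct(numeric(0)), logical(0))
  expect_error(holm_correct(c(0, 0.5)), "in \\(0, 1\\]")
})

test_that("Holm agrees with p.adjust and dominates Bonferroni", {
  for (s in 1:25) {
    set.seed(s)
    m <- sample(3:40, 1)
    p <- runif(m)^sample(1:3, 1)
    flags <- holm_correct(p, 0.05)
    expect_equal(flags, p.adjust(p, "holm") <= 0.05)
    bonf <- p <= 0.05 / m
    expect_true(all(flags[bonf]))
  }
})

test_that("a perfect family-centered predictor is selected first", {
  set.seed(1)
  inst <- random_instance(n = 40, m = 5, seed = 2)
  g <- inst$genotypes
  y <- g$M03 * 2 + ifelse(g$family == "FA", 1, -1)
  blues <- toy_blues(g, y)
  cof <- select_cofactors(blues, g)
  expect_equal(as.character(cof)[1], "M03")
})

test_that("pure-noise traits select only a handful of cofactors", {
  # BIC-type penalties keep null selections small but not exactly zero when
  # the best of 50 candidate F statistics is scanned at n = 100
  picked <- sapply(1:30, function(s) {
    inst <- random_instance(n = 100, m = 50, seed = 100 + s)
    length(select_cofactors(inst$blues, inst$genotypes))
  })
  expect_gte(mean(picked <= 3), 0.8)
  expect_lte(median(picked), 2)
  expect_lte(max(picked), 10)
})

test_that("forward SBC path matches exhaustive best-subset on 3 markers", {
  sbc <- function(x, y) {
    fit <- lm.fit(x, y)
    rss <- sum(fit$residuals^2)
    length(y) * log(rss / length(y)) + fit$rank * log(length(y))
  }
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 36
    fam <- rep(c("FA", "FB"), each = n / 2)
    x <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
    y <- 0.8 * x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.7)
    g <- toy_genotypes(x, family = fam, markers = c("M01", "M02", "M03"))
    blues <- toy_blues(g, y)
    cof <- sort(as.character(select_cofactors(blues, g)))
    base <- model.matrix(~ factor(fam))
    subsets <- list(character(0), "M01", "M02", "M03",
                    c("M01", "M02"), c("M01", "M03"), c("M02", "M03"),
                    c("M01", "M02", "M03"))
    vals <- vapply(subsets, function(ss) {
      xx <- cbind(base, x[, match(ss, c("M01", "M02", "M03")), drop = FALSE])
      sbc(xx, y)
    }, numeric(1))
    best <- subsets[[which.min(vals)]]
    expect_equal(cof, sort(best))
  }
})

test_that("scan F and p match a brute-force normal-equations oracle", {
  skip_if_not_installed("MASS")
  for (s in 1:40) {
    inst <- random_instance(n = 20 + (s * 7) %% 41, m = 3 + s %% 6,
                            seed = 500 + s)
    g <- inst$genotypes
    mk <- dynqtl:::marker_cols(g)
    sc <- scan_markers(inst$blues, g, inst$map, cofactors = character())
    base <- model.matrix(~ factor(g$family))
    y <- inst$blues$blue
    for (q in mk) {
      xq <- g[[q]]
      if (length(unique(xq)) < 2) next
      orc <- oracle_f_test(base, cbind(base, xq), y)
      row <- sc[sc$marker == q & is.na(sc$duplicate_of), ]
      if (nrow(row) == 0) next
      # mixed tolerance: near-zero F is dominated by cancellation error
      expect_lt(abs(row$f - orc$f), 1e-10 * max(1, abs(orc$f)))
      expect_lt(abs(row$p - orc$p), 1e-10)
    }
  }
})

test_that("scan with cofactors matches the oracle and honours exclusions", {
  skip_if_not_installed("MASS")
  set.seed(9)
  inst <- random_instance(n = 60, m = 8, seed = 77,
                          beta = c(1, 0, 0, 0.8, 0, 0, 0, 0))
  g <- inst$genotypes
  map <- inst$map
  cof <- c("M01", "M04")
  sc <- scan_markers(inst$blues, g, map, cofactors = cof,
                     cofactor_window_cM = 0)
  base <- model.matrix(~ factor(g$family))
  y <- inst$blues$blue
  for (q in dynqtl:::marker_cols(g)) {
    active <- setdiff(cof, q)
    # drop cofactors identical to the tested marker
    active <- active[vapply(active, function(a) !identical(g[[a]], g[[q]]),
                            logical(1))]
    xr <- cbind(base, as.matrix(g[, active, drop = FALSE]))
    orc <- oracle_f_test(xr, cbind(xr, g[[q]]), y)
    row <- sc[sc$marker == q & is.na(sc$duplicate_of), ]
    if (nrow(row) == 0) next
    expect_equal(row$f, orc$f, tolerance = 1e-10)
  }
  # window exclusion: a cofactor within the window is dropped from the fit
  w <- 1 + abs(map$pos_cM[map$marker == "M01"] -
                 map$pos_cM[map$marker == "M02"])
  same_group <- map$group[map$marker == "M01"] == map$group[map$marker == "M02"]
  if (same_group) {
    sc_w <- scan_markers(inst$blues, g, map, cofactors = cof,
                         cofactor_window_cM = w)
    orc2 <- oracle_f_test(cbind(base, g$M04), cbind(base, g$M04, g$M02), y)
    row2 <- sc_w[sc_w$marker == "M02" & is.na(sc_w$duplicate_of), ]
    expect_equal(row2$f, orc2$f, tolerance = 1e-10)
  }
})

test_that("a marker confounded with family is absorbed by the family effect", {
  n <- 8
  fam <- rep(c("FA", "FB"), each = 4)
  x <- cbind(as.numeric(fam == "FA"), rbinom(n, 1, 0.5))
  g <- toy_genotypes(x, family = fam)
  set.seed(3)
  y <- rnorm(n) + 2 * (fam == "FA")
  blues <- toy_blues(g, y)
  map <- toy_map(pos = c(0, 50))
  sc <- scan_markers(blues, g, map)
  row <- sc[sc$marker == "M01", ]
  expect_lt(row$f, 1e-10)
  expect_false(row$significant)
  expect_true(is.na(row$beta))
})

test_that("p-values are invariant to response shifts and line permutations", {
  inst <- random_instance(n = 40, m = 6, seed = 31, beta = c(1, rep(0, 5)))
  sc0 <- scan_markers(inst$blues, inst$genotypes, inst$map)
  b2 <- inst$blues
  b2$blue <- b2$blue + 100
  sc1 <- scan_markers(b2, inst$genotypes, inst$map)
  expect_equal(sc0$p, sc1$p, tolerance = 1e-12)
  perm <- sample(nrow(inst$blues))
  b3 <- inst$blues[perm, ]
  sc2 <- scan_markers(b3, inst$genotypes, inst$map)
  expect_equal(sc0$p, sc2$p, tolerance = 1e-12)
})

test_that("duplicate marker columns collapse to one representative", {
  set.seed(5)
  n <- 30
  x <- matrix(rbinom(n * 2, 1, 0.5), n, 2)
  x <- cbind(x, x[, 1])  # M03 duplicates M01
  g <- toy_genotypes(x, family = rep(c("FA", "FB"), length.out = n))
  y <- x[, 1] * 1.5 + rnorm(n, 0, 0.5) + (g$family == "FA")
  blues <- toy_blues(g, y)
  map <- toy_map(pos = c(0, 30, 60))
  sc <- scan_markers(blues, g, map)
  expect_equal(attr(sc, "m"), 2)  # only distinct columns tested
  r1 <- sc[sc$marker == "M01", ]
  r3 <- sc[sc$marker == "M03", ]
  expect_equal(r3$duplicate_of, "M01")
  expect_equal(r1$p, r3$p)
  expect_equal(r1$beta, r3$beta)
})

test_that("missing genotypes trigger complete-case per-marker fits", {
  inst <- random_instance(n = 50, m = 5, seed = 8, missing = 0.2,
                          beta = c(1.5, 0, 0, 0, 0))
  g <- inst$genotypes
  sc <- scan_markers(inst$blues, g, inst$map)
  for (q in dynqtl:::marker_cols(g)) {
    row <- sc[sc$marker == q & is.na(sc$duplicate_of), ]
    if (nrow(row) == 1 && !is.na(row$n)) {
      expect_equal(row$n, sum(!is.na(g[[q]])))
    }
  }
})

test_that("a strong simulated QTL is declared by the Holm-corrected scan", {
  hits <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 300
    m <- 80
    fam <- rep(c("FA", "FB"), each = n / 2)
    x <- matrix(rbinom(n * m, 1, 0.5), n, m)
    y <- x[, 7] * 0.6 + rnorm(n, 0, 0.8)
    g <- toy_genotypes(x, family = fam)
    map <- toy_map(pos = seq(0, 79) * 2, groups = rep("1A", m))
    map$marker <- sprintf("M%02d", 1:m)
    sc <- scan_markers(toy_blues(g, y), g, map)
    hits <- hits + sc$significant[sc$marker == "M07"]
  }
  expect_gte(hits, 9)
})
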