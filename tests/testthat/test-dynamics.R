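# build a minimal qtl_scan-like object for region matching
fake_scan <- function(markers, groups, pos, p, beta, sig = TRUE) {
  out <- tibble::tibble(marker = markers, group = groups, pos_cM = pos,
                        n = 100L, beta = beta, f = 1, p = p,
                        significant = rep_len(sig, length(markers)),
                        duplicate_of = NA_character_)
  class(out) <- c("qtl_scan", class(out))
  out
}

test_that("region matching follows single linkage within groups", {
  s1 <- fake_scan(c("A1", "A2"), c("1A", "1A"), c(12, 15), c(1e-6, 1e-5),
                  c(0.5, 0.4))
  m <- match_regions(list(DS1 = s1), window_cM = 5)
  expect_equal(nrow(m), 1)

  # same positions, different groups: never merged
  s2 <- fake_scan(c("B1", "B2"), c("1A", "2A"), c(12, 12), c(1e-6, 1e-5),
                  c(0.5, 0.4))
  m2 <- match_regions(list(DS1 = s2), window_cM = 5)
  expect_equal(nrow(m2), 2)

  # chain 0, 4, 8, 20 with window 5: {0,4,8} and {20}
  s3 <- fake_scan(paste0("C", 1:4), rep("1A", 4), c(0, 4, 8, 20),
                  rep(1e-6, 4), rep(0.5, 4))
  m3 <- match_regions(list(DS1 = s3), window_cM = 5)
  expect_equal(nrow(m3), 2)
  members <- attr(m3, "members")
  expect_setequal(members$marker[members$region == m3$region[1]],
                  c("C1", "C2", "C3"))
})

test_that("region matching is invariant to stage input order", {
  s1 <- fake_scan(c("A1", "A2"), c("1A", "1A"), c(10, 13), c(1e-7, 1e-4),
                  c(0.5, 0.3))
  s2 <- fake_scan("A3", "1A", 16, 1e-5, -0.2)
  m_ab <- match_regions(list(DS1 = s1, DS2 = s2), window_cM = 5)
  m_ba <- match_regions(list(DS2 = s2, DS1 = s1), window_cM = 5)
  expect_equal(sort(attr(m_ab, "members")$region),
               sort(attr(m_ba, "members")$region))
})

test_that("venn classes partition regions and reconcile per-stage totals", {
  sA <- fake_scan(c("Q1", "Q2"), c("1A", "2A"), c(10, 50), c(1e-8, 1e-6),
                  c(0.6, 0.4))
  sB <- fake_scan(c("Q1", "Q3"), c("1A", "3A"), c(11, 70), c(1e-7, 1e-5),
                  c(0.5, -0.3))
  sC <- fake_scan("Q1", "1A", 12, 1e-6, 0.4)
  matches <- match_regions(list(DS1 = sA, DS2 = sB, DS3 = sC), window_cM = 5)
  vc <- venn_counts(matches)
  expect_equal(sum(vc$n), nrow(matches))
  expect_equal(vc$n[vc$venn_class == "DS1&DS2&DS3"], 1)
  expect_equal(vc$n[vc$venn_class == "DS1"], 1)
  expect_equal(vc$n[vc$venn_class == "DS2"], 1)
  # per-stage totals reconcile
  for (s in c("DS1", "DS2", "DS3")) {
    expect_equal(sum(matches[[s]]),
                 sum(vc$n[grepl(s, vc$venn_class)]))
  }
  # identical lists across all stages: everything in the triple class
  m_same <- match_regions(list(DS1 = sA, DS2 = sA, DS3 = sA), window_cM = 5)
  expect_true(all(m_same$venn_class == "DS1&DS2&DS3"))
  # disjoint lists: only single-stage classes populated
  sD <- fake_scan("Q9", "7A", 5, 1e-6, 0.2)
  m_dis <- match_regions(list(DS1 = sA, DS2 = sD), window_cM = 5)
  expect_true(all(m_dis$venn_class %in% c("DS1", "DS2")))
})

test_that("marker-level venn counts classify by marker identity", {
  sA <- fake_scan(c("Q1", "Q2"), c("1A", "2A"), c(10, 50), c(1e-8, 1e-6),
                  c(0.6, 0.4))
  sB <- fake_scan("Q1", "1A", 10, 1e-7, 0.5)
  mv <- marker_venn_counts(list(DS1 = sA, DS2 = sB))
  expect_equal(mv$n[mv$venn_class == "DS1&DS2"], 1)
  expect_equal(mv$n[mv$venn_class == "DS1"], 1)
  expect_equal(sum(mv$n), 2)
})

test_that("sign-change report flags only discordant effect signs", {
  sA <- fake_scan(c("Q1", "Q2"), c("1A", "2A"), c(10, 50), c(1e-8, 1e-6),
                  c(0.5, 0.5))
  sB <- fake_scan(c("Q1", "Q2"), c("1A", "2A"), c(10, 50), c(1e-7, 1e-5),
                  c(-0.4, 0.4))
  matches <- match_regions(list(DS1 = sA, DS3 = sB), window_cM = 5)
  rep <- sign_change_report(matches)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$stage_a, "DS1")
  expect_equal(rep$stage_b, "DS3")
  expect_equal(rep$group, "1A")
  expect_equal(sign(rep$beta_a) * sign(rep$beta_b), -1)
})

test_that("progression scan detects sign flips and cancels stable effects", {
  set.seed(14)
  n <- 400
  fam <- rep(c("FA", "FB"), each = n / 2)
  x <- matrix(rbinom(n * 20, 1, 0.5), n, 20)
  g <- toy_genotypes(x, family = fam)
  map <- toy_map(pos = rep(seq(0, 45, by = 5), 2),
                 groups = rep(c("1A", "2A"), each = 10))
  map$marker <- sprintf("M%02d", 1:20)
  b <- 0.5
  noise1 <- rnorm(n, 0, 0.15)
  noise2 <- rnorm(n, 0, 0.15)
  # M03: +b at DS1, -b at DS2 (flips); M13: +b at both (cancels)
  blues_wide <- tibble::tibble(
    line = g$line, family = g$family,
    DS1 = b * x[, 3] + b * x[, 13] + noise1,
    DS2 = -b * x[, 3] + b * x[, 13] + noise2
  )
  ps <- progression_scan(blues_wide, "DS1", "DS2", g, map)
  row3 <- ps[ps$marker == "M03", ]
  expect_true(row3$significant)
  expect_equal(row3$beta, -2 * b, tolerance = 0.15)
  row13 <- ps[ps$marker == "M13", ]
  expect_false(isTRUE(row13$significant))

  # constant progression trait aborts
  bw2 <- blues_wide
  bw2$DS2 <- bw2$DS1 + 3
  expect_error(progression_scan(bw2, "DS1", "DS2", g, map), "constant")
})

test_that("progression scan on the negated trait flips effects, keeps p", {
  set.seed(4)
  n <- 120
  fam <- rep(c("FA", "FB"), each = n / 2)
  x <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  g <- toy_genotypes(x, family = fam)
  map <- toy_map(pos = seq(0, 50, by = 10), groups = rep(c("1A", "2A"), 3))
  map <- dplyr::arrange(map, group, pos_cM)
  bw <- tibble::tibble(line = g$line, family = g$family,
                       DS1 = rnorm(n), DS2 = 0.8 * x[, 2] + rnorm(n, 0, 0.5))
  p12 <- progression_scan(bw, "DS1", "DS2", g, map)
  p21 <- progression_scan(bw, "DS2", "DS1", g, map)
  m <- match(p12$marker, p21$marker)
  expect_equal(p12$p, p21$p[m], tolerance = 1e-10)
  expect_equal(p12$beta, -p21$beta[m], tolerance = 1e-10)
})

test_that("missing map positions for significant QTL raise an error", {
  s1 <- fake_scan("Q1", NA_character_, NA_real_, 1e-8, 0.5)
  expect_error(match_regions(list(DS1 = s1)), "Q1")
})
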