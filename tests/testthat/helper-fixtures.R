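# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no data files.

# tiny two-group map with explicit positions
toy_map <- function(pos = c(0, 10, 25, 40), groups = NULL) {
  n <- length(pos)
  groups <- groups %||% rep("1A", n)
  tibble::tibble(
    marker = sprintf("M%02d", seq_len(n)),
    group = groups,
    pos_cM = pos
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype tibble from a plain matrix (rows = lines)
toy_genotypes <- function(x, family = rep("F1", nrow(x)),
                          markers = sprintf("M%02d", seq_len(ncol(x)))) {
  colnames(x) <- markers
  dplyr::bind_cols(
    tibble::tibble(line = sprintf("L%03d", seq_len(nrow(x))),
                   family = family),
    tibble::as_tibble(x)
  )
}

# BLUE tibble from a response vector aligned to a genotype tibble
toy_blues <- function(genotypes, y, stage = "DS1") {
  b <- tibble::tibble(line = genotypes$line, family = genotypes$family,
                      blue = y)
  attr(b, "stage") <- stage
  b
}

# random small scan instance: n lines, m markers, 2 families, optional
# missing rate; returns list(blues, genotypes, map)
random_instance <- function(n = 30, m = 6, seed = 1, missing = 0,
                            beta = NULL) {
  set.seed(seed)
  fam <- rep(c("FA", "FB"), length.out = n)
  x <- matrix(rbinom(n * m, 1, 0.5), n, m)
  g <- toy_genotypes(x, family = fam)
  map <- toy_map(pos = sort(runif(m, 0, 100)),
                 groups = rep(c("1A", "2A"), length.out = m))
  map$marker <- sprintf("M%02d", seq_len(m))
  y <- rnorm(n) + (fam == "FA") * 0.5
  if (!is.null(beta)) y <- y + x %*% beta
  if (missing > 0) {
    mk <- dynqtl:::marker_cols(g)
    for (mm in mk) {
      hit <- runif(n) < missing
      g[[mm]][hit] <- NA
    }
  }
  list(blues = toy_blues(g, as.numeric(y)), genotypes = g, map = map)
}

# brute-force OLS F-test oracle via explicit normal equations
oracle_f_test <- function(x_red, x_full, y) {
  rss <- function(x) {
    xtx <- crossprod(x)
    b <- tryCatch(solve(xtx, crossprod(x, y)), error = function(e) {
      MASS::ginv(xtx) %*% crossprod(x, y)
    })
    r <- y - x %*% b
    sum(r^2)
  }
  r0 <- rss(x_red)
  r1 <- rss(x_full)
  rank_full <- qr(x_full)$rank
  df2 <- length(y) - rank_full
  f <- ((r0 - r1) / 1) / (r1 / df2)
  list(f = f, p = pf(f, 1, df2, lower.tail = FALSE))
}

default_stages <- c("DS1", "DS2", "DS3")

# small but structured study: fewer markers, same family layout, scaled-down
# family sizes unless full = TRUE
small_preset <- function(n_markers = 120, n_lines = c(26, 24, 40, 40)) {
  default_study_preset(n_markers = n_markers, n_lines = n_lines)
}
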