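#' Read and write the pipeline's tabular formats
#'
#' All tables are tab-separated UTF-8 with `NA` as the missing token; comma
#' separation is accepted on read. Result tables written by [run_pipeline()]
#' carry a `#`-prefixed header comment with the stage name and configuration
#' hash for auditability.
#'
#' @name dynqtl_io
NULL

read_delim_auto <- function(path, ...) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, comment = "#", na = "NA",
                    show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a genotype table
#'
#' Expects the first column to be the line identifier (named `line`), an
#' optional `family` column, and one 0/1/NA column per marker.
#'
#' @param path TSV/CSV file path.
#' @param map Optional map tibble; marker sets are cross-checked and any
#'   symmetric difference is reported as a warning.
#' @return Genotype tibble (`line`, optional `family`, markers).
#' @export
read_genotype_tsv <- function(path, map = NULL) {
  g <- read_delim_auto(path)
  if (names(g)[1] != "line") names(g)[1] <- "line"
  if (anyDuplicated(g$line)) {
    abort(sprintf("Duplicate line ids: %s.",
                  paste(unique(g$line[duplicated(g$line)]), collapse = ", ")))
  }
  mk <- marker_cols(g)
  for (m in mk) {
    v <- g[[m]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("Non-binary genotype at line %s marker %s (value %s).",
                    g$line[bad[1]], m, v[bad[1]]))
    }
    g[[m]] <- as.numeric(v)
  }
  if (!is.null(map)) {
    only_geno <- setdiff(mk, map$marker)
    only_map <- setdiff(map$marker, mk)
    if (length(only_geno) + length(only_map) > 0) {
      warn(sprintf(
        "Genotype/map marker mismatch: %d only in genotypes (%s), %d only in map (%s).",
        length(only_geno), paste(head(only_geno, 3), collapse = ", "),
        length(only_map), paste(head(only_map, 3), collapse = ", ")
      ))
    }
  }
  g
}

#' @rdname read_genotype_tsv
#' @param genotypes Genotype tibble to write.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  readr::write_tsv(genotypes, path, na = "NA")
  invisible(path)
}

#' Read or write a genetic map table (`marker`, `group`, `pos_cM`)
#'
#' @param path TSV/CSV file path.
#' @return Validated map tibble.
#' @export
read_map_tsv <- function(path) {
  m <- read_delim_auto(path)
  validate_map(m)
  m[, c("marker", "group", "pos_cM")]
}

#' @rdname read_map_tsv
#' @param map Map tibble to write.
#' @export
write_map_tsv <- function(map, path) {
  validate_map(map)
  readr::write_tsv(map, path, na = "NA")
  invisible(path)
}

#' Read or write a plot-level phenotype table
#'
#' Columns `line`, `family`, `env`, `rep`, then one column per stage.
#'
#' @param path TSV/CSV file path.
#' @return Phenotype tibble.
#' @export
read_phenotype_tsv <- function(path) {
  p <- read_delim_auto(path)
  need <- c("line", "family", "env")
  if (!all(need %in% names(p))) {
    abort(sprintf("Phenotype table needs columns %s.",
                  paste(need, collapse = ", ")))
  }
  p
}

#' @rdname read_phenotype_tsv
#' @param phenotypes Phenotype tibble to write.
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path, na = "NA")
  invisible(path)
}

# result table with an audit header comment
write_result_tsv <- function(x, path, stage, config_hash) {
  con <- file(path, "w")
  writeLines(sprintf("# stage=%s config=%s", stage, config_hash), con)
  close(con)
  readr::write_tsv(as_tibble(x), path, na = "NA", append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Validated run configuration for the full pipeline
#'
#' Bundles input paths and analysis parameters, validating every numeric
#' bound up front. The configuration is serialised into each output
#' directory as an audit copy.
#'
#' @param genotypes,map,phenotypes Input file paths (TSV/CSV).
#' @param out_dir Output directory (created if absent).
#' @param alpha Family-wise level for main-effect scans.
#' @param cofactor_window_cM Cofactor exclusion window.
#' @param overlap_window_cM Region-matching half-window of the dynamic layer.
#' @param cv_runs,cv_folds Cross-validation replications and folds.
#' @param n_groups Linkage-group count override for the epistasis threshold
#'   (`NULL`: use the map's count).
#' @param epistasis_thin_cM Marker thinning for the pair scan (0 = full scan).
#' @param seed Master seed.
#' @param stages Stage column names, in developmental order.
#' @return List of class `run_config`.
#' @export
run_config <- function(genotypes, map, phenotypes, out_dir,
                       alpha = 0.05, cofactor_window_cM = 10,
                       overlap_window_cM = 5, cv_runs = 20, cv_folds = 5,
                       n_groups = NULL, epistasis_thin_cM = 0, seed = 1,
                       stages = c("DS1", "DS2", "DS3")) {
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  assert_number(cofactor_window_cM, "cofactor_window_cM", lower = 0)
  assert_number(overlap_window_cM, "overlap_window_cM", lower = 0)
  assert_number(cv_runs, "cv_runs", lower = 1, integer = TRUE)
  assert_number(cv_folds, "cv_folds", lower = 2, integer = TRUE)
  assert_number(epistasis_thin_cM, "epistasis_thin_cM", lower = 0)
  assert_number(seed, "seed", integer = TRUE)
  if (!is.null(n_groups)) assert_number(n_groups, "n_groups", lower = 1,
                                        integer = TRUE)
  if (length(stages) < 1) abort("Need at least one stage.")
  structure(
    list(genotypes = genotypes, map = map, phenotypes = phenotypes,
         out_dir = out_dir, alpha = alpha,
         cofactor_window_cM = cofactor_window_cM,
         overlap_window_cM = overlap_window_cM, cv_runs = cv_runs,
         cv_folds = cv_folds, n_groups = n_groups,
         epistasis_thin_cM = epistasis_thin_cM, seed = seed,
         stages = stages),
    class = "run_config"
  )
}

#' Run the full dynamic QTL pipeline
#'
#' Orchestrates BLUE computation, variance components and heritability,
#' main-effect and epistasis scans per stage, explained-genotypic-variance
#' accounting, cross-validation, and the dynamic layer (region matching,
#' Venn partitions, progression scans, sign-change report). Every result is
#' written to `config$out_dir` as a TSV with an audit header; a
#' machine-readable manifest records the seed, configuration and package
#' version. A failing stage aborts with the stage name; tables already
#' written are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  # hash the analysis parameters only, so the same analysis written to a
  # different directory carries the same audit hash
  params <- unclass(config)[setdiff(names(config),
                                    c("genotypes", "map", "phenotypes",
                                      "out_dir"))]
  cfg_hash <- rlang::hash(as.character(
    jsonlite::toJSON(params, auto_unbox = TRUE, null = "null")
  ))
  writeLines(as.character(cfg_json), file.path(config$out_dir, "config.json"))
  out <- function(...) file.path(config$out_dir, ...)
  stage_ctx <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  seeds <- derive_seeds(config$seed, 2, c("cv", "unused"))
  stages <- config$stages

  map <- stage_ctx("read_map", read_map_tsv(config$map))
  geno <- stage_ctx("read_genotypes",
                    read_genotype_tsv(config$genotypes, map = map))
  pheno <- stage_ctx("read_phenotypes", read_phenotype_tsv(config$phenotypes))
  if (!"family" %in% names(geno)) {
    fam <- pheno[!duplicated(pheno$line), c("line", "family")]
    geno <- left_join(geno, fam, by = "line") |>
      select(all_of(c("line", "family")), dplyr::everything())
  }

  blues <- stage_ctx("blue", compute_blues_wide(pheno, stages))
  write_result_tsv(blues, out("blues.tsv"), "blue", cfg_hash)

  vc <- stage_ctx("variance_components",
                  variance_components_table(pheno, stages))
  write_result_tsv(vc, out("variance_components.tsv"),
                   "variance_components", cfg_hash)
  if (length(stages) >= 2) {
    sc <- stage_ctx("stage_correlations", stage_correlations(blues, stages))
    write_result_tsv(sc, out("stage_correlations.tsv"),
                     "stage_correlations", cfg_hash)
  }
  h2 <- setNames(vc$h2, vc$stage)

  scans <- list()
  episcans <- list()
  n_groups <- config$n_groups %||% length(unique(map$group))
  for (s in stages) {
    b <- blues[, c("line", "family", s)]
    names(b)[3] <- "blue"
    attr(b, "stage") <- s
    scans[[s]] <- stage_ctx(paste0("scan_", s), association_scan(
      b, geno, map, alpha = config$alpha,
      cofactor_window_cM = config$cofactor_window_cM
    ))
    write_result_tsv(as_tibble(scans[[s]]), out(sprintf("scan_%s.tsv", s)),
                     paste0("scan_", s), cfg_hash)
    episcans[[s]] <- stage_ctx(paste0("episcan_", s), scan_pairs(
      b, geno, map,
      threshold = epistasis_threshold(n_groups, config$alpha),
      thin_cM = config$epistasis_thin_cM
    ))
    write_result_tsv(as_tibble(episcans[[s]]),
                     out(sprintf("episcan_%s.tsv", s)),
                     paste0("episcan_", s), cfg_hash)

    sig <- scans[[s]]$marker[scans[[s]]$significant &
                               is.na(scans[[s]]$duplicate_of)]
    if (length(sig) > 0) {
      shares <- stage_ctx(paste0("pg_", s), sequential_partial_r2(
        b, geno,
        marker_p = scans[[s]][match(sig, scans[[s]]$marker),
                              c("marker", "p")],
        h2 = h2[[s]], map = map
      ))
      write_result_tsv(shares, out(sprintf("pg_%s.tsv", s)),
                       paste0("pg_", s), cfg_hash)
    }
  }

  cvs <- list()
  for (s in stages) {
    b <- blues[, c("line", "family", s)]
    names(b)[3] <- "blue"
    attr(b, "stage") <- s
    cvs[[s]] <- stage_ctx(paste0("cv_", s), run_cv(
      b, geno, map, h2 = h2[[s]], runs = config$cv_runs,
      folds = config$cv_folds, seed = seeds[["cv"]],
      alpha = config$alpha,
      cofactor_window_cM = config$cofactor_window_cM
    ))
  }
  cv_summary <- purrr::map_dfr(cvs, function(x) x$summary)
  write_result_tsv(cv_summary, out("cv_summary.tsv"), "cv", cfg_hash)
  det <- purrr::map_dfr(stages, function(s) {
    mutate(detection_frequency(cvs[[s]], map, config$overlap_window_cM),
           stage = s)
  })
  write_result_tsv(det, out("cv_detection_frequency.tsv"), "cv", cfg_hash)

  dyn <- stage_ctx("dynamics", {
    matches <- match_regions(scans, window_cM = config$overlap_window_cM)
    list(matches = matches,
         venn = venn_counts(matches),
         marker_venn = marker_venn_counts(scans),
         signs = sign_change_report(matches),
         profile = temporal_pg_profile(matches, scans, blues, geno, h2))
  })
  write_result_tsv(as_tibble(dyn$matches), out("regions.tsv"), "dynamics",
                   cfg_hash)
  write_result_tsv(dyn$venn, out("venn_regions.tsv"), "dynamics", cfg_hash)
  write_result_tsv(dyn$marker_venn, out("venn_markers.tsv"), "dynamics",
                   cfg_hash)
  write_result_tsv(dyn$signs, out("sign_changes.tsv"), "dynamics", cfg_hash)
  write_result_tsv(dyn$profile, out("temporal_pg.tsv"), "dynamics", cfg_hash)

  progressions <- list()
  if (length(stages) >= 2) {
    for (i in seq_len(length(stages) - 1)) {
      lab <- paste0(stages[i + 1], "-", stages[i])
      progressions[[lab]] <- stage_ctx(paste0("progression_", lab), {
        tryCatch(
          progression_scan(blues, stages[i], stages[i + 1], geno, map,
                           alpha = config$alpha,
                           cofactor_window_cM = config$cofactor_window_cM),
          error = function(e) NULL
        )
      })
      if (!is.null(progressions[[lab]])) {
        write_result_tsv(as_tibble(progressions[[lab]]),
                         out(sprintf("progression_%s.tsv", lab)),
                         paste0("progression_", lab), cfg_hash)
      }
    }
  }

  manifest <- list(
    package = "dynqtl",
    version = as.character(utils::packageVersion("dynqtl")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = cfg_hash,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(list(blues = blues, variance_components = vc, h2 = h2,
                 scans = scans, episcans = episcans, cv = cvs,
                 dynamics = dyn, progressions = progressions,
                 config_hash = cfg_hash))
}

#' Write all tables of a simulated study to a directory
#'
#' Writes the genotype, map and phenotype TSVs plus a provenance JSON
#' (seed and preset parameters), the on-disk starting point for
#' [run_pipeline()].
#'
#' @param sim A `study_simulation` from [simulate_study()].
#' @param dir Output directory.
#' @param seed Seed recorded in the provenance file.
#' @return The directory, invisibly.
#' @export
write_study_tsv <- function(sim, dir, seed = NA) {
  stopifnot(inherits(sim, "study_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_map_tsv(sim$map, file.path(dir, "map.tsv"))
  write_phenotype_tsv(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  prov <- list(
    seed = seed,
    n_lines = sum(sim$design$n_lines),
    families = as.list(setNames(sim$design$n_lines, sim$design$family)),
    n_markers = nrow(sim$map),
    n_groups = length(unique(sim$map$group)),
    stages = sim$truth$arch$stages,
    qtl = sim$truth$arch$qtl,
    epistasis = sim$truth$arch$epistasis
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
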