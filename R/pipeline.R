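# recognised configuration keys with their defaults; every threshold is
# echoed verbatim into the report
default_run_config <- function() {
  list(
    # inputs: either a VCF + metadata ...
    vcf = NULL, metadata = NULL,
    # ... or a simulated cohort (any cohort_spec argument prefixed sim_)
    simulate = TRUE,
    sim_n_pops_sp1 = 8L, sim_n_pops_sp2 = 4L, sim_samples_per_pop = 4L,
    sim_n_sites = 5000L, sim_fixed_diff_fraction = 0.1,
    sim_fst_drift = 0.3, sim_clone_mutation_rate = 0.001,
    sim_region_extent_km = 200, sim_ibd_strength = 100,
    sim_mean_depth = 60, sim_error_rate = 0.001, sim_missing_rate = 0.02,
    sim_ploidy_sp2 = "MMT", sim_reference = "Lm",
    # stage thresholds
    qual_min = 20, dp_min = 10, dp_max = 1000, completeness = 0.8,
    fdr_thresh = 0.05, dev_thresh = 80,
    spectrum_min_depth = 20, cluster_height = 0.15, cluster_k = NULL,
    nperm = 9999,
    exclude_samples = character(0),
    seed = 1L,
    out_dir = NULL
  )
}

#' Read a plain-text key = value run configuration
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines are ignored.  Values are coerced to numeric where
#' possible; comma-separated values become vectors.  Unknown keys are
#' rejected.
#'
#' @param path configuration file.
#' @return Named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  config <- list()
  for (line in lines) {
    kv <- strsplit(line, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", line)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    config[[key]] <- if (!anyNA(num)) num else parts
  }
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> filter -> distances -> cluster ->
#' species assignment -> assignment-marker scan -> allele-balance ploidy
#' -> sub-genome coverage -> structure statistics -> isolation by
#' distance, and writes a machine-readable JSON report plus TSV/newick
#' artifacts.  Every stage threshold is echoed into the report, every
#' written file is checksummed, and the run is deterministic given the
#' seed.
#'
#' Species assignment for the per-species statistics uses the sub-genome
#' coverage call when the variant table carries both M and T tags, and
#' otherwise a two-way cut of the distance dendrogram; the report
#' records which rule fired.
#'
#' @param config named list of options (see `default_run_config` in the
#'   package sources), or the path of a key = value text file.  Unknown
#'   keys are rejected.
#' @return The report, invisibly (a nested list; also written as
#'   `report.json` under `out_dir` when set).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  t0 <- proc.time()[["elapsed"]]
  report <- list(thresholds = cfg[c("qual_min", "dp_min", "dp_max",
                                    "completeness", "fdr_thresh",
                                    "dev_thresh", "spectrum_min_depth",
                                    "cluster_height", "nperm", "seed")],
                 stages = list(), notices = character(0))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  written <- character(0)
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]]$seconds <<- round(proc.time()[["elapsed"]] - t1, 3)
    res
  }

  # --- input -------------------------------------------------------------
  if (!is.null(cfg$vcf)) {
    table <- stage("input", read_vcf(cfg$vcf))
    meta <- if (!is.null(cfg$metadata)) read_metadata(cfg$metadata) else NULL
    truth <- NULL
  } else if (isTRUE(cfg$simulate) || identical(cfg$simulate, 1)) {
    sim_args <- cfg[grepl("^sim_", names(cfg))]
    names(sim_args) <- sub("^sim_", "", names(sim_args))
    sim_args$seed <- cfg$seed
    spec <- do.call(cohort_spec, sim_args)
    cohort <- stage("input", simulate_cohort(spec))
    table <- cohort$table
    truth <- cohort$truth
    meta <- truth$samples[, c("sample", "population", "lat", "lon")]
    if (!is.null(out_dir)) {
      written <- c(written, write_cohort(table, truth,
                                         file.path(out_dir, "cohort")))
    }
  } else {
    stop("config must either set vcf or simulate = TRUE")
  }
  if (length(cfg$exclude_samples)) {
    keep <- !(table$samples %in% cfg$exclude_samples)
    table <- subset_variant_table(table, samples = keep)
    if (!is.null(meta)) meta <- meta[!(meta$sample %in% cfg$exclude_samples), ]
    report$notices <- c(report$notices,
                        paste("excluded samples:",
                              paste(cfg$exclude_samples, collapse = ", ")))
  }
  report$stages$input$n_sites <- nrow(table$sites)
  report$stages$input$n_samples <- length(table$samples)

  # --- filter ------------------------------------------------------------
  filtered <- stage("filter", filter_variants(
    table, qual_min = cfg$qual_min, dp_min = cfg$dp_min,
    dp_max = cfg$dp_max, completeness = cfg$completeness))
  report$stages$filter$counts <- as.list(attr(filtered, "filter_counts"))

  # --- distances & clustering --------------------------------------------
  d <- stage("distance", pairwise_allele_distance(filtered))
  cl <- stage("cluster", if (is.null(cfg$cluster_k)) {
    cluster_samples(d, h = cfg$cluster_height)
  } else {
    cluster_samples(d, k = cfg$cluster_k)
  })
  report$stages$cluster$groups <- as.list(cl$groups)
  if (!is.null(out_dir)) {
    p1 <- file.path(out_dir, "distance.tsv")
    write_distance_tsv(d, p1)
    p2 <- file.path(out_dir, "dendrogram.nwk")
    writeLines(cl$newick, p2)
    written <- c(written, p1, p2)
  }

  # --- species assignment ------------------------------------------------
  has_both_sg <- all(c("M", "T") %in% table$sites$subgenome)
  if (has_both_sg) {
    cov_calls <- vapply(filtered$samples, function(s) {
      subgenome_coverage(filtered, s)$call
    }, "")
    species <- ifelse(cov_calls == "pure_M", "sp1", "sp2")
    rule <- "subgenome_coverage"
    report$stages$coverage$calls <- as.list(cov_calls)
  } else {
    two <- cluster_samples(d, k = 2)$groups
    species <- paste0("sp", two)
    rule <- "two_way_clustering"
  }
  names(species) <- filtered$samples
  report$stages$species <- list(rule = rule, assignment = as.list(species))

  # --- assignment-marker scan --------------------------------------------
  if (length(unique(species)) == 2 && all(table(species) >= 3)) {
    scan <- stage("scan", scan_assignment_markers(
      filtered, species, fdr_thresh = cfg$fdr_thresh,
      dev_thresh = cfg$dev_thresh))
    report$stages$scan <- scan$summary
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "assignment_scan.tsv")
      write.table(scan$table, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      written <- c(written, p)
    }
  } else {
    report$notices <- c(report$notices,
                        "scan skipped: need two species with >= 3 samples each")
  }

  # --- allele-balance ploidy ---------------------------------------------
  ploidy <- stage("ploidy", {
    vapply(filtered$samples, function(s) {
      sp <- suppressWarnings(allele_ratio_spectrum(
        filtered, s, min_depth = cfg$spectrum_min_depth))
      classify_hybrid_dosage(sp)$class
    }, "")
  })
  report$stages$ploidy$dosage_class <- as.list(ploidy)
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "dosage_classes.tsv")
    write.table(data.frame(sample = names(ploidy), dosage_class = ploidy),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  }

  # --- structure statistics ----------------------------------------------
  if (!is.null(meta)) {
    pops <- meta$population[match(filtered$samples, meta$sample)]
    wb <- within_between_summary(d, pops)
    report$stages$structure$within_mean <- wb$within_mean
    report$stages$structure$between_mean <- wb$between_mean
    sizes <- table(pops)
    if (sum(sizes >= 2) >= 2) {
      keep <- pops %in% names(sizes)[sizes >= 2]
      disp <- stage("dispersion", dispersion_test(
        d[keep, keep], pops[keep], nperm = cfg$nperm, seed = cfg$seed))
      report$stages$structure$dispersion <-
        list(f_stat = disp$f_stat, p = disp$p, nperm = disp$nperm)
    }
    ibd <- stage("ibd", ibd_test(
      d, meta[match(filtered$samples, meta$sample), ],
      nperm = cfg$nperm, seed = cfg$seed))
    report$stages$ibd <- list(mantel_r = ibd$mantel$r, mantel_p = ibd$mantel$p,
                              pearson_r = ibd$pearson_r,
                              anova_f = ibd$anova_f, anova_p = ibd$anova_p)
  } else {
    report$notices <- c(report$notices,
                        "IBD and dispersion skipped: no metadata provided")
  }

  # --- report ------------------------------------------------------------
  report$files <- if (length(written)) {
    as.list(unname(tools::md5sum(unlist(written))))
  } else {
    list()
  }
  names(report$files) <- basename(unlist(written))
  report$total_seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(report)
}
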