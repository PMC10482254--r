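#' Default pipeline configuration
#'
#' A nested list mirroring the YAML layout accepted by [run_pipeline()]:
#' a `seed`, either a `simulate` block (overrides for [sim_config()]) or an
#' `inputs` block (`ped`, `vcf`, and `markers` and/or `regions` file paths),
#' plus `scan` ([scan_params()] overrides), `cascade` ([cascade_config()]
#' overrides) and `report` (`annotations`/`expression` paths, `window`,
#' `z_threshold`).
#'
#' @return A nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(),
    scan = list(max_errors = 0, min_markers = 1, boundary = "inner",
                missing = "compatible"),
    cascade = list(),
    report = list(window = c(0.1, 2.4), z_threshold = 1)
  )
}

#' Write / read a pipeline configuration file
#'
#' @param config A nested configuration list.
#' @param path YAML file path.
#' @return `write_pipeline_config()` the config invisibly;
#'   `read_pipeline_config()` a list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(config)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the end-to-end pipeline
#'
#' Simulate (or read) inputs, scan for linked regions, run the filter
#' cascade, and write the candidate report, with a reproducibility manifest.
#' Outputs in `out_dir`: `regions.bed`, `regions.tsv`, `survivors.vcf`,
#' `trace.tsv`, `report.tsv`, `manifest.json`. Given the same configuration
#' and seed, `trace.tsv` and `report.tsv` are byte-identical across runs.
#'
#' @param config A nested list (see [default_pipeline_config()]) or a path to
#'   a YAML file.
#' @param out_dir Output directory, created if needed.
#' @param seed Optional override of `config$seed`.
#' @return A `coseg_run` list: `out_dir`, `paths`, `regions`, `cascade`,
#'   `report`, `manifest` (invisibly).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  defaults <- default_pipeline_config()
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  if (!is.null(seed)) config$seed <- as.integer(seed)

  inputs <- config$inputs
  if (!is.null(inputs)) {
    paths <- unlist(inputs[intersect(names(inputs),
                                     c("ped", "vcf", "markers", "regions"))])
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files)) {
      abort(paste0("missing input files: ", paste(missing_files, collapse = ", ")))
    }
    if (is.null(inputs$ped) || is.null(inputs$vcf)) {
      abort("inputs block needs at least ped and vcf")
    }
    if (is.null(inputs$markers) && is.null(inputs$regions)) {
      abort("inputs block needs markers (to scan) or regions (precomputed)")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, from) {
    timings[[name]] <<- round(as.numeric(Sys.time()) - as.numeric(from), 3)
    Sys.time()
  }

  digests <- list()
  if (is.null(inputs)) {
    scfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    sim <- simulate_family(scfg)
    ped <- sim$pedigree
    variants <- sim$variants
    markers <- sim$markers
    regions_in <- NULL
  } else {
    ped <- read_ped(inputs$ped)
    variants <- read_vcf(inputs$vcf, ped)
    markers <- if (!is.null(inputs$markers)) read_markers(inputs$markers) else NULL
    regions_in <- if (!is.null(inputs$regions)) read_regions(inputs$regions) else NULL
    digests <- as.list(tools::md5sum(unlist(inputs[c("ped", "vcf", "markers",
                                                     "regions")])[!is.na(unlist(inputs[c("ped", "vcf", "markers", "regions")]))]))
  }
  t1 <- tick("inputs", t0)

  regs <- if (!is.null(regions_in)) {
    regions_in
  } else {
    do.call(scan_regions,
            list(markers, ped, do.call(scan_params, config$scan)))
  }
  t2 <- tick("scan", t1)

  casc_cfg <- do.call(cascade_config, config$cascade)
  casc <- run_cascade(variants, ped, regs, casc_cfg)
  t3 <- tick("cascade", t2)

  rep_cfg <- config$report
  annotations <- if (!is.null(rep_cfg$annotations)) read_annotations(rep_cfg$annotations)
  expression <- if (!is.null(rep_cfg$expression)) read_expression(rep_cfg$expression)
  report <- build_report(casc$survivors, annotations, expression,
                         window = rep_cfg$window %||% c(0.1, 2.4),
                         z_threshold = rep_cfg$z_threshold %||% 1,
                         trace = casc$trace)
  t4 <- tick("report", t3)

  paths <- list(
    regions_bed = file.path(out_dir, "regions.bed"),
    regions_tsv = file.path(out_dir, "regions.tsv"),
    survivors_vcf = file.path(out_dir, "survivors.vcf"),
    trace_tsv = file.path(out_dir, "trace.tsv"),
    report_tsv = file.path(out_dir, "report.tsv"),
    manifest_json = file.path(out_dir, "manifest.json")
  )
  write_regions(regs, paths$regions_bed, "bed")
  write_regions(regs, paths$regions_tsv, "table_tsv")
  write_vcf(casc$survivors, paths$survivors_vcf)
  write_tsv(casc$trace, paths$trace_tsv, na = "")
  write_report(report, paths$report_tsv)

  manifest <- list(
    package = as.character(utils::packageVersion("cosegr")),
    seed = config$seed,
    config = config,
    input_digests = digests,
    stage_counts = as.list(setNames(casc$counts$n_out, casc$counts$stage)),
    n_input_variants = nrow(variants),
    n_regions = nrow(regs),
    n_survivors = nrow(casc$survivors),
    timings_sec = timings
  )
  jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  out <- list(out_dir = out_dir, paths = paths, regions = regs,
              cascade = casc, report = report, manifest = manifest)
  class(out) <- "coseg_run"
  invisible(out)
}

#' @export
print.coseg_run <- function(x, ...) {
  cat("<coseg_run> ", x$out_dir, "\n", sep = "")
  cat(sprintf("  %d input variants, %d linked regions, %d survivors\n",
              x$manifest$n_input_variants, x$manifest$n_regions,
              x$manifest$n_survivors))
  invisible(x)
}
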