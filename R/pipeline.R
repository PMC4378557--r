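# Structured run configuration and the umbrella pipeline driver behind the
# sbkit command-line script. Every run writes a manifest recording input
# checksums, parameters, seed and package version, so that identical
# config + seed reproduces byte-identical outputs.

CONFIG_KEYS <- c("genome", "annotation", "site_tables", "output_dir",
                 "seed", "window_width", "bin_edges", "confidence_q",
                 "p_local", "local_window", "alpha", "depth",
                 "n_replicates")

#' Load and validate a run configuration
#'
#' YAML configuration with path entries (`genome`, `annotation`,
#' `site_tables`, `output_dir`) and per-module parameters (`seed`,
#' `window_width`, `bin_edges`, `confidence_q`, `p_local`, `local_window`,
#' `alpha`, `depth`, `n_replicates`). Unknown keys are rejected; referenced
#' input paths must exist.
#'
#' @param path YAML file path, or a named list of the same shape.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("genome", "annotation")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config path '", key, "' does not exist: ", cfg[[key]])
    }
  }
  for (p in cfg$site_tables) {
    if (!file.exists(p)) stop("site table does not exist: ", p)
  }
  defaults <- list(seed = 1L, window_width = 20000L,
                   bin_edges = c(0, 1, 5, 12.5, 50, 100),
                   confidence_q = 25, p_local = 0.85, local_window = 6e6,
                   alpha = 0.05, depth = 10000, n_replicates = 3L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  structure(cfg, class = "run_config")
}

write_manifest <- function(config, subcommand, inputs, outputs, dir) {
  lines <- c(
    paste0("sbkit_version: ", as.character(packageVersion("sbkit"))),
    paste0("subcommand: ", subcommand),
    paste0("seed: ", config$seed),
    paste0("parameters: ",
           paste(sprintf("%s=%s",
                         setdiff(names(config),
                                 c("genome", "annotation", "site_tables",
                                   "output_dir")),
                         vapply(config[setdiff(names(config),
                                               c("genome", "annotation",
                                                 "site_tables",
                                                 "output_dir"))],
                                function(v) paste(v, collapse = ","),
                                character(1))),
                 collapse = " ")),
    "inputs:",
    if (length(inputs)) {
      paste0("  ", inputs, " md5=", tools::md5sum(inputs))
    } else "  (none)",
    "outputs:",
    if (length(outputs)) paste0("  ", outputs) else "  (none)"
  )
  manifest <- file.path(dir, paste0("manifest_", subcommand, ".txt"))
  writeLines(lines, manifest)
  manifest
}

#' Run an sbkit pipeline subcommand
#'
#' Executes one analysis stage from a [run_config()], writes its artifacts
#' under `output_dir`, and records a manifest (input checksums, parameters,
#' seed, package version). Deterministic given config + seed.
#'
#' Subcommands:
#' * `ta-index`: BED of every TA position in the genome.
#' * `simulate`: a clonal tumor with replicate profiles, written as site
#'   tables (one per replicate).
#' * `clonality-fdr`: leave-one-out FDR table from the configured replicate
#'   site tables.
#' * `bias-scan`: PRIM window report from the pooled configured site tables.
#'
#' @param config A `run_config` (or path/list coercible to one).
#' @param subcommand One of the stage names above.
#' @return Invisible character vector of output paths (manifest last).
#' @export
run_pipeline <- function(config,
                         subcommand = c("ta-index", "simulate",
                                        "clonality-fdr", "bias-scan")) {
  subcommand <- match.arg(subcommand)
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir <- config$output_dir
  if (is.null(dir)) stop("config must set output_dir")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  outputs <- character(0)
  if (subcommand == "ta-index") {
    if (is.null(config$genome)) stop("'ta-index' requires a genome path")
    genome <- read_genome(config$genome)
    idx <- build_ta_index(genome)
    out <- file.path(dir, "ta_sites.bed")
    write_bed(ta_sites(idx), out)
    inputs <- config$genome
    outputs <- out
  } else if (subcommand == "simulate") {
    if (is.null(config$genome)) stop("'simulate' requires a genome path")
    genome <- read_genome(config$genome)
    idx <- build_ta_index(genome)
    tumor <- simulate_tumor(idx, seed = config$seed)
    reps <- simulate_replicates(tumor, n_replicates = config$n_replicates,
                                depth = config$depth,
                                seed = config$seed + 1L)
    outputs <- vapply(names(reps), function(r) {
      out <- file.path(dir, paste0("sim_", r, ".tsv"))
      write_site_table(reps[[r]], out,
                       sample_id = paste0(tumor$sample_id, "_", r))
      out
    }, character(1))
    inputs <- config$genome
  } else if (subcommand == "clonality-fdr") {
    if (length(config$site_tables) < 2L) {
      stop("'clonality-fdr' requires >= 2 replicate site tables")
    }
    reps <- lapply(config$site_tables, read_site_table)
    fdr <- estimate_fdr(reps, edges = config$bin_edges)
    out <- file.path(dir, "fdr_table.tsv")
    write.table(as.data.frame(fdr), out, sep = "\t", quote = FALSE,
                row.names = FALSE)
    inputs <- unlist(config$site_tables)
    outputs <- out
  } else if (subcommand == "bias-scan") {
    if (is.null(config$genome) || length(config$site_tables) == 0L) {
      stop("'bias-scan' requires a genome and site tables")
    }
    genome <- read_genome(config$genome)
    sites <- do.call(rbind, lapply(config$site_tables, read_site_table))
    windows <- partition_windows(genome, width = config$window_width)
    prim <- fit_prim(windows, sites)
    scanned <- window_pvalues(prim, alpha = config$alpha)
    annot <- if (!is.null(config$annotation)) {
      read_annotation(config$annotation)
    }
    out <- file.path(dir, "window_report.tsv")
    write_window_report(scanned, out, annot = annot)
    inputs <- c(config$genome, unlist(config$site_tables))
    outputs <- out
  }
  manifest <- write_manifest(config, subcommand, inputs, outputs, dir)
  invisible(c(outputs, manifest))
}
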