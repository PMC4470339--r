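#' Pipeline configuration
#'
#' Assembles and validates the parameter set for [run_pipeline()]. Two
#' presets are provided: `"desk"` (k = 50, 100 repeats, k2 = 10), sized for
#' interactive work and testing, and `"paper"` (k = 1500, 1000 repeats,
#' k2 = 100), the full-scale parameterization for a complete 10-stage
#' transcriptome. Both run the identical code path.
#'
#' @param counts path to a counts TSV or a [meristem_counts()] object.
#' @param out_dir output directory (created if missing).
#' @param profile `"desk"` or `"paper"` parameter preset.
#' @param filter_threshold minimum normalized count for the expression
#'   filter (default 5).
#' @param fdr FDR threshold for DE calls (default 0.05).
#' @param k,repeats,k2 clustering parameters; defaults come from `profile`.
#' @param min_size minimum cluster size for the dynamic cut (default 5).
#' @param focus_stage,margin pattern classifier parameters.
#' @param seed RNG seed for the clustering ensembles.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts, out_dir, profile = c("desk", "paper"),
                            filter_threshold = 5, fdr = 0.05,
                            k = NULL, repeats = NULL, k2 = NULL,
                            min_size = 5, focus_stage = 5, margin = 0.2,
                            seed = 1) {
  profile <- match.arg(profile)
  preset <- if (profile == "paper") list(k = 1500, repeats = 1000, k2 = 100)
  else list(k = 50, repeats = 100, k2 = 10)
  cfg <- list(counts = counts, out_dir = out_dir, profile = profile,
              filter_threshold = filter_threshold, fdr = fdr,
              k = if (is.null(k)) preset$k else k,
              repeats = if (is.null(repeats)) preset$repeats else repeats,
              k2 = if (is.null(k2)) preset$k2 else k2,
              min_size = min_size, focus_stage = focus_stage,
              margin = margin, seed = as.integer(seed))
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("fdr must lie in (0, 1)")
  if (cfg$filter_threshold < 0) stop("filter_threshold must be >= 0")
  for (key in c("k", "repeats", "k2", "min_size"))
    if (cfg[[key]] < 1) stop(key, " must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()] (`counts`,
#' `out_dir`, `profile`, `filter_threshold`, `fdr`, `k`, `repeats`, `k2`,
#' `min_size`, `focus_stage`, `margin`, `seed`).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (key in c("counts", "out_dir"))
    if (is.null(y[[key]])) stop("configuration must set '", key, "'")
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end workflow on a count matrix: size-factor
#' normalization, the expression filter, consecutive-stage differential
#' expression, relative expression profiles, two-tier consensus clustering
#' and transition-point pattern classification. All declared TSV outputs
#' plus a JSON manifest (parameter echo, seed, package version, summary
#' statistics) are written to `config$out_dir`. Fully deterministic given
#' the seed; sample columns are aligned by their stage/replicate metadata,
#' so permuting input columns does not change any result.
#'
#' @param config a [pipeline_config()].
#' @param verbose emit progress messages (default TRUE).
#' @return invisibly, a list with the in-memory results (`norm`,
#'   `size_factors`, `expressed`, `de`, `profiles`, `tier1`, `super`,
#'   `patterns`, `manifest`, `paths`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  counts <- if (inherits(config$counts, "meristem_counts")) config$counts
  else read_counts_tsv(config$counts)
  ord <- order(counts$samples$experiment, counts$samples$stage,
               counts$samples$replicate)
  counts <- meristem_counts(counts$counts[, ord, drop = FALSE],
                            counts$samples[ord, , drop = FALSE])

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }

  s <- compute_size_factors(counts)
  norm <- normalize_counts(counts, s)
  expressed <- filter_expressed(norm, threshold = config$filter_threshold)
  say("normalized %d genes x %d samples; %d genes pass the expression filter",
      nrow(counts$counts), ncol(counts$counts), length(expressed))

  de <- de_series(norm, fdr = config$fdr)
  say("DE genes per consecutive stage pair: %s",
      paste(sprintf("%s=%d", names(de$n_de), de$n_de), collapse = ", "))

  avg <- stage_average(norm)
  profiles <- relative_expression(avg[expressed, , drop = FALSE])

  k <- config$k
  if (k > length(expressed))
    stop("k = ", k, " exceeds the ", length(expressed),
         " filtered genes; scale k down")
  tier1 <- consensus_cluster(profiles, k = k, repeats = config$repeats,
                             min_size = config$min_size, seed = config$seed)
  k2 <- min(config$k2, length(tier1$clusters))
  super <- supercluster(tier1, profiles, k2 = k2, repeats = config$repeats,
                        min_size = config$min_size, seed = config$seed)
  cov1 <- 1 - length(tier1$unassigned) / length(expressed)
  cov2 <- mean(!is.na(super$gene_assignment))
  say("tier 1: %d clusters (%.0f%% of filtered genes); tier 2: %d super-clusters (%.0f%%)",
      length(tier1$clusters), 100 * cov1, length(super$super_members), 100 * cov2)

  patterns <- classify_patterns(profiles, focus_stage = config$focus_stage,
                                margin = config$margin)

  paths <- list(
    size_factors = emit("size_factors.tsv", function(p)
      utils::write.table(data.frame(sample = names(s), size_factor = s),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)),
    normalized = emit("normalized.tsv", function(p) write_counts_tsv(norm, p)),
    profiles = emit("profiles.tsv", function(p)
      utils::write.table(data.frame(gene_id = rownames(profiles$values),
                                    profiles$values, check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)),
    de_summary = emit("de_summary.tsv", function(p)
      utils::write.table(data.frame(pair = names(de$n_de), n_de = de$n_de),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)),
    assignments = emit("assignments.tsv", function(p) {
      genes <- rownames(profiles$values)
      utils::write.table(
        data.frame(gene_id = genes,
                   cluster = tier1$assignment[genes],
                   supercluster = super$gene_assignment[genes],
                   pattern = patterns[genes]),
        p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    }),
    cluster_profiles = emit("cluster_profiles.tsv", function(p)
      utils::write.table(data.frame(cluster = rownames(tier1$mean_profiles),
                                    tier1$mean_profiles, check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)),
    supercluster_profiles = emit("supercluster_profiles.tsv", function(p)
      utils::write.table(data.frame(supercluster = rownames(super$mean_profiles),
                                    super$mean_profiles, check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  )
  for (pair in names(de$tables))
    paths[[paste0("de_", pair)]] <- emit(sprintf("de_%s.tsv", pair), function(p)
      write_de_tsv(de$tables[[pair]], p))

  manifest <- list(
    package = "meristemr",
    version = as.character(utils::packageVersion("meristemr")),
    seed = config$seed,
    parameters = config[c("profile", "filter_threshold", "fdr", "k",
                          "repeats", "k2", "min_size", "focus_stage",
                          "margin")],
    n_genes = nrow(counts$counts),
    n_samples = ncol(counts$counts),
    n_expressed = length(expressed),
    n_de = as.list(de$n_de),
    n_clusters = length(tier1$clusters),
    cluster_coverage = cov1,
    n_superclusters = length(super$super_members),
    supercluster_coverage = cov2,
    pattern_counts = as.list(table(patterns)))
  paths$manifest <- emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
  ok <- TRUE
  invisible(list(norm = norm, size_factors = s, expressed = expressed,
                 de = de, profiles = profiles, tier1 = tier1, super = super,
                 patterns = patterns, manifest = manifest, paths = paths))
}

#' Simulate counts and write them to disk
#'
#' Wraps [simulate_counts()]: generates a synthetic data set from a
#' simulation spec (object or YAML path), writes the count matrix and the
#' ground truth as TSV and prints a short summary.
#'
#' @param spec a [simulation_spec()] or path to a YAML spec.
#' @param out_dir output directory.
#' @param seed optional seed overriding the spec's.
#' @param verbose print the summary (default TRUE).
#' @return invisibly, list with `counts`, `truth` and the output `paths`.
#' @export
simulate_counts_files <- function(spec, out_dir, seed = NULL, verbose = TRUE) {
  if (is.character(spec)) spec <- read_simulation_spec(spec)
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  sim <- simulate_counts(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(counts = file.path(out_dir, "counts.tsv"),
                truth = file.path(out_dir, "truth.tsv"))
  write_counts_tsv(sim$counts, paths$counts)
  write_truth_tsv(sim$truth, paths$truth)
  if (verbose) {
    tab <- table(sim$truth$archetype)
    message(sprintf("simulated %d genes x %d samples (%d stages x %d replicates); archetypes: %s",
                    nrow(sim$counts$counts), ncol(sim$counts$counts),
                    spec$n_stages, spec$n_replicates,
                    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(c(sim, list(paths = paths)))
}
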