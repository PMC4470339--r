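#' Archetype profile specification
#'
#' Describes one planted expression-profile archetype: a named shape over the
#' developmental stages (relative levels in \[0, 1\] with maximum exactly 1),
#' the number of genes drawn from it, and the range of mean expression at the
#' profile maximum.
#'
#' @param name label for the archetype.
#' @param shape numeric vector of relative levels, one per stage; must be
#'   non-negative with `max(shape) == 1`.
#' @param n_genes number of genes to simulate from this archetype.
#' @param base_mean_range length-2 interval for the mean count at the
#'   profile maximum; per-gene base means are drawn log-uniformly from it.
#' @return an `archetype_spec` object.
#' @export
archetype_spec <- function(name, shape, n_genes, base_mean_range = c(200, 1000)) {
  shape <- as.numeric(shape)
  if (any(shape < 0) || !isTRUE(all.equal(max(shape), 1)))
    stop("archetype shape must be non-negative with max equal to 1")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (length(base_mean_range) != 2L || any(base_mean_range <= 0) ||
      base_mean_range[2] < base_mean_range[1])
    stop("base_mean_range must be a positive increasing interval")
  structure(list(name = as.character(name), shape = shape,
                 n_genes = as.integer(n_genes),
                 base_mean_range = as.numeric(base_mean_range)),
            class = "archetype_spec")
}

#' Default archetype set
#'
#' Seven archetypes over ten stages mirroring the profile classes seen in
#' meristem development time courses: a flat profile, a pronounced spike at
#' M5 (the S-phase/histone-like pattern), a dip at M5, an M4-up/M5-down/M6-up
#' double peak (the mitotic-cyclin-like pattern), monotone increase, monotone
#' decrease, and a late burst at M9-M10 (floral-organ-identity-like).
#'
#' @param n_genes_each genes per archetype.
#' @param base_mean_range interval for base means at the profile maximum.
#' @return list of [archetype_spec()] objects.
#' @export
default_archetypes <- function(n_genes_each = 100, base_mean_range = c(200, 1000)) {
  shapes <- list(
    flat      = rep(1, 10),
    spike_m5  = c(0.15, 0.15, 0.2, 0.3, 1, 0.3, 0.2, 0.15, 0.15, 0.15),
    dip_m5    = c(0.9, 0.9, 0.9, 1, 0.25, 1, 0.9, 0.9, 0.9, 0.9),
    m4_m6_up  = c(0.2, 0.2, 0.35, 1, 0.3, 0.95, 0.35, 0.2, 0.2, 0.2),
    mono_up   = seq(0.1, 1, length.out = 10),
    mono_down = seq(1, 0.1, length.out = 10),
    late_burst = c(rep(0.05, 8), 0.6, 1)
  )
  mapply(archetype_spec, names(shapes), shapes,
         MoreArgs = list(n_genes = n_genes_each,
                         base_mean_range = base_mean_range),
         SIMPLIFY = FALSE)
}

#' Simulation specification
#'
#' Full description of a synthetic count data set: archetypes, study layout
#' (stages x replicates), negative-binomial dispersion, the interval for
#' per-sample library size factors and the RNG seed. The defaults emulate
#' the study design the package targets: ten developmental stages sampled in
#' two biological replicates.
#'
#' @param archetypes list of [archetype_spec()] objects.
#' @param n_stages number of developmental stages (default 10).
#' @param n_replicates biological replicates per stage (default 2).
#' @param dispersion NB dispersion `alpha >= 0` (variance `mu + alpha*mu^2`);
#'   0 degenerates to Poisson.
#' @param size_factor_range interval from which per-sample library size
#'   factors are drawn log-uniformly.
#' @param seed integer RNG seed.
#' @return a `simulation_spec` object.
#' @export
simulation_spec <- function(archetypes = default_archetypes(),
                            n_stages = 10, n_replicates = 2,
                            dispersion = 0.05,
                            size_factor_range = c(0.5, 2),
                            seed = 1) {
  if (!length(archetypes)) stop("at least one archetype is required")
  archetypes <- lapply(archetypes, function(a) {
    if (!inherits(a, "archetype_spec")) stop("archetypes must be archetype_spec objects")
    if (length(a$shape) != n_stages)
      stop("archetype '", a$name, "' has shape length ", length(a$shape),
           " but n_stages = ", n_stages)
    a
  })
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(size_factor_range) != 2L || any(size_factor_range <= 0) ||
      size_factor_range[2] < size_factor_range[1])
    stop("size_factor_range must be a positive increasing interval")
  structure(list(archetypes = archetypes, n_stages = as.integer(n_stages),
                 n_replicates = as.integer(n_replicates),
                 dispersion = as.numeric(dispersion),
                 size_factor_range = as.numeric(size_factor_range),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Draw one NB count vector with mean mu and dispersion alpha.
rnb <- function(mu, alpha) {
  n <- length(mu)
  if (alpha == 0) return(stats::rpois(n, mu))
  out <- integer(n)
  pos <- mu > 0
  out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / alpha)
  out
}

# Per-gene base means and archetype labels, deterministic given spec$seed.
.gene_truth <- function(spec) {
  labels <- unlist(lapply(spec$archetypes,
                          function(a) rep(a$name, a$n_genes)))
  gene_id <- sprintf("GENE%05d", seq_along(labels))
  base <- with_stream(spec$seed, "base", {
    unlist(lapply(spec$archetypes, function(a) {
      r <- log(a$base_mean_range)
      exp(stats::runif(a$n_genes, r[1], r[2]))
    }))
  })
  data.frame(gene_id = gene_id, archetype = labels, base_mean = base,
             stringsAsFactors = FALSE)
}

.shape_matrix <- function(spec) {
  shapes <- do.call(rbind, lapply(spec$archetypes, function(a) a$shape))
  rownames(shapes) <- vapply(spec$archetypes, function(a) a$name, "")
  shapes
}

# One simulated sample column: size factor and counts for (stage, rep),
# drawn from sub-streams keyed only by (stage, replicate) so that any stage
# subset reproduces the identical columns.
.simulate_column <- function(spec, truth, shapes, stage, rep) {
  sf <- with_stream(spec$seed, sprintf("sf/%d/%d", stage, rep), {
    r <- log(spec$size_factor_range)
    exp(stats::runif(1, r[1], r[2]))
  })
  mu <- sf * truth$base_mean * shapes[truth$archetype, stage]
  counts <- with_stream(spec$seed, sprintf("counts/%d/%d", stage, rep),
                        rnb(mu, spec$dispersion))
  list(sf = sf, counts = counts)
}

#' Simulate a count matrix with planted structure
#'
#' Draws NB counts `counts[g, (stage j, rep r)] ~ NB(mean = s_jr * base_g *
#' shape_g[j], dispersion alpha)`, independently across genes and samples,
#' with per-sample size factors drawn log-uniformly. Deterministic given
#' `spec$seed`: each sample column has its own derived RNG sub-stream, so a
#' later replication run over a stage subset reproduces columns exactly.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `counts` (a [meristem_counts()]) and `truth`
#'   (data frame gene_id/archetype/base_mean with the per-sample true size
#'   factors as attribute `size_factors`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  truth <- .gene_truth(spec)
  shapes <- .shape_matrix(spec)
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      stage = seq_len(spec$n_stages))[, c("stage", "replicate")]
  grid <- grid[order(grid$stage, grid$replicate), ]
  cols <- lapply(seq_len(nrow(grid)), function(i)
    .simulate_column(spec, truth, shapes, grid$stage[i], grid$replicate[i]))
  m <- vapply(cols, function(cl) as.numeric(cl$counts), numeric(nrow(truth)))
  rownames(m) <- truth$gene_id
  samples <- data.frame(stage = grid$stage, replicate = grid$replicate,
                        experiment = 1L)
  colnames(m) <- sample_ids(samples)
  sf <- vapply(cols, function(cl) cl$sf, 1.0)
  names(sf) <- colnames(m)
  attr(truth, "size_factors") <- sf
  list(counts = meristem_counts(m, samples), truth = truth)
}

#' Simulate an independent replication experiment
#'
#' Generates fresh counts for the same genes (same archetype means, from the
#' ground truth of a previous [simulate_counts()] run) over a subset of
#' stages, with fresh NB noise and fresh size factors. Deterministic given
#' `seed2`; with `seed2` equal to the original seed and all stages, the
#' output reproduces the original columns exactly.
#'
#' @param spec the original [simulation_spec()].
#' @param truth ground-truth data frame from [simulate_counts()].
#' @param stages integer subset of stages to re-profile.
#' @param seed2 seed for the replication experiment.
#' @param experiment experiment index recorded in the metadata (default 2).
#' @return list with `counts` and `truth` as for [simulate_counts()].
#' @export
simulate_replication <- function(spec, truth, stages, seed2,
                                 experiment = 2L) {
  stopifnot(inherits(spec, "simulation_spec"))
  stages <- as.integer(stages)
  if (!length(stages) || any(stages < 1L | stages > spec$n_stages))
    stop("stages must be a non-empty subset of 1..", spec$n_stages)
  need <- c("gene_id", "archetype", "base_mean")
  if (!all(need %in% names(truth)))
    stop("truth must carry gene_id, archetype and base_mean")
  known <- vapply(spec$archetypes, function(a) a$name, "")
  if (!all(truth$archetype %in% known))
    stop("truth contains genes with unknown archetypes")
  spec2 <- spec
  spec2$seed <- as.integer(seed2)
  shapes <- .shape_matrix(spec2)
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      stage = sort(stages))[, c("stage", "replicate")]
  grid <- grid[order(grid$stage, grid$replicate), ]
  cols <- lapply(seq_len(nrow(grid)), function(i)
    .simulate_column(spec2, truth, shapes, grid$stage[i], grid$replicate[i]))
  m <- vapply(cols, function(cl) as.numeric(cl$counts), numeric(nrow(truth)))
  rownames(m) <- truth$gene_id
  samples <- data.frame(stage = grid$stage, replicate = grid$replicate,
                        experiment = as.integer(experiment))
  colnames(m) <- sample_ids(samples)
  sf <- vapply(cols, function(cl) cl$sf, 1.0)
  names(sf) <- colnames(m)
  truth2 <- truth[, need]
  attr(truth2, "size_factors") <- sf
  list(counts = meristem_counts(m, samples), truth = truth2)
}

#' Write ground truth to TSV
#'
#' @param truth ground-truth data frame from [simulate_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation specification from YAML
#'
#' The YAML layout mirrors [simulation_spec()]: top-level keys `n_stages`,
#' `n_replicates`, `dispersion`, `size_factor_range`, `seed` and a list
#' `archetypes` of maps with `name`, `shape`, `n_genes` and optionally
#' `base_mean_range`.
#'
#' @param path YAML file path.
#' @return a [simulation_spec()].
#' @export
read_simulation_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$archetypes))
    stop("simulation spec YAML must define 'archetypes'")
  arch <- lapply(y$archetypes, function(a) {
    for (key in c("name", "shape", "n_genes"))
      if (is.null(a[[key]]))
        stop("archetype entry missing key '", key, "'")
    archetype_spec(a$name, unlist(a$shape), a$n_genes,
                   if (!is.null(a$base_mean_range)) unlist(a$base_mean_range)
                   else c(200, 1000))
  })
  args <- list(archetypes = arch)
  for (key in c("n_stages", "n_replicates", "dispersion",
                "size_factor_range", "seed"))
    if (!is.null(y[[key]])) args[[key]] <- unlist(y[[key]])
  do.call(simulation_spec, args)
}
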