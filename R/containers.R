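#' Count matrix with sample metadata
#'
#' Container for a gene x sample matrix of total gene read (TGR) counts
#' together with per-sample metadata (developmental stage, biological
#' replicate, experiment). Modelled on the list-based containers of the
#' limma/edgeR family: a plain list with a `counts` matrix and a `samples`
#' data frame, validated on construction.
#'
#' @param counts integer-valued matrix, genes in rows (rownames = gene IDs),
#'   samples in columns. All values must be non-negative and integral.
#' @param samples data frame with one row per column of `counts` and columns
#'   `stage` (integer stage index, 1-based), `replicate` (integer) and
#'   optionally `experiment` (integer, default 1). Row order must match the
#'   column order of `counts`.
#' @return An object of class `meristem_counts`.
#' @export
meristem_counts <- function(counts, samples) {
  x <- .validate_set(counts, samples, integral = TRUE)
  class(x) <- c("meristem_counts", "meristem_set")
  x
}

#' Normalized expression matrix
#'
#' Same layout as [meristem_counts()] but holding size-factor-scaled
#' (real-valued) normalized TGR counts.
#'
#' @param values numeric matrix of non-negative normalized counts.
#' @param samples sample metadata, as for [meristem_counts()].
#' @return An object of class `meristem_norm`.
#' @export
meristem_norm <- function(values, samples) {
  x <- .validate_set(values, samples, integral = FALSE)
  names(x)[names(x) == "counts"] <- "values"
  class(x) <- c("meristem_norm", "meristem_set")
  x
}

.validate_set <- function(counts, samples, integral = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)))
    stop("`counts` must have gene IDs as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs in count matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (integral && any(counts != round(counts)))
    stop("counts must be integral")
  if (!is.data.frame(samples))
    stop("`samples` must be a data frame")
  if (nrow(samples) != ncol(counts))
    stop("`samples` must have one row per sample column")
  for (col in c("stage", "replicate"))
    if (is.null(samples[[col]]))
      stop("sample metadata lacks required column '", col, "'")
  if (is.null(samples$experiment)) samples$experiment <- 1L
  samples$stage <- as.integer(samples$stage)
  samples$replicate <- as.integer(samples$replicate)
  samples$experiment <- as.integer(samples$experiment)
  if (any(samples$stage < 1L))
    stop("stage indices must be >= 1")
  if (is.null(colnames(counts)))
    colnames(counts) <- sample_ids(samples)
  rownames(samples) <- colnames(counts)
  list(counts = counts, samples = samples)
}

#' @export
print.meristem_set <- function(x, ...) {
  m <- if (!is.null(x$counts)) x$counts else x$values
  kind <- if (inherits(x, "meristem_counts")) "counts" else "normalized values"
  cat(sprintf("%s: %d genes x %d samples (%s)\n",
              class(x)[1], nrow(m), ncol(m), kind))
  cat(sprintf("stages: %s; replicates per stage: %s; experiments: %s\n",
              paste(sort(unique(x$samples$stage)), collapse = ","),
              paste(range(table(x$samples$stage)), collapse = "-"),
              paste(sort(unique(x$samples$experiment)), collapse = ",")))
  invisible(x)
}

#' @export
dim.meristem_set <- function(x) {
  dim(if (!is.null(x$counts)) x$counts else x$values)
}

#' Sample identifiers from metadata
#'
#' Builds canonical sample IDs of the form `M<stage>_R<replicate>` with an
#' `_E<experiment>` suffix for experiments other than the first.
#'
#' @param samples sample metadata data frame.
#' @return character vector of sample IDs.
#' @export
sample_ids <- function(samples) {
  ids <- sprintf("M%d_R%d", samples$stage, samples$replicate)
  extra <- !is.null(samples$experiment) & samples$experiment != 1L
  if (any(extra))
    ids[extra] <- sprintf("%s_E%d", ids[extra], samples$experiment[extra])
  ids
}

#' Parse sample metadata from sample IDs
#'
#' Inverse of [sample_ids()]: parses `M<stage>_R<rep>[_E<exp>]` labels.
#'
#' @param ids character vector of sample IDs.
#' @return data frame with columns `stage`, `replicate`, `experiment`.
#' @export
parse_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^M([0-9]+)_R([0-9]+)(?:_E([0-9]+))?$", ids))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("malformed sample IDs: ", paste(ids[bad], collapse = ", "))
  data.frame(
    stage = vapply(m, function(g) as.integer(g[2]), 1L),
    replicate = vapply(m, function(g) as.integer(g[3]), 1L),
    experiment = vapply(m, function(g) {
      if (g[4] == "") 1L else as.integer(g[4])
    }, 1L)
  )
}

#' Write a count matrix to TSV
#'
#' First column `gene_id`, remaining columns one per sample with canonical
#' sample IDs as headers.
#'
#' @param x a `meristem_counts` or `meristem_norm` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  m <- if (!is.null(x$counts)) x$counts else x$values
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' Expects the layout written by [write_counts_tsv()]; sample metadata is
#' recovered from the column headers. Malformed values (non-integer counts,
#' duplicate gene IDs) raise an error naming the offending row.
#'
#' @param path input file path.
#' @param integral require integral values (`TRUE` for raw counts).
#' @return a `meristem_counts` (or `meristem_norm` when `integral = FALSE`).
#' @export
read_counts_tsv <- function(path, integral = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "gene_id")
    stop("expected a 'gene_id' first column in ", path)
  dup <- which(duplicated(df$gene_id))
  if (length(dup))
    stop("duplicate gene ID at row ", dup[1], ": ", df$gene_id[dup[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 1,
                        function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric count at row ", if (length(bad)) bad[1] else "?")
  }
  if (integral && any(m != round(m))) {
    bad <- which(apply(m, 1, function(r) any(r != round(r))))
    stop("non-integer count at row ", bad[1])
  }
  rownames(m) <- df$gene_id
  samples <- parse_sample_ids(colnames(m))
  if (integral) meristem_counts(m, samples) else meristem_norm(m, samples)
}

#' Relative expression profiles
#'
#' Per-gene per-stage relative expression values on the \[0, 1\] scale
#' (replicate-averaged, max-normalized), plus the scaling record: which max
#' was used for each gene and over which stage set it was taken.
#'
#' @param values numeric gene x stage matrix with values in \[0, 1\]
#'   (values may exceed 1 only under joint cross-experiment scaling).
#' @param stages integer stage indices labelling the columns.
#' @param max_used per-gene maximum used as the divisor.
#' @param scaling_stages the stage set over which the maximum was taken.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, stages, max_used, scaling_stages) {
  stopifnot(is.matrix(values), length(stages) == ncol(values),
            length(max_used) == nrow(values))
  colnames(values) <- paste0("M", stages)
  structure(list(values = values, stages = as.integer(stages),
                 max_used = max_used,
                 all_zero = max_used == 0,
                 scaling_stages = as.integer(scaling_stages)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d genes x %d stages (%d all-zero)\n",
              nrow(x$values), ncol(x$values), sum(x$all_zero)))
  invisible(x)
}

# Extract the numeric matrix from a profile_matrix or pass a matrix through.
profile_values <- function(x) {
  if (inherits(x, "profile_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a profile_matrix or a numeric matrix")
}
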