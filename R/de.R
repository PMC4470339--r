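#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values at the module surface used by all DE code.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene NB dispersion by method of moments
#'
#' Estimates the negative-binomial dispersion for each gene from the pooled
#' within-condition variance of normalized counts:
#' `alpha_g = max(0, (v_g - mu_g) / mu_g^2)`, where `v_g` is the pooled
#' within-condition sample variance and `mu_g` the overall mean. A
#' mean-dispersion trend `a0 + a1/mu` is fitted robustly across genes and,
#' with `share = "maximum"`, each gene uses the larger of its own estimate
#' and the trend value — guarding against the strong downward noise of
#' per-gene variance estimates at two replicates.
#'
#' @param x numeric matrix of normalized counts (genes x samples), restricted
#'   to the two conditions of interest.
#' @param condition factor/vector of length `ncol(x)` giving the condition of
#'   each sample; every condition must have at least one replicate and at
#'   least one condition must have two or more.
#' @param share `"maximum"` (default) or `"gene"` (raw per-gene estimates).
#' @return data frame with `base_mean`, `dispersion_gene`,
#'   `dispersion_trend`, `dispersion` (one row per gene).
#' @export
estimate_dispersion <- function(x, condition, share = c("maximum", "gene")) {
  share <- match.arg(share)
  stopifnot(is.matrix(x), ncol(x) == length(condition))
  condition <- as.factor(condition)
  n_per <- table(condition)
  if (any(n_per == 0L)) stop("every condition needs at least one replicate")
  if (!any(n_per >= 2L)) stop("dispersion needs a condition with >= 2 replicates")
  mu <- rowMeans(x)
  ss <- 0
  df <- 0
  for (lev in levels(condition)) {
    cols <- condition == lev
    if (sum(cols) < 2L) next
    sub <- x[, cols, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + sum(cols) - 1L
  }
  v <- ss / df
  alpha_gene <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), NA_real_)
  alpha_trend <- .dispersion_trend(mu, alpha_gene)
  alpha <- if (share == "maximum") pmax(alpha_gene, alpha_trend) else alpha_gene
  data.frame(base_mean = mu, dispersion_gene = alpha_gene,
             dispersion_trend = alpha_trend, dispersion = alpha,
             row.names = rownames(x))
}

# Robust fit of alpha ~ a0 + a1/mu over genes with defined estimates;
# falls back to the median dispersion for tiny gene sets.
.dispersion_trend <- function(mu, alpha_gene) {
  ok <- is.finite(alpha_gene) & mu > 0
  fallback <- function() {
    med <- stats::median(alpha_gene[ok])
    rep(if (is.finite(med)) med else 0, length(mu))
  }
  if (sum(ok) < 10L) return(fallback())
  fit <- tryCatch(
    MASS::rlm(alpha_gene[ok] ~ I(1 / mu[ok]), maxit = 50),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(fallback())
  co <- pmax(stats::coef(fit), 0)
  tr <- co[1] + co[2] / pmax(mu, .Machine$double.eps)
  tr[mu <= 0] <- co[1]
  tr
}

#' NB Wald test between two stages
#'
#' Per-gene test of mean equality between two developmental stages on
#' normalized counts, with a Wald statistic on log means using the
#' method-of-moments dispersion (trend-shared by default) and BH control at
#' the configured FDR. The statistic is referred to a t distribution
#' rather than a normal, with degrees of freedom equal to the residual df
#' plus a moderation credit of two for the information the fitted
#' mean-dispersion trend contributes (in the spirit of quasi-likelihood df
#' moderation): at two replicates per condition this gives df = 4, a
#' small-sample guard that keeps the extreme tail calibrated where log
#' mean counts are visibly non-normal. Genes with all-zero counts in both conditions are
#' excluded from testing and from the BH denominator (their p and q are NA).
#' If exactly one condition mean is zero, the fold change is reported as a
#' signed infinity and the Wald statistic is formed on the mean scale, which
#' keeps the p-value finite.
#'
#' @param norm a [meristem_norm()] object.
#' @param stage_a,stage_b the two (distinct) stage indices; the fold change
#'   is B over A.
#' @param fdr FDR threshold for `is_de` (default 0.05).
#' @param share dispersion sharing mode, see [estimate_dispersion()].
#' @return data frame with one row per gene: `gene`, `base_mean_a`,
#'   `base_mean_b`, `log2_fold_change`, `p_value`, `q_value`, `is_de`.
#' @export
test_stage_pair <- function(norm, stage_a, stage_b, fdr = 0.05,
                            share = "maximum") {
  stopifnot(inherits(norm, "meristem_norm"))
  if (stage_a == stage_b) stop("stage_a and stage_b must differ")
  ca <- norm$samples$stage == stage_a
  cb <- norm$samples$stage == stage_b
  if (sum(ca) < 2L || sum(cb) < 2L)
    stop("both stages need >= 2 replicates")
  xa <- norm$values[, ca, drop = FALSE]
  xb <- norm$values[, cb, drop = FALSE]
  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  tested <- mean_a > 0 | mean_b > 0
  na <- sum(ca)
  nb <- sum(cb)

  x <- cbind(xa, xb)[tested, , drop = FALSE]
  cond <- rep(c("A", "B"), c(na, nb))
  disp <- estimate_dispersion(x, cond, share = share)$dispersion

  ma <- mean_a[tested]
  mb <- mean_b[tested]
  z <- numeric(sum(tested))
  both <- ma > 0 & mb > 0
  se2 <- (1 / ma[both] + disp[both]) / na + (1 / mb[both] + disp[both]) / nb
  z[both] <- (log(mb[both]) - log(ma[both])) / sqrt(se2)
  one <- !both
  if (any(one)) {
    mpos <- pmax(ma[one], mb[one])
    npos <- ifelse(ma[one] > 0, na, nb)
    se2o <- (mpos + disp[one] * mpos^2) / npos
    z[one] <- (mb[one] - ma[one]) / sqrt(se2o)
  }
  p <- 2 * stats::pt(-abs(z), df = na + nb)
  q <- bh_adjust(p)

  l2fc <- rep(NA_real_, length(mean_a))
  l2fc[tested][both] <- log2(mb[both] / ma[both])
  l2fc[tested][one] <- ifelse(mb[one] > ma[one], Inf, -Inf)
  out <- data.frame(gene = rownames(norm$values),
                    base_mean_a = mean_a, base_mean_b = mean_b,
                    log2_fold_change = l2fc,
                    p_value = NA_real_, q_value = NA_real_,
                    is_de = NA, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$p_value[tested] <- p
  out$q_value[tested] <- q
  out$is_de[tested] <- q <= fdr
  out
}

#' Differential expression over consecutive stage pairs
#'
#' Applies [test_stage_pair()] to every pair of consecutive stages of the
#' time course and tallies the genes declared differentially expressed.
#'
#' @param norm a [meristem_norm()] object.
#' @param stages stage order; defaults to the sorted unique stages present.
#' @param fdr FDR threshold.
#' @param share dispersion sharing mode.
#' @return list with `n_de` (named integer vector, one entry per consecutive
#'   pair, names like `"M4_vs_M5"`) and `tables` (the full per-pair DE
#'   tables).
#' @export
de_series <- function(norm, stages = NULL, fdr = 0.05, share = "maximum") {
  stopifnot(inherits(norm, "meristem_norm"))
  if (is.null(stages)) stages <- sort(unique(norm$samples$stage))
  if (length(stages) < 2L) stop("need at least two stages")
  tables <- list()
  n_de <- integer(length(stages) - 1L)
  names(n_de) <- sprintf("M%d_vs_M%d", stages[-length(stages)], stages[-1])
  for (i in seq_len(length(stages) - 1L)) {
    tab <- test_stage_pair(norm, stages[i], stages[i + 1L], fdr = fdr,
                           share = share)
    tables[[names(n_de)[i]]] <- tab
    n_de[i] <- sum(tab$is_de, na.rm = TRUE)
  }
  list(n_de = n_de, tables = tables)
}

#' Write a DE table to TSV
#'
#' @param tab DE table from [test_stage_pair()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
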