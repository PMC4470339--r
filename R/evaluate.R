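#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement used to score planted-structure recovery.
#' Unassigned items (NA) are treated as one extra category of their own, so
#' leaving structure unclustered is penalized rather than ignored.
#'
#' @param a,b two label vectors of equal length (NA allowed).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  a <- as.character(a); a[is.na(a)] <- ".unassigned"
  b <- as.character(b); b[is.na(b)] <- ".unassigned"
  mclust::adjustedRandIndex(a, b)
}
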