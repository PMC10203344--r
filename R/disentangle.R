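#' Eigendecomposition of the SR matrix into principal components
#'
#' The SR matrix is decomposed, without centering or rescaling, into
#' orthonormal principal components: its rows are already standardized
#' association vectors, and centering would destroy their interpretation.
#' Components are ranked by descending eigenvalue. Each AV's score on a
#' component is the projection of its AV-vector on the loading, which for a
#' symmetric matrix equals eigenvalue times loading coordinate. The sign of
#' each loading is fixed by making its largest-magnitude coordinate positive,
#' so component numbering and all downstream codes are reproducible.
#'
#' @param sr a \code{pdd_sr} object (symmetric, finite).
#' @return list of class \code{pdd_pca}: \code{values} (eigenvalues,
#'   descending), \code{loadings} (K x K, columns orthonormal), \code{scores}
#'   (K x K projections), \code{av} metadata.
#' @export
decompose_sr <- function(sr) {
  stopifnot(inherits(sr, "pdd_sr"))
  m <- sr$sr
  if (!all(is.finite(m))) stop("SR matrix contains non-finite entries")
  if (nrow(m) < 2) stop("need at least two AVs")
  e <- eigen(m, symmetric = TRUE)
  for (k in seq_len(ncol(e$vectors))) {
    v <- e$vectors[, k]
    if (v[which.max(abs(v))] < 0) e$vectors[, k] <- -v
  }
  scores <- sweep(e$vectors, 2, e$values, `*`)   # m %*% v = lambda v
  dimnames(e$vectors) <- list(rownames(m), paste0("PC", seq_len(ncol(m))))
  dimnames(scores) <- dimnames(e$vectors)
  structure(list(values = e$values, loadings = e$vectors,
                 scores = scores, av = sr$av),
            class = "pdd_pca")
}

#' Rank-1 reconstructed SR matrix for one principal component
#'
#' Re-expresses the projection of every AV-vector on component \code{k} in
#' the original AV coordinates: the outer product of the score vector with
#' the loading, i.e. \eqn{\lambda_k v_k v_k^T}. Summing the reconstructions
#' over all components recovers the SR matrix exactly.
#'
#' @param pca a \code{pdd_pca} object.
#' @param k component index (1-based, eigenvalue order).
#' @return K x K numeric matrix with AV dimnames.
#' @export
reconstruct_rsr <- function(pca, k) {
  stopifnot(inherits(pca, "pdd_pca"), k >= 1, k <= length(pca$values))
  v <- pca$loadings[, k]
  m <- pca$values[k] * tcrossprod(v)
  dimnames(m) <- list(rownames(pca$loadings), rownames(pca$loadings))
  m
}

# maximum potentially-significant entry of an RSR matrix: off-diagonal and
# cross-attribute only, since same-attribute values never co-occur
rsr_signal_max <- function(rsr, av) {
  mask <- outer(av$attribute, av$attribute, `!=`)
  if (!any(mask)) return(-Inf)
  max(rsr[mask])
}

#' Select statistically significant disentangled spaces
#'
#' A component's reconstructed SR matrix is a disentangled association space
#' (DS) when it contains at least one significant positive association:
#' its maximum off-diagonal, cross-attribute entry exceeds the threshold
#' (1.96 for the 95% level by default). Significant spaces are re-indexed
#' 1..D in eigenvalue order; that index is the #DS field of DSU codes.
#'
#' @param pca a \code{pdd_pca} object.
#' @param threshold positive significance threshold on the reconstructed SR.
#' @return list of disentangled spaces, each a list with \code{ds_index},
#'   \code{pc} (component rank), \code{eigenvalue}, \code{rsr},
#'   \code{scores} (named numeric), \code{max_rsr}.
#' @export
select_significant_ds <- function(pca, threshold = 1.96) {
  stopifnot(inherits(pca, "pdd_pca"), threshold > 0)
  out <- list()
  for (k in seq_along(pca$values)) {
    rsr <- reconstruct_rsr(pca, k)
    mx <- rsr_signal_max(rsr, pca$av)
    if (is.finite(mx) && mx > threshold) {
      out[[length(out) + 1L]] <- list(
        ds_index = length(out) + 1L,
        pc = k,
        eigenvalue = pca$values[k],
        rsr = rsr,
        scores = stats::setNames(pca$scores[, k], rownames(pca$loadings)),
        max_rsr = mx)
    }
  }
  out
}
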