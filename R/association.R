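#' Adjusted standardized residual for one AV pair
#'
#' Measures the deviation of the observed co-occurrence count of two
#' attribute values from its expectation under independence,
#' \eqn{Exp = Occ_a \cdot Occ_b / T}:
#' \deqn{SR = \frac{Occ_{ab} - Exp}{\sqrt{Exp}}\left(1 - \frac{Occ_a Occ_b}{T^2}\right)}
#' The default multiplies the raw residual by the printed adjustment factor;
#' \code{variant = "haberman"} instead divides by
#' \eqn{\sqrt{(1 - Occ_a/T)(1 - Occ_b/T)}}, the classical adjusted residual
#' for a two-way table, for sensitivity analysis.
#'
#' @param occ_a,occ_b marginal occurrence counts of the two AVs.
#' @param occ_ab their co-occurrence count.
#' @param total total number of records T.
#' @param variant \code{"printed"} (default) or \code{"haberman"}.
#' @return the SR value; 0 (with a warning) when the expectation is 0.
#' @examples
#' sr_pair(50, 50, 50, 100)  # 3.75
#' sr_pair(50, 50, 25, 100)  # 0: observed equals expected
#' @export
sr_pair <- function(occ_a, occ_b, occ_ab, total,
                    variant = c("printed", "haberman")) {
  variant <- match.arg(variant)
  stopifnot(total > 0, occ_ab >= 0, occ_ab <= min(occ_a, occ_b))
  expv <- occ_a * occ_b / total
  if (expv <= 0) {
    warning("zero expectation (an AV never occurs); SR defined as 0")
    return(0)
  }
  raw <- (occ_ab - expv) / sqrt(expv)
  if (variant == "printed") {
    raw * (1 - occ_a * occ_b / total^2)
  } else {
    raw / sqrt((1 - occ_a / total) * (1 - occ_b / total))
  }
}

#' Pairwise frequency and SR matrices over all distinct AVs
#'
#' Builds the K x K co-occurrence count matrix and the corresponding matrix of
#' adjusted standardized residuals over all distinct attribute values. Counts
#' come from address-table intersections, never from rescanning rows. Pairs of
#' values of the same attribute are structurally exclusive; their entries (and
#' the diagonal) are forced to 0 in the SR matrix so within-attribute
#' exclusivity never masquerades as association signal.
#'
#' @param dataset a \code{pdd_data} object.
#' @param table its \code{pdd_address_table}.
#' @param variant residual variant passed to \code{\link{sr_pair}}.
#' @return object of class \code{pdd_sr}: list with \code{freq} (K x K integer
#'   matrix), \code{sr} (K x K numeric), and \code{av} (data frame of AV
#'   metadata in matrix order). Row i of \code{sr} is the AV-vector of AV i.
#' @export
build_sr_matrix <- function(dataset, table, variant = c("printed", "haberman")) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "pdd_data"), inherits(table, "pdd_address_table"))
  av <- attr(table, "av")
  k <- nrow(av)
  if (k < 2) stop("need at least two distinct AVs to form pairs")
  total <- dataset$n_entities

  freq <- matrix(0L, k, k, dimnames = list(av$key, av$key))
  sr <- matrix(0, k, k, dimnames = list(av$key, av$key))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (av$attribute[i] == av$attribute[j]) next
      n_ab <- length(eid_intersection(table, c(av$key[i], av$key[j])))
      freq[i, j] <- freq[j, i] <- n_ab
      s <- sr_pair(av$occ[i], av$occ[j], n_ab, total, variant = variant)
      sr[i, j] <- sr[j, i] <- s
    }
  }
  structure(list(freq = freq, sr = sr, av = av, n_entities = total),
            class = "pdd_sr")
}

#' @export
print.pdd_sr <- function(x, ...) {
  k <- nrow(x$sr)
  cat("SR matrix over", k, "AVs;",
      sum(x$sr[upper.tri(x$sr)] > 1.96), "pairs with SR > 1.96\n")
  invisible(x)
}

#' Write frequency and SR matrices as TSV
#'
#' @param sr a \code{pdd_sr} object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_sr_matrix <- function(sr, dir) {
  stopifnot(inherits(sr, "pdd_sr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- file.path(dir, "frequency_matrix.tsv")
  ps <- file.path(dir, "sr_matrix.tsv")
  utils::write.table(sr$freq, pf, sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(sr$sr, ps, sep = "\t", quote = FALSE, col.names = NA)
  invisible(c(pf, ps))
}
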