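# minimal union-find for AV clustering
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[max(ri, rj)] <- min(ri, rj)
  p
}

#' Cluster attribute values into statistically connected AV-groups
#'
#' Within one disentangled space, AVs are grouped so that every member has at
#' least one other member it is significantly associated with. This is
#' exactly the set of connected components, of size at least two, of the
#' graph whose edges are cross-attribute AV pairs with reconstructed SR above
#' the threshold; merging is done with union-find, so the result does not
#' depend on edge order. Groups are ordered by descending maximum absolute
#' component score of their members; isolated AVs are dropped.
#'
#' @param ds one disentangled space from \code{\link{select_significant_ds}}.
#' @param av AV metadata data frame (attribute, value, key).
#' @param threshold significance threshold on reconstructed SR entries.
#' @return list of AV-groups: each a list with \code{avg_index} and
#'   \code{members} (character vector of AV keys).
#' @export
av_clustering <- function(ds, av, threshold = 1.96) {
  rsr <- ds$rsr
  k <- nrow(rsr)
  parent <- uf_new(k)
  mask <- outer(av$attribute, av$attribute, `!=`) & upper.tri(rsr)
  idx <- which(rsr > threshold & mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  for (r in seq_len(nrow(idx))) parent <- uf_union(parent, idx[r, 1], idx[r, 2])
  roots <- vapply(seq_len(k), function(i) uf_find(parent, i), integer(1))
  comp <- split(seq_len(k), roots)
  comp <- comp[vapply(comp, length, integer(1)) >= 2]
  # only components actually touched by an edge qualify (size >= 2 ensures it)
  strength <- vapply(comp, function(m) max(abs(ds$scores[m])), numeric(1))
  comp <- comp[order(-strength)]
  lapply(seq_along(comp), function(g)
    list(avg_index = g, members = av$key[comp[[g]]]))
}

#' Cover-overlap similarity between two attribute values
#'
#' Dice coefficient of the two AV covers: twice the cardinality of their
#' entity-ID intersection over the sum of their cover sizes. 1 for identical
#' covers, 0 for disjoint ones.
#'
#' @param table a \code{pdd_address_table}.
#' @param av_i,av_j AV keys (\code{"Attr=Value"}).
#' @return similarity in [0, 1].
#' @export
av_similarity <- function(table, av_i, av_j) {
  ci <- table[[av_i]]; cj <- table[[av_j]]
  if (length(ci) + length(cj) == 0) stop("both covers empty")
  2 * length(intersect(ci, cj)) / (length(ci) + length(cj))
}

#' Refine an AV-group into AV-subgroups by entity-cover similarity
#'
#' Agglomerative clustering (average linkage by default) on pairwise
#' \code{\link{av_similarity}}; merging stops when no inter-cluster
#' similarity reaches \code{cutoff} (50% by default). Each resulting cluster
#' is one AV-subgroup; subgroup ordinals are assigned by descending member
#' count, ties broken by lexical order of the sorted member keys, so the
#' triple codes are reproducible.
#'
#' @param members character vector of AV keys forming one AV-group.
#' @param table a \code{pdd_address_table}.
#' @param cutoff similarity lower bound in (0, 1].
#' @param linkage \code{"average"} (default), \code{"single"} or
#'   \code{"complete"}.
#' @return list of character vectors (subgroup members), in ordinal order.
#' @export
subgroup_clustering <- function(members, table, cutoff = 0.5,
                                linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(cutoff > 0, cutoff <= 1)
  n <- length(members)
  if (n == 1) return(list(members))
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sim[i, j] <- sim[j, i] <- av_similarity(table, members[i], members[j])
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = linkage)
  # clusters joined at distance <= 1 - cutoff, i.e. similarity >= cutoff
  grp <- stats::cutree(hc, h = 1 - cutoff)
  subs <- split(members, grp)
  ord <- order(-vapply(subs, length, integer(1)),
               vapply(subs, function(s) paste(sort(s), collapse = "|"),
                      character(1)))
  unname(subs[ord])
}

#' Derive all disentangled-space units (DSUs) for a set of spaces
#'
#' Runs AV clustering and subgroup refinement over every significant
#' disentangled space and assigns each subgroup its triple code
#' [#DS #AVG #AVSG].
#'
#' @param spaces output of \code{\link{select_significant_ds}}.
#' @param av AV metadata data frame.
#' @param table a \code{pdd_address_table}.
#' @param threshold SR significance threshold.
#' @param cutoff subgroup similarity cutoff.
#' @param linkage linkage for \code{\link{subgroup_clustering}}.
#' @return list of DSUs: each a list with \code{code} (integer triple),
#'   \code{label} (e.g. \code{"DSU[1 2 1]"}), \code{members}, \code{cover}
#'   (entity IDs covered by the whole subgroup, possibly empty).
#' @export
derive_dsus <- function(spaces, av, table, threshold = 1.96, cutoff = 0.5,
                        linkage = "average") {
  dsus <- list()
  for (ds in spaces) {
    groups <- av_clustering(ds, av, threshold)
    for (g in groups) {
      subs <- subgroup_clustering(g$members, table, cutoff, linkage)
      for (s in seq_along(subs)) {
        code <- c(ds$ds_index, g$avg_index, s)
        dsus[[length(dsus) + 1L]] <- list(
          code = code,
          label = sprintf("DSU[%d %d %d]", code[1], code[2], code[3]),
          members = subs[[s]],
          cover = eid_intersection(table, subs[[s]]))
      }
    }
  }
  dsus
}
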