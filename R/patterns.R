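#' Residual hypothesis test for a high-order AV set
#'
#' Generalizes the pairwise adjusted standardized residual to a candidate
#' pattern \eqn{P} of two or more attribute values. With \eqn{M} entities and
#' marginal counts \eqn{Occ(AV)}:
#' \deqn{Exp(P) = M \prod_{AV \in P} Occ(AV)/M, \quad
#'       R(P) = \frac{Occ(P) - Exp(P)}{\sqrt{Exp(P)}}, \quad
#'       V(P) = 1 - \prod_{AV \in P} Occ(AV)/M, \quad
#'       SR(P) = R(P)/\sqrt{V(P)}}
#' The expectation is the mutual-independence product model. When some AV
#' occurs in every entity the variance term vanishes; the SR then falls back
#' to the raw residual with a warning.
#'
#' @param avs character vector of at least two AV keys.
#' @param table a \code{pdd_address_table}.
#' @param n_entities total entity count M.
#' @return list with \code{occ}, \code{exp}, \code{residual},
#'   \code{variance}, \code{sr}, and \code{cover} (entity IDs).
#' @examples
#' # M = 100, three AVs of occurrence 50 co-occurring 40 times:
#' # exp = 12.5, residual ~ 7.778, variance = 0.875, sr ~ 8.315
#' @export
pattern_sr <- function(avs, table, n_entities) {
  stopifnot(length(avs) >= 2, n_entities > 0)
  occ_av <- vapply(avs, function(k) length(table[[k]]), integer(1))
  if (any(occ_av == 0)) stop("every member AV must have non-zero cover")
  cover <- eid_intersection(table, avs)
  occ <- length(cover)
  prod_frac <- prod(occ_av / n_entities)
  expv <- n_entities * prod_frac
  residual <- (occ - expv) / sqrt(expv)
  variance <- 1 - prod_frac
  if (variance <= 0) {
    warning("non-positive variance term (an AV occurs in every entity); ",
            "SR defined as the raw residual")
    sr <- residual
  } else {
    sr <- residual / sqrt(variance)
  }
  list(occ = occ, exp = expv, residual = residual, variance = variance,
       sr = sr, cover = cover)
}

#' Remove patterns that are not delta-closed
#'
#' A pattern is redundant when an accepted strict superset explains (almost)
#' the same entities: it is dropped if some accepted superset's support is at
#' least its own support minus \code{delta}. \code{delta = 0} keeps exactly
#' the classical closed patterns.
#'
#' @param patterns list of pattern records (fields \code{avs}, \code{occ}).
#' @param delta non-negative support slack.
#' @return the filtered list, original order preserved.
#' @export
delta_closed_filter <- function(patterns, delta = 0) {
  stopifnot(delta >= 0)
  if (length(patterns) <= 1) return(patterns)
  keep <- rep(TRUE, length(patterns))
  for (i in seq_along(patterns)) {
    pi <- patterns[[i]]
    for (j in seq_along(patterns)) {
      if (i == j) next
      pj <- patterns[[j]]
      if (length(pj$avs) > length(pi$avs) && all(pi$avs %in% pj$avs) &&
          pj$occ >= pi$occ - delta) {
        keep[i] <- FALSE
        break
      }
    }
  }
  patterns[keep]
}

#' Discover significant patterns within one DSU
#'
#' Breadth-first growth over subsets of the subgroup's AVs, starting at order
#' 2. A candidate is accepted when its \code{\link{pattern_sr}} exceeds the
#' threshold. Growth is pruned only below zero-support sets (support is
#' anti-monotone), so non-significant but occurring candidates still seed
#' larger ones. Accepted patterns pass through the delta-closed filter and
#' are returned sorted by descending order, then descending SR.
#'
#' @param dsu a DSU record (fields \code{code}, \code{label}, \code{members}).
#' @param table a \code{pdd_address_table}.
#' @param n_entities total entity count M.
#' @param threshold SR acceptance threshold.
#' @param delta slack for \code{\link{delta_closed_filter}}.
#' @return list of pattern records: \code{avs}, \code{order}, \code{occ},
#'   \code{exp}, \code{residual}, \code{variance}, \code{sr}, \code{cover},
#'   \code{dsu_code}, \code{dsu_label}.
#' @export
discover_patterns <- function(dsu, table, n_entities, threshold = 1.96,
                              delta = 0) {
  members <- sort(dsu$members)
  n <- length(members)
  if (n < 2) return(list())
  accepted <- list()
  # order-2 frontier
  frontier <- utils::combn(members, 2, simplify = FALSE)
  keep_stats <- function(avs) {
    st <- pattern_sr(avs, table, n_entities)
    st$avs <- avs
    st
  }
  stats_list <- lapply(frontier, keep_stats)
  repeat {
    supported <- stats_list[vapply(stats_list, function(s) s$occ > 0,
                                   logical(1))]
    for (s in supported) {
      if (s$sr > threshold) {
        s$order <- length(s$avs)
        s$dsu_code <- dsu$code
        s$dsu_label <- dsu$label
        accepted[[length(accepted) + 1L]] <- s
      }
    }
    if (length(supported) == 0) break
    order_now <- length(supported[[1]]$avs)
    if (order_now >= n) break
    # extend each supported set by every lexically larger member
    seen <- character(0)
    nxt <- list()
    for (s in supported) {
      last <- max(match(s$avs, members))
      if (last >= n) next
      for (j in (last + 1):n) {
        cand <- c(s$avs, members[j])
        key <- paste(cand, collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        nxt[[length(nxt) + 1L]] <- keep_stats(cand)
      }
    }
    if (length(nxt) == 0) break
    stats_list <- nxt
  }
  accepted <- delta_closed_filter(accepted, delta)
  if (length(accepted) > 1) {
    ord <- order(-vapply(accepted, `[[`, integer(1), "order"),
                 -vapply(accepted, `[[`, numeric(1), "sr"))
    accepted <- accepted[ord]
  }
  accepted
}

#' Class associated with a pattern
#'
#' The class holding the plurality of the entities the pattern covers;
#' \code{NA} on a tie (the pattern is then class-unassigned).
#'
#' @param pattern a pattern record with a non-empty \code{cover}.
#' @param labels named character vector, entity ID -> class.
#' @return class name or \code{NA_character_}.
#' @export
associate_pattern_class <- function(pattern, labels) {
  if (length(pattern$cover) == 0) stop("pattern with empty cover")
  cls <- labels[as.character(pattern$cover)]
  if (anyNA(cls)) stop("labels must cover the pattern's entities")
  tab <- sort(table(cls), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
  names(tab)[1]
}

#' Union pattern of a DSU
#'
#' @param patterns accepted patterns of one DSU.
#' @return list with \code{avs} (union of member AV sets) and
#'   \code{n_patterns}, or \code{NULL} when no pattern was accepted.
#' @export
union_pattern <- function(patterns) {
  if (length(patterns) == 0) return(NULL)
  list(avs = sort(unique(unlist(lapply(patterns, `[[`, "avs")))),
       n_patterns = length(patterns))
}
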