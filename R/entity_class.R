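#' Assign entities to DSU clusters by shared-AV percentage
#'
#' For entity \eqn{E_i} and subgroup \eqn{AVSG_j} the sharing score is
#' \eqn{|E_i \cap AVSG_j| / |AVSG_j|}; each entity goes to the DSU maximizing
#' it, ties broken by the lowest triple code. Entities sharing nothing with
#' any DSU form an explicit outlier cluster (\code{NA} assignment).
#'
#' @param dataset a \code{pdd_data} object.
#' @param dsus list of DSU records (from \code{\link{derive_dsus}}).
#' @return data frame with \code{eid}, \code{dsu} (label or \code{NA}),
#'   \code{sharing}.
#' @export
cluster_entities <- function(dataset, dsus) {
  stopifnot(length(dsus) >= 1)
  # stable order: lowest code first, so which.max resolves ties correctly
  codes <- t(vapply(dsus, `[[`, integer(3), "code"))
  ord <- order(codes[, 1], codes[, 2], codes[, 3])
  dsus <- dsus[ord]
  labels <- vapply(dsus, `[[`, character(1), "label")
  member_sets <- lapply(dsus, `[[`, "members")

  m <- dataset$n_entities
  out_dsu <- rep(NA_character_, m)
  out_share <- numeric(m)
  for (r in seq_len(m)) {
    row <- dataset$cells[r, ]
    eavs <- av_key(dataset$attributes[!is.na(row)], row[!is.na(row)])
    sh <- vapply(member_sets,
                 function(ms) sum(ms %in% eavs) / length(ms), numeric(1))
    best <- which.max(sh)
    if (sh[best] > 0) {
      out_dsu[r] <- labels[best]
      out_share[r] <- sh[best]
    }
  }
  data.frame(eid = dataset$entity_ids, dsu = out_dsu, sharing = out_share,
             stringsAsFactors = FALSE)
}

#' Class status of one entity from its per-class pattern counts
#'
#' Given \code{f}, the number of accepted patterns of each class occurring on
#' the entity, and the entity's reference class (its given label, or its
#' cluster's implicit class in label-free mode):
#' \itemize{
#'   \item \code{Cor} — the reference class strictly dominates every other;
#'   \item \code{Inc} — some other class strictly dominates and the
#'     reference count is non-zero;
#'   \item \code{Und} — the maximal count is non-zero and shared between the
#'     reference class and another;
#'   \item \code{OL} — no pattern of any class (outlier);
#'   \item \code{Cra} — the reference count is zero but another class has
#'     patterns: the class is readjusted to the unique argmax (a tied argmax
#'     falls back to \code{Und}).
#' }
#'
#' @param f named numeric vector of per-class pattern counts (all classes).
#' @param given_class reference class name (must appear in \code{names(f)}).
#' @return list with \code{status} and \code{adjusted_class}
#'   (\code{NA} unless status is \code{Cra}).
#' @export
assign_class_status <- function(f, given_class) {
  stopifnot(!is.null(names(f)), given_class %in% names(f))
  fi <- f[[given_class]]
  fo <- f[setdiff(names(f), given_class)]
  mx_other <- if (length(fo)) max(fo) else 0
  if (fi == 0 && mx_other == 0) {
    return(list(status = "OL", adjusted_class = NA_character_))
  }
  if (fi == 0) {
    top <- names(fo)[fo == mx_other]
    if (length(top) > 1) {
      return(list(status = "Und", adjusted_class = NA_character_))
    }
    return(list(status = "Cra", adjusted_class = top))
  }
  if (fi > mx_other) return(list(status = "Cor", adjusted_class = NA_character_))
  if (fi == mx_other) return(list(status = "Und", adjusted_class = NA_character_))
  list(status = "Inc", adjusted_class = NA_character_)
}

# class a mode's record positively asserts for the entity, or NA
asserted_class <- function(rec) {
  if (rec$status == "Cor") return(rec$given_class)
  if (rec$status == "Cra") return(rec$adjusted_class)
  NA_character_
}

#' Integrate with-label and no-label class statuses for one entity
#'
#' Rule 1: a Cor/Inc/Und decision from the with-label (wCL) run stands, but a
#' confirmed readjustment (Cra) found in either run is applied. Rule 2: an
#' entity that is OL/Und in both keeps the status found in either one. A
#' positive class assertion (Cor or confirmed Cra) from one mode overrides
#' OL/Und/Inc in the other; the wCL assertion wins on conflict.
#'
#' @param wcl,ncl records for the same entity: lists with \code{eid},
#'   \code{status}, \code{given_class}, \code{adjusted_class}.
#' @return list with \code{final_status} and \code{final_class} (\code{NA}
#'   when no class is asserted).
#' @export
integrate_class_status <- function(wcl, ncl) {
  if (!identical(wcl$eid, ncl$eid)) stop("EID mismatch between modes")
  wc <- asserted_class(wcl)
  nc <- asserted_class(ncl)
  if (!is.na(wc)) {
    return(list(final_status = wcl$status, final_class = wc))
  }
  if (!is.na(nc)) {
    # readjusted from the no-label run (Rule 1 readjustment / Rule 2 rescue)
    st <- if (ncl$status == "Cor" && wcl$status %in% c("OL", "Inc", "Und"))
      "Cra" else ncl$status
    return(list(final_status = st, final_class = nc))
  }
  st <- if (wcl$status == "OL" && ncl$status != "OL") ncl$status else wcl$status
  list(final_status = st, final_class = NA_character_)
}

#' Class-association accuracy
#'
#' Share of entities whose class is established: correctly classified plus
#' (optionally) confirmed readjusted mislabels, over all entities. Incorrect
#' and undecided entities count as errors.
#'
#' @param statuses character vector of class statuses
#'   (\code{Cor}/\code{Cra}/\code{Und}/\code{Inc}/\code{OL}).
#' @param count_readjusted include \code{Cra} entities as correct (after
#'   readjustment, the default); \code{FALSE} gives the before-readjustment
#'   accuracy.
#' @return accuracy in percent.
#' @examples
#' compute_accuracy(c(rep("Cor", 90), rep("Cra", 0), rep("Inc", 2)))  # 97.83 on N = 92
#' @export
compute_accuracy <- function(statuses, count_readjusted = TRUE) {
  stopifnot(length(statuses) > 0)
  good <- if (count_readjusted) c("Cor", "Cra") else "Cor"
  100 * sum(statuses %in% good) / length(statuses)
}

# per-entity, per-class accepted-pattern counts; every accepted pattern
# (including sub-patterns) counts once on each entity it covers
entity_class_counts <- function(patterns, entity_ids, classes) {
  f <- matrix(0L, nrow = length(entity_ids), ncol = length(classes),
              dimnames = list(as.character(entity_ids), classes))
  for (p in patterns) {
    if (is.na(p$class)) next
    f[as.character(p$cover), p$class] <- f[as.character(p$cover), p$class] + 1L
  }
  f
}

# majority given-label per entity cluster (implicit class); ties and empty
# clusters resolve to the alphabetically first involved label
implicit_classes <- function(assignment, labels) {
  cl <- rep(NA_character_, nrow(assignment))
  key <- ifelse(is.na(assignment$dsu), "<outlier>", assignment$dsu)
  for (g in unique(key)) {
    idx <- which(key == g)
    tab <- sort(table(labels[as.character(assignment$eid[idx])]),
                decreasing = TRUE)
    cl[idx] <- names(tab)[1]
  }
  stats::setNames(cl, as.character(assignment$eid))
}
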