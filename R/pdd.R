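#' Fit the pattern discovery and disentanglement model
#'
#' Runs the full pipeline on a mixed-mode table: equal-frequency
#' discretization, address-table construction, the pairwise adjusted
#' standardized residual (SR) matrix, PCA disentanglement into significant
#' association spaces, AV-group/subgroup clustering into DSUs, high-order
#' pattern discovery with a delta-closed filter, entity clustering, and —
#' when a class column is present — class-status assignment in both the
#' with-label (wCL) and no-label (nCL) modes, their integration, and
#' mislabel readjustment. Labels never influence discovery (steps 1-5); the
#' two modes differ only in the reference class each entity is judged
#' against.
#'
#' @param data data frame, one row per entity.
#' @param class_col name of the class column, or \code{NULL} for unlabeled.
#' @param eid_col name of the entity-ID column, or \code{NULL} to number
#'   rows 1..M.
#' @param bins quantile bins for numeric attributes (default 3: low/mid/high).
#' @param sr_threshold significance threshold on residuals (1.96 = 95%).
#' @param sim_cutoff subgroup cover-similarity cutoff (default 0.5).
#' @param delta support slack of the delta-closed filter (0 = closed).
#' @param variant pairwise residual variant, see \code{\link{sr_pair}}.
#' @param linkage subgroup clustering linkage.
#' @param missing_as_av treat missing cells as an explicit AV.
#' @return an object of class \code{pdd}; see \code{\link{summary.pdd}},
#'   \code{\link{export_kb}}.
#' @examples
#' d <- synth_generate(synth_spec(), seed = 7)
#' fit <- pdd(d$data, class_col = "class", eid_col = "eid")
#' fit
#' @export
pdd <- function(data, class_col = NULL, eid_col = NULL, bins = 3,
                sr_threshold = 1.96, sim_cutoff = 0.5, delta = 0,
                variant = c("printed", "haberman"),
                linkage = "average", missing_as_av = FALSE) {
  variant <- match.arg(variant)
  cl <- match.call()
  dataset <- categorical_dataset(data, class_col = class_col,
                                 eid_col = eid_col, bins = bins,
                                 missing_as_av = missing_as_av)
  table <- build_address_table(dataset)
  srm <- build_sr_matrix(dataset, table, variant = variant)
  pca <- decompose_sr(srm)
  spaces <- select_significant_ds(pca, threshold = sr_threshold)
  dsus <- derive_dsus(spaces, srm$av, table, threshold = sr_threshold,
                      cutoff = sim_cutoff, linkage = linkage)

  patterns <- list()
  union_patterns <- list()
  for (d in dsus) {
    pats <- discover_patterns(d, table, dataset$n_entities,
                              threshold = sr_threshold, delta = delta)
    up <- union_pattern(pats)
    if (!is.null(up)) union_patterns[[d$label]] <- up
    patterns <- c(patterns, pats)
  }

  fit <- structure(list(
    call = cl,
    config = list(bins = bins, sr_threshold = sr_threshold,
                  sim_cutoff = sim_cutoff, delta = delta, variant = variant,
                  linkage = linkage, missing_as_av = missing_as_av,
                  class_col = class_col, eid_col = eid_col),
    dataset = dataset, table = table, freq = srm$freq, sr = srm,
    pca = pca, spaces = spaces, dsus = dsus,
    patterns = patterns, union_patterns = union_patterns),
    class = "pdd")

  if (length(dsus) > 0) {
    fit$assignment <- cluster_entities(dataset, dsus)
  } else {
    fit$assignment <- data.frame(eid = dataset$entity_ids,
                                 dsu = NA_character_, sharing = 0)
  }
  fit <- assemble_knowledge(fit)
  fit
}

# steps 6-7 + knowledge base assembly on a fitted structure
assemble_knowledge <- function(fit) {
  dataset <- fit$dataset
  eids <- as.character(dataset$entity_ids)
  labeled <- !is.null(dataset$class_labels)

  # class universe: given classes, or cluster identities when unlabeled
  if (labeled) {
    classes <- sort(unique(dataset$class_labels))
    labels <- dataset$class_labels
  } else {
    classes <- sort(unique(stats::na.omit(fit$assignment$dsu)))
    labels <- stats::setNames(
      ifelse(is.na(fit$assignment$dsu), NA_character_, fit$assignment$dsu),
      eids)
    if (length(classes) == 0) classes <- character(0)
  }

  # pattern-class association (labels used for evaluation only)
  for (i in seq_along(fit$patterns)) {
    p <- fit$patterns[[i]]
    fit$patterns[[i]]$class <- if (length(classes) == 0) NA_character_ else {
      cls <- labels[as.character(p$cover)]
      cls <- cls[!is.na(cls)]
      if (length(cls) == 0) NA_character_ else {
        tab <- sort(table(cls), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) NA_character_ else
          names(tab)[1]
      }
    }
  }

  # per-entity per-DSU pattern indicator counts
  dsu_labels <- vapply(fit$dsus, `[[`, character(1), "label")
  ind <- matrix(0L, nrow = dataset$n_entities, ncol = length(dsu_labels),
                dimnames = list(eids, dsu_labels))
  for (p in fit$patterns) {
    ind[as.character(p$cover), p$dsu_label] <-
      ind[as.character(p$cover), p$dsu_label] + 1L
  }
  fit$indicator <- ind

  if (length(classes) > 0) {
    f <- entity_class_counts(fit$patterns, dataset$entity_ids, classes)
  } else {
    f <- matrix(0L, dataset$n_entities, 0, dimnames = list(eids, NULL))
  }
  fit$class_counts <- f

  # knowledge space: DSU x class pattern-occurrence totals
  ks <- matrix(0L, nrow = length(dsu_labels), ncol = length(classes),
               dimnames = list(dsu_labels, classes))
  if (length(dsu_labels) && length(classes)) {
    ok <- !is.na(labels[eids])
    for (cc in classes) {
      sel <- ok & labels[eids] == cc
      if (any(sel)) ks[, cc] <- colSums(ind[sel, , drop = FALSE])
    }
  }
  fit$knowledge_space <- ks

  status_row <- function(eid, given) {
    if (is.na(given) || length(classes) == 0) {
      return(list(eid = eid, given_class = NA_character_, status = "OL",
                  adjusted_class = NA_character_))
    }
    st <- assign_class_status(f[as.character(eid), ], given)
    list(eid = eid, given_class = given, status = st$status,
         adjusted_class = st$adjusted_class)
  }

  if (labeled) {
    wcl <- lapply(dataset$entity_ids, function(e)
      status_row(e, dataset$class_labels[[as.character(e)]]))
    impl <- implicit_classes(fit$assignment, dataset$class_labels)
    ncl <- lapply(dataset$entity_ids, function(e)
      status_row(e, impl[[as.character(e)]]))
    final <- Map(integrate_class_status, wcl, ncl)
    fit$implicit <- impl
  } else {
    ncl <- lapply(seq_along(dataset$entity_ids), function(i)
      status_row(dataset$entity_ids[i], labels[[i]]))
    wcl <- NULL
    final <- lapply(ncl, function(r) list(
      final_status = r$status,
      final_class = if (r$status == "Cor") r$given_class else
        if (r$status == "Cra") r$adjusted_class else NA_character_))
  }

  es <- data.frame(eid = dataset$entity_ids, stringsAsFactors = FALSE)
  es$cluster <- fit$assignment$dsu
  es$sharing <- fit$assignment$sharing
  if (labeled) es$given_class <- dataset$class_labels[eids]
  if (!is.null(wcl)) {
    es$wcl_status <- vapply(wcl, `[[`, character(1), "status")
    es$wcl_adjusted <- vapply(wcl, `[[`, character(1), "adjusted_class")
  }
  es$ncl_status <- vapply(ncl, `[[`, character(1), "status")
  es$ncl_adjusted <- vapply(ncl, `[[`, character(1), "adjusted_class")
  es$final_status <- vapply(final, `[[`, character(1), "final_status")
  es$final_class <- vapply(final, `[[`, character(1), "final_class")
  fit$entity_space <- es

  if (labeled) {
    fit$accuracy <- c(
      before = compute_accuracy(es$wcl_status, count_readjusted = FALSE),
      after = compute_accuracy(es$final_status, count_readjusted = TRUE))
    fit$clustering_accuracy <- c(
      before = placement_accuracy(es, use_final = FALSE),
      after = placement_accuracy(es, use_final = TRUE))
  }
  fit
}

# share of entities sitting in a cluster whose majority class matches their
# own; a cluster member is misplaced when its (given or error-corrected)
# class differs from the cluster's majority class
placement_accuracy <- function(es, use_final = TRUE) {
  ref <- if (use_final) {
    ifelse(is.na(es$final_class), es$given_class, es$final_class)
  } else {
    es$given_class
  }
  key <- ifelse(is.na(es$cluster), "<outlier>", es$cluster)
  misplaced <- 0L
  for (g in unique(key)) {
    idx <- which(key == g)
    tab <- sort(table(ref[idx]), decreasing = TRUE)
    maj <- names(tab)[1]
    misplaced <- misplaced + sum(ref[idx] != maj)
  }
  100 * (nrow(es) - misplaced) / nrow(es)
}

#' @export
print.pdd <- function(x, ...) {
  cat("Pattern discovery and disentanglement fit\n")
  cat("  entities:", x$dataset$n_entities,
      "| attributes:", length(x$dataset$attributes),
      "| distinct AVs:", nrow(x$sr$av), "\n")
  cat("  significant disentangled spaces:", length(x$spaces),
      "| DSUs:", length(x$dsus),
      "| accepted patterns:", length(x$patterns), "\n")
  if (!is.null(x$accuracy)) {
    cat(sprintf("  class association accuracy: %.2f%% before, %.2f%% after readjustment\n",
                x$accuracy["before"], x$accuracy["after"]))
  }
  invisible(x)
}

#' Summarize a fitted disentanglement model
#'
#' @param object a \code{pdd} fit.
#' @param ... unused.
#' @return object of class \code{summary.pdd}: per-DSU table (members,
#'   pattern count, union-pattern size, dominant class), status counts, and
#'   accuracies.
#' @export
summary.pdd <- function(object, ...) {
  dsu_tab <- do.call(rbind, lapply(object$dsus, function(d) {
    pats <- Filter(function(p) identical(p$dsu_label, d$label), object$patterns)
    up <- object$union_patterns[[d$label]]
    cls <- vapply(pats, `[[`, character(1), "class")
    cls <- cls[!is.na(cls)]
    data.frame(dsu = d$label,
               n_avs = length(d$members),
               cover = length(d$cover),
               n_patterns = length(pats),
               union_size = if (is.null(up)) 0L else length(up$avs),
               dominant_class = if (length(cls) == 0) NA_character_ else
                 names(sort(table(cls), decreasing = TRUE))[1],
               stringsAsFactors = FALSE)
  }))
  structure(list(dsu_table = dsu_tab,
                 status_counts = table(object$entity_space$final_status),
                 accuracy = object$accuracy,
                 clustering_accuracy = object$clustering_accuracy,
                 config = object$config),
            class = "summary.pdd")
}

#' @export
print.summary.pdd <- function(x, ...) {
  cat("Disentangled-space units:\n")
  if (is.null(x$dsu_table)) cat("  (none significant)\n") else
    print(x$dsu_table, row.names = FALSE)
  cat("\nFinal class status counts:\n")
  print(x$status_counts)
  if (!is.null(x$accuracy)) {
    cat(sprintf("\nClass association accuracy: %.2f%% -> %.2f%% after readjustment\n",
                x$accuracy["before"], x$accuracy["after"]))
    cat(sprintf("Entity clustering accuracy: %.2f%% -> %.2f%% after readjustment\n",
                x$clustering_accuracy["before"], x$clustering_accuracy["after"]))
  }
  invisible(x)
}

#' Adjusted standardized residual matrix of a fit
#'
#' @param object a \code{pdd} fit.
#' @param ... unused.
#' @return the K x K SR matrix.
#' @export
residuals.pdd <- function(object, ...) object$sr$sr

#' Plot AV scores on the significant disentangled spaces
#'
#' Scatter of every attribute value's projection on the first two significant
#' spaces (or the first two components when fewer than two are significant).
#' AVs far from the origin carry strong associations; implanted or
#' source-specific AV sets appear at the extremes.
#'
#' @param x a \code{pdd} fit.
#' @param n_label number of extreme AVs to label per axis.
#' @param ... passed to \code{plot}.
#' @export
plot.pdd <- function(x, n_label = 6, ...) {
  sc <- x$pca$scores
  ij <- if (length(x$spaces) >= 2) c(x$spaces[[1]]$pc, x$spaces[[2]]$pc) else
    c(1, min(2, ncol(sc)))
  xs <- sc[, ij[1]]; ys <- sc[, ij[2]]
  graphics::plot(xs, ys, pch = 19, col = "grey40",
       xlab = paste0("PC", ij[1], " score"),
       ylab = paste0("PC", ij[2], " score"), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  ext <- unique(c(order(-abs(xs))[seq_len(min(n_label, length(xs)))],
                  order(-abs(ys))[seq_len(min(n_label, length(ys)))]))
  graphics::text(xs[ext], ys[ext], rownames(sc)[ext], pos = 3, cex = 0.7)
  invisible(x)
}

#' Predict classes for new entities from discovered patterns
#'
#' Applies the fit's discretization to new rows, counts the accepted
#' patterns of each class occurring on each row, and returns the
#' plurality class (\code{NA} when no pattern occurs or the top classes tie).
#'
#' @param object a \code{pdd} fit made from labeled data.
#' @param newdata data frame with the same attribute columns.
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.pdd <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  attrs <- object$dataset$attributes
  missing_cols <- setdiff(attrs, names(newdata))
  if (length(missing_cols)) stop("newdata lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  cells <- matrix(NA_character_, nrow(newdata), length(attrs),
                  dimnames = list(NULL, attrs))
  for (a in attrs) {
    col <- newdata[[a]]
    br <- object$dataset$discretization[[a]]
    if (!is.null(br) && is.numeric(col)) {
      cells[, a] <- if (length(br) == 1L) {
        ifelse(is.na(col), NA_character_, format(br))
      } else {
        as.character(cut(col, breaks = br, include.lowest = TRUE,
                         right = TRUE))
      }
    } else {
      cells[, a] <- as.character(col)
    }
  }
  classes <- colnames(object$class_counts)
  out <- rep(NA_character_, nrow(newdata))
  if (length(classes) == 0 || length(object$patterns) == 0) return(out)
  for (r in seq_len(nrow(newdata))) {
    row <- cells[r, ]
    eavs <- av_key(attrs[!is.na(row)], row[!is.na(row)])
    fr <- stats::setNames(numeric(length(classes)), classes)
    for (p in object$patterns) {
      if (!is.na(p$class) && all(p$avs %in% eavs)) {
        fr[p$class] <- fr[p$class] + 1
      }
    }
    if (max(fr) > 0) {
      top <- names(fr)[fr == max(fr)]
      if (length(top) == 1) out[r] <- top
    }
  }
  out
}
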