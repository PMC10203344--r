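#' Specification for a synthetic dataset with implanted associations
#'
#' Describes a discrete table of \code{m_entities} rows whose background
#' cells are i.i.d. uniform over each attribute's alphabet, with a set of
#' AV associations implanted on known entity-ID blocks, optional label-flip
#' noise and optional corruption of implant cells. The default replicates
#' the illustrative design used throughout the package's validation: 400
#' entities, 6 attributes each with a 10-letter alphabet (P..Y), and three
#' disjoint implanted triples, the first being \{A2=P, A3=Q, A5=R\} on
#' entities 75..129 (cover 55), the others on entities 150..219 and
#' 240..324. The block sizes are deliberately distinct so the three
#' association sources have well-separated eigenvalues, and the alphabet is
#' sized so that an implant's within-block association strength clearly
#' dominates background co-incidence (see the methods vignette for the
#' derivation).
#'
#' @param m_entities number of entities M.
#' @param attributes named list: attribute name -> character alphabet.
#' @param implants list of implants, each a list with \code{avs} (named
#'   character vector: attribute -> value), \code{eids} (integer vector of
#'   target entities), \code{class} (class name).
#' @param classes character vector of all class names (defaults to the
#'   implant classes).
#' @param label_flip_rate fraction of labels flipped to a different class.
#' @param cell_noise_rate fraction of implanted cells re-randomized.
#' @param labeled generate class labels at all.
#' @return object of class \code{pdd_synth_spec}.
#' @export
synth_spec <- function(m_entities = 400,
                       attributes = NULL,
                       implants = NULL,
                       classes = NULL,
                       label_flip_rate = 0,
                       cell_noise_rate = 0,
                       labeled = TRUE) {
  if (is.null(attributes)) {
    attributes <- stats::setNames(
      rep(list(LETTERS[16:25]), 6),    # P..Y, 10 symbols per attribute
      paste0("A", 1:6))
  }
  if (is.null(implants)) {
    implants <- list(
      list(avs = c(A2 = "P", A3 = "Q", A5 = "R"), eids = 75:129, class = "C1"),
      list(avs = c(A1 = "Q", A4 = "R", A6 = "P"), eids = 150:219, class = "C2"),
      list(avs = c(A2 = "S", A4 = "P", A5 = "T"), eids = 240:324, class = "C3"))
  }
  stopifnot(m_entities >= 1, length(attributes) >= 1,
            label_flip_rate >= 0, label_flip_rate < 1,
            cell_noise_rate >= 0, cell_noise_rate <= 1)
  for (im in implants) {
    stopifnot(all(names(im$avs) %in% names(attributes)),
              all(im$eids >= 1), all(im$eids <= m_entities))
    for (a in names(im$avs)) {
      if (!im$avs[[a]] %in% attributes[[a]])
        stop("implant value ", im$avs[[a]], " not in alphabet of ", a)
    }
  }
  # conflicting implants: two implants writing different values to one cell
  # (an implant flagged overwrite = TRUE deliberately replaces earlier cells)
  if (length(implants) > 1) {
    for (i in seq_along(implants)) {
      for (j in seq_along(implants)) {
        if (j <= i) next
        if (isTRUE(implants[[i]]$overwrite) || isTRUE(implants[[j]]$overwrite))
          next
        shared_e <- intersect(implants[[i]]$eids, implants[[j]]$eids)
        shared_a <- intersect(names(implants[[i]]$avs), names(implants[[j]]$avs))
        if (length(shared_e) && length(shared_a)) {
          for (a in shared_a) {
            if (implants[[i]]$avs[[a]] != implants[[j]]$avs[[a]])
              stop("conflicting implants at attribute ", a,
                   ", entity ", shared_e[1])
          }
        }
      }
    }
  }
  if (is.null(classes)) {
    classes <- unique(vapply(implants, `[[`, character(1), "class"))
    classes <- classes[!is.na(classes)]
    if (length(classes) == 0) classes <- "C1"
  }
  structure(list(m_entities = m_entities, attributes = attributes,
                 implants = implants, classes = classes,
                 label_flip_rate = label_flip_rate,
                 cell_noise_rate = cell_noise_rate, labeled = labeled),
            class = "pdd_synth_spec")
}

#' Generate a synthetic dataset from a specification
#'
#' Background cells are drawn i.i.d. uniform over each attribute's alphabet;
#' implant cells then overwrite their target entities and are corrupted at
#' \code{cell_noise_rate}; labels are set from implant classes (background
#' entities drawn uniformly over the declared classes) and flipped at
#' \code{label_flip_rate}. Fully reproducible from \code{seed}. The manifest
#' records every implanted cell, the true class of every entity, and the
#' flipped entity IDs, so expected pattern covers can be recomputed without
#' running the pipeline.
#'
#' @param spec a \code{pdd_synth_spec}.
#' @param seed integer seed.
#' @return list with \code{data} (data frame with \code{eid}, attribute
#'   columns, and \code{class} when labeled) and \code{manifest}.
#' @export
synth_generate <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pdd_synth_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  m <- spec$m_entities
  attrs <- names(spec$attributes)
  cells <- matrix(NA_character_, m, length(attrs), dimnames = list(NULL, attrs))
  for (a in attrs) {
    cells[, a] <- sample(spec$attributes[[a]], m, replace = TRUE)
  }

  implanted_cells <- list()
  true_class <- rep(NA_character_, m)
  for (im in spec$implants) {
    for (a in names(im$avs)) {
      cells[im$eids, a] <- im$avs[[a]]
      implanted_cells[[length(implanted_cells) + 1L]] <- data.frame(
        eid = im$eids, attribute = a, value = im$avs[[a]],
        class = im$class, stringsAsFactors = FALSE)
    }
    if (!is.na(im$class)) true_class[im$eids] <- im$class
  }
  implanted_cells <- if (length(implanted_cells))
    do.call(rbind, implanted_cells) else
    data.frame(eid = integer(0), attribute = character(0),
               value = character(0), class = character(0))

  # corrupt implanted cells
  noisy_cells <- integer(0)
  if (spec$cell_noise_rate > 0 && nrow(implanted_cells) > 0) {
    hit <- which(stats::runif(nrow(implanted_cells)) < spec$cell_noise_rate)
    for (r in hit) {
      a <- implanted_cells$attribute[r]
      cells[implanted_cells$eid[r], a] <- sample(spec$attributes[[a]], 1)
    }
    noisy_cells <- hit
  }

  df <- data.frame(eid = seq_len(m), cells, stringsAsFactors = FALSE)

  flipped <- integer(0)
  labels <- NULL
  if (spec$labeled) {
    bg <- is.na(true_class)
    true_class[bg] <- sample(spec$classes, sum(bg), replace = TRUE)
    labels <- true_class
    if (spec$label_flip_rate > 0) {
      flipped <- which(stats::runif(m) < spec$label_flip_rate)
      for (i in flipped) {
        labels[i] <- sample(setdiff(spec$classes, true_class[i]), 1)
      }
    }
    df$class <- labels
  }

  manifest <- list(spec = spec, seed = as.integer(seed),
                   implanted_cells = implanted_cells,
                   implant_avsets = lapply(spec$implants, function(im)
                     sort(av_key(names(im$avs), unname(im$avs)))),
                   true_class = true_class,
                   flipped_eids = flipped,
                   noisy_implant_cells = noisy_cells)
  list(data = df, manifest = manifest)
}

#' Add a rare cross-class group to a specification
#'
#' Implants one extra common pattern on \code{group_size} entities drawn
#' from distinct existing implant blocks (so from distinct classes) while
#' keeping their original class labels — a small group sharing a common
#' functionality across classes.
#'
#' @param base a \code{pdd_synth_spec}.
#' @param group_size number of entities to mark (>= 1).
#' @param pattern named character vector attribute -> value.
#' @return a new \code{pdd_synth_spec} with the extra implant; the extra
#'   implant carries class \code{NA} so member labels are untouched.
#' @export
make_rare_group_spec <- function(base, group_size, pattern) {
  stopifnot(inherits(base, "pdd_synth_spec"), group_size >= 1)
  if (group_size > base$m_entities) stop("group_size exceeds entity count")
  donors <- base$implants
  if (length(donors) == 0) stop("base spec has no implant blocks to draw from")
  eids <- integer(0)
  for (g in seq_len(group_size)) {
    blk <- donors[[((g - 1) %% length(donors)) + 1]]
    cand <- setdiff(blk$eids, eids)
    if (length(cand) == 0) stop("not enough distinct entities across classes")
    eids <- c(eids, cand[1])
  }
  for (a in names(pattern)) {
    stopifnot(a %in% names(base$attributes),
              pattern[[a]] %in% base$attributes[[a]])
  }
  extra <- list(avs = pattern, eids = eids, class = NA_character_,
                overwrite = TRUE)
  spec <- base
  spec$implants <- c(base$implants, list(extra))
  spec
}
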