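#' Equal-frequency discretization of a numeric vector
#'
#' Maps numeric values onto at most \code{n_bins} quantile intervals with
#' (approximately) equal occupancy. Ties at a quantile boundary fall into the
#' lower bin, so a value equal to a boundary is never split across bins and
#' the mapping is deterministic. A constant column collapses to a single bin.
#'
#' @param values numeric vector (may contain \code{NA}); at least one value
#'   must be non-missing.
#' @param n_bins positive integer, the requested number of intervals.
#' @param name optional column name used in error messages.
#' @return character vector of bin labels of the form \code{"(lo,hi]"}
#'   (or \code{"<constant>"} for a degenerate column), same length as
#'   \code{values}, \code{NA} where the input is \code{NA}. The numeric break
#'   points are attached as attribute \code{"breaks"} for audit export.
#' @examples
#' discretize_numeric(1:9, 3)   # tertiles {1,2,3} {4,5,6} {7,8,9}
#' discretize_numeric(c(5, 5, 5, 5), 3)  # one bin
#' @export
discretize_numeric <- function(values, n_bins, name = "column") {
  stopifnot(length(values) >= 1, n_bins >= 1)
  if (all(is.na(values))) {
    stop("all values missing in numeric column '", name, "'")
  }
  finite <- values[!is.na(values)]
  qs <- stats::quantile(finite, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7)
  breaks <- unique(qs)
  if (length(breaks) == 1L) {
    out <- rep(NA_character_, length(values))
    out[!is.na(values)] <- format(breaks)
    attr(out, "breaks") <- breaks
    return(out)
  }
  # right-closed intervals put boundary ties in the lower bin
  lab <- cut(values, breaks = breaks, include.lowest = TRUE, right = TRUE)
  out <- as.character(lab)
  attr(out, "breaks") <- breaks
  out
}

#' Construct a categorical dataset from a data frame
#'
#' Normalizes a mixed-mode table into the discrete form used throughout the
#' pipeline: every attribute holds a finite alphabet of categorical attribute
#' values (AVs), numeric attributes having been quantized into equal-frequency
#' intervals. Missing cells carry no AV by default (they contribute to no AV
#' cover); set \code{missing_as_av = TRUE} to treat missingness as an explicit
#' category.
#'
#' @param df data frame, one row per entity.
#' @param class_col optional name of the class-label column (excluded from the
#'   attribute set).
#' @param eid_col optional name of an entity-ID column; when absent, entities
#'   are numbered 1..M in row order.
#' @param bins default number of quantile bins for numeric attributes; may be
#'   a named vector to override per attribute.
#' @param missing_as_av logical; keep missing cells as an \code{"<NA>"} AV.
#' @return an object of class \code{pdd_data}: list with \code{cells}
#'   (M x N character matrix, \code{NA} = missing), \code{entity_ids},
#'   \code{attributes}, \code{class_labels} (named character or \code{NULL}),
#'   \code{n_entities}, and \code{discretization} (attribute -> breaks).
#' @export
categorical_dataset <- function(df, class_col = NULL, eid_col = NULL,
                                bins = 3, missing_as_av = FALSE) {
  stopifnot(is.data.frame(df), nrow(df) >= 1)
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  if (!is.null(eid_col)) {
    stopifnot(eid_col %in% names(df))
    entity_ids <- as.integer(df[[eid_col]])
    df[[eid_col]] <- NULL
  } else {
    entity_ids <- seq_len(nrow(df))
  }
  if (anyDuplicated(entity_ids)) stop("entity IDs must be unique")

  class_labels <- NULL
  if (!is.null(class_col)) {
    stopifnot(class_col %in% names(df))
    class_labels <- as.character(df[[class_col]])
    if (anyNA(class_labels)) stop("class labels must cover every entity")
    names(class_labels) <- as.character(entity_ids)
    df[[class_col]] <- NULL
  }
  if (ncol(df) < 1) stop("dataset needs at least one attribute")

  discretization <- list()
  cells <- matrix(NA_character_, nrow = nrow(df), ncol = ncol(df),
                  dimnames = list(NULL, names(df)))
  for (a in names(df)) {
    col <- df[[a]]
    if (is.numeric(col)) {
      nb <- if (length(bins) > 1 && a %in% names(bins)) bins[[a]] else
        if (!is.null(names(bins))) 3 else bins
      lab <- discretize_numeric(col, nb, name = a)
      discretization[[a]] <- attr(lab, "breaks")
      cells[, a] <- as.character(lab)
    } else {
      v <- as.character(col)
      v[!is.na(v) & v == ""] <- NA_character_
      cells[, a] <- v
    }
    if (missing_as_av) cells[is.na(cells[, a]), a] <- "<NA>"
  }

  structure(list(cells = cells,
                 entity_ids = entity_ids,
                 attributes = colnames(cells),
                 class_labels = class_labels,
                 n_entities = nrow(cells),
                 discretization = discretization),
            class = "pdd_data")
}

#' @export
print.pdd_data <- function(x, ...) {
  cat("Categorical dataset:", x$n_entities, "entities x",
      length(x$attributes), "attributes\n")
  k <- sum(vapply(seq_along(x$attributes),
                  function(j) length(unique(stats::na.omit(x$cells[, j]))),
                  integer(1)))
  cat("  distinct AVs:", k,
      if (is.null(x$class_labels)) "(unlabeled)" else
        paste0("| classes: ", paste(sort(unique(x$class_labels)), collapse = ", ")),
      "\n")
  invisible(x)
}

# canonical AV key "Attr=Value"
av_key <- function(attribute, value) paste0(attribute, "=", value)

#' Build the Entity-ID address table
#'
#' Lists, for every distinct attribute value in the dataset, the sorted
#' entity IDs of the entities carrying it. The support of any AV set is then
#' the cardinality of the intersection of its members' ID lists, so no
#' candidate ever requires a rescan of the raw table.
#'
#' @param dataset a \code{pdd_data} object.
#' @return object of class \code{pdd_address_table}: a named list of strictly
#'   increasing integer vectors keyed \code{"Attr=Value"}, with attributes
#'   \code{av} (data frame: attribute, value, occ) and \code{n_entities}.
#' @export
build_address_table <- function(dataset) {
  stopifnot(inherits(dataset, "pdd_data"))
  entries <- list()
  av_attr <- character(0); av_val <- character(0)
  for (a in dataset$attributes) {
    col <- dataset$cells[, a]
    ok <- !is.na(col)
    if (!any(ok)) next                      # all-missing attribute: no entries
    sp <- split(dataset$entity_ids[ok], col[ok])
    for (v in names(sp)) {
      entries[[av_key(a, v)]] <- sort(sp[[v]])
      av_attr <- c(av_attr, a); av_val <- c(av_val, v)
    }
  }
  structure(entries,
            av = data.frame(attribute = av_attr, value = av_val,
                            occ = vapply(entries, length, integer(1)),
                            key = names(entries),
                            row.names = NULL, stringsAsFactors = FALSE),
            n_entities = dataset$n_entities,
            class = "pdd_address_table")
}

#' @export
print.pdd_address_table <- function(x, ...) {
  cat("Address table:", length(x), "distinct AVs over",
      attr(x, "n_entities"), "entities\n")
  invisible(x)
}

#' Entity-ID intersection of a set of attribute values
#'
#' Returns the sorted entity IDs of the entities containing every AV in
#' \code{avs}; its length is the co-occurrence count used by all downstream
#' significance tests. An AV absent from the table has an empty cover.
#'
#' @param table a \code{pdd_address_table}.
#' @param avs character vector of AV keys (\code{"Attr=Value"}), non-empty.
#' @return sorted integer vector of entity IDs.
#' @export
eid_intersection <- function(table, avs) {
  stopifnot(inherits(table, "pdd_address_table"))
  if (length(avs) == 0) stop("eid_intersection of an empty AV set is undefined")
  covers <- lapply(avs, function(k) {
    cv <- table[[k]]
    if (is.null(cv)) integer(0) else cv
  })
  Reduce(intersect, covers)
}
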