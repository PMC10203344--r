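#' Export the three-space knowledge base of a fit
#'
#' Writes the linked knowledge base to \code{directory}:
#' \describe{
#'   \item{knowledge_space.tsv}{DSU x class matrix of pattern-occurrence
#'     totals — how concentrated each DSU's patterns are on one source.}
#'   \item{pattern_space.json}{per-DSU accepted patterns (AVs, order,
#'     observed and expected support, SR, class, cover size) and the union
#'     pattern summarizing each DSU.}
#'   \item{entity_space.tsv}{per-entity cluster assignment, per-DSU pattern
#'     indicator counts, class statuses in both modes, and the final
#'     (error-corrected) status and class.}
#'   \item{provenance.json}{configuration, thresholds, discretization map
#'     and accuracy figures, for auditability.}
#' }
#' Row and column orderings and JSON key order are stable, so identical fits
#' export byte-identical files.
#'
#' @param fit a \code{pdd} object.
#' @param directory output directory (created if needed).
#' @return invisibly, the character vector of paths written.
#' @export
export_kb <- function(fit, directory) {
  stopifnot(inherits(fit, "pdd"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)

  ks_path <- file.path(directory, "knowledge_space.tsv")
  ks <- fit$knowledge_space
  utils::write.table(ks, ks_path, sep = "\t", quote = FALSE, col.names = NA)

  pat_path <- file.path(directory, "pattern_space.json")
  pattern_space <- lapply(fit$dsus, function(d) {
    pats <- Filter(function(p) identical(p$dsu_label, d$label), fit$patterns)
    list(dsu = d$label,
         code = d$code,
         members = d$members,
         union_pattern = if (is.null(fit$union_patterns[[d$label]])) NULL else
           fit$union_patterns[[d$label]],
         patterns = lapply(pats, function(p) list(
           avs = p$avs, order = p$order, occ = p$occ, exp = p$exp,
           sr = p$sr, class = p$class, cover_size = length(p$cover))))
  })
  jsonlite::write_json(pattern_space, pat_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  es_path <- file.path(directory, "entity_space.tsv")
  es <- cbind(fit$entity_space,
              as.data.frame(fit$indicator, check.names = FALSE))
  utils::write.table(es, es_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  prov_path <- file.path(directory, "provenance.json")
  prov <- list(schema_version = "1.0",
               package = "pddisc",
               config = fit$config,
               n_entities = fit$dataset$n_entities,
               attributes = fit$dataset$attributes,
               discretization = fit$dataset$discretization,
               n_avs = nrow(fit$sr$av),
               n_significant_ds = length(fit$spaces),
               n_dsus = length(fit$dsus),
               n_patterns = length(fit$patterns),
               accuracy = as.list(fit$accuracy),
               clustering_accuracy = as.list(fit$clustering_accuracy))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  invisible(c(ks_path, pat_path, es_path, prov_path))
}
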