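# fixtures and independent brute-force oracles used across the suite

# small random categorical data frame (no implants)
random_table <- function(m, n_attr, alphabet = c("a", "b", "c"), seed = 1) {
  withr::local_seed(seed)
  df <- as.data.frame(
    replicate(n_attr, sample(alphabet, m, replace = TRUE), simplify = FALSE),
    stringsAsFactors = FALSE)
  names(df) <- paste0("A", seq_len(n_attr))
  df
}

# brute-force cover of one AV by full row scan
scan_cover <- function(dataset, key) {
  parts <- strsplit(key, "=", fixed = TRUE)[[1]]
  a <- parts[1]; v <- paste(parts[-1], collapse = "=")
  hit <- !is.na(dataset$cells[, a]) & dataset$cells[, a] == v
  sort(dataset$entity_ids[hit])
}

# brute-force co-occurrence count of an AV set by row scan
scan_support <- function(dataset, keys) {
  covers <- lapply(keys, function(k) scan_cover(dataset, k))
  length(Reduce(intersect, covers))
}

# connected components (size >= 2) of an undirected edge list, via igraph
igraph_components <- function(edges, vertices) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  mem <- igraph::components(g)$membership
  comp <- split(names(mem), mem)
  comp <- comp[vapply(comp, length, integer(1)) >= 2]
  lapply(unname(comp), sort)
}

# Eq.-style arithmetic, written independently of the package internals
oracle_pattern_stats <- function(occ_av, occ, m) {
  pf <- prod(occ_av / m)
  expv <- m * pf
  res <- (occ - expv) / sqrt(expv)
  list(exp = expv, residual = res, variance = 1 - pf,
       sr = res / sqrt(1 - pf))
}

# exhaustive pattern discovery: every subset of size >= 2, support by row
# scan, accept iff sr > threshold, then brute-force delta-closedness
oracle_discover <- function(dataset, members, threshold, delta = 0) {
  m <- dataset$n_entities
  accepted <- list()
  for (k in 2:length(members)) {
    for (sub in utils::combn(members, k, simplify = FALSE)) {
      occ_av <- vapply(sub, function(x) length(scan_cover(dataset, x)),
                       integer(1))
      if (any(occ_av == 0)) next
      occ <- scan_support(dataset, sub)
      st <- oracle_pattern_stats(occ_av, occ, m)
      if (st$sr > threshold) {
        accepted[[length(accepted) + 1L]] <- list(avs = sort(sub), occ = occ)
      }
    }
  }
  if (length(accepted) <= 1) return(accepted)
  keep <- rep(TRUE, length(accepted))
  for (i in seq_along(accepted)) {
    for (j in seq_along(accepted)) {
      if (i != j &&
          length(accepted[[j]]$avs) > length(accepted[[i]]$avs) &&
          all(accepted[[i]]$avs %in% accepted[[j]]$avs) &&
          accepted[[j]]$occ >= accepted[[i]]$occ - delta) {
        keep[i] <- FALSE
      }
    }
  }
  accepted[keep]
}

# brute-force class-status rule table (independent re-statement of the rules)
oracle_status <- function(f, given) {
  others <- f[names(f) != given]
  mo <- if (length(others)) max(others) else 0
  fi <- f[[given]]
  if (fi == 0 && mo == 0) return("OL")
  if (fi == 0) {
    return(if (sum(others == mo) > 1) "Und" else "Cra")
  }
  if (fi > mo) "Cor" else if (fi == mo) "Und" else "Inc"
}

pattern_set_found <- function(fit, avset) {
  any(vapply(fit$patterns, function(p) setequal(p$avs, avset), logical(1)))
}
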