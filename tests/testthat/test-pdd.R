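fit_replica <- function(seed = 7, ...) {
  g <- synth_generate(synth_spec(...), seed = seed)
  list(g = g, fit = pdd(g$data, class_col = "class", eid_col = "eid"))
}

test_that("the full pipeline recovers implants inside class-pure DSUs", {
  r <- fit_replica(seed = 7)
  fit <- r$fit
  expect_gte(length(fit$spaces), 3)
  for (avset in r$g$manifest$implant_avsets) {
    expect_true(pattern_set_found(fit, avset))
  }
  # every AV-group member keeps a significant partner in its DSU's space
  for (d in fit$dsus) {
    sp <- fit$spaces[[d$code[1]]]
    if (length(d$members) < 2) next
    for (m in d$members) {
      expect_true(any(sp$rsr[m, setdiff(colnames(sp$rsr), m)] >
                      fit$config$sr_threshold))
    }
  }
  # knowledge-space rows with patterns concentrate on a single class
  ks <- fit$knowledge_space
  for (r_i in which(rowSums(ks) > 0)) {
    expect_gte(max(ks[r_i, ]) / sum(ks[r_i, ]), 0.8)
  }
})

test_that("implanted AVs sit at the extremes of their disentangled space", {
  r <- fit_replica(seed = 19)
  fit <- r$fit
  for (avset in r$g$manifest$implant_avsets) {
    hit <- FALSE
    for (sp in fit$spaces) {
      ext <- names(sort(-abs(sp$scores))[seq_len(3)])
      if (setequal(ext, avset)) hit <- TRUE
    }
    expect_true(hit)
  }
})

test_that("reruns and re-exports are byte-identical", {
  g <- synth_generate(synth_spec(), seed = 23)
  f1 <- pdd(g$data, class_col = "class", eid_col = "eid")
  f2 <- pdd(g$data, class_col = "class", eid_col = "eid")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_kb(f1, d1)
  export_kb(f2, d2)
  for (f in c("knowledge_space.tsv", "pattern_space.json",
              "entity_space.tsv", "provenance.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("exports reload into the in-memory knowledge base", {
  g <- synth_generate(synth_spec(), seed = 29)
  fit <- pdd(g$data, class_col = "class", eid_col = "eid")
  dir <- withr::local_tempdir()
  export_kb(fit, dir)

  ks <- as.matrix(utils::read.delim(file.path(dir, "knowledge_space.tsv"),
                                    row.names = 1, check.names = FALSE))
  expect_equal(ks, fit$knowledge_space, ignore_attr = TRUE)
  expect_identical(rownames(ks), rownames(fit$knowledge_space))

  es <- utils::read.delim(file.path(dir, "entity_space.tsv"),
                          check.names = FALSE)
  expect_equal(nrow(es), fit$dataset$n_entities)
  expect_identical(es$final_status, fit$entity_space$final_status)

  ps <- jsonlite::read_json(file.path(dir, "pattern_space.json"))
  expect_length(ps, length(fit$dsus))
  expect_equal(sum(vapply(ps, function(d) length(d$patterns), integer(1))),
               length(fit$patterns))
  # cross-space consistency: entity-space DSU columns match pattern space
  dsu_cols <- setdiff(names(es),
                      c("eid", "cluster", "sharing", "given_class",
                        "wcl_status", "wcl_adjusted", "ncl_status",
                        "ncl_adjusted", "final_status", "final_class"))
  expect_setequal(dsu_cols, vapply(ps, function(d) d$dsu, character(1)))
})

test_that("unlabeled data yields implicit-group statuses and a valid KB", {
  g <- synth_generate(synth_spec(labeled = FALSE), seed = 31)
  expect_false("class" %in% names(g$data))
  fit <- pdd(g$data, eid_col = "eid")
  es <- fit$entity_space
  expect_false("wcl_status" %in% names(es))
  expect_true(all(es$ncl_status %in% c("Cor", "Cra", "Und", "Inc", "OL")))
  # knowledge-space columns are the cluster-derived implicit groups
  expect_true(all(colnames(fit$knowledge_space) %in%
                  stats::na.omit(unique(es$cluster))))
  dir <- withr::local_tempdir()
  expect_length(export_kb(fit, dir), 4)
})

test_that("a dataset with no significant associations exports an empty, well-formed KB", {
  df <- data.frame(A1 = rep(c("a", "b"), each = 2),
                   A2 = rep(c("x", "y"), 2), stringsAsFactors = FALSE)
  fit <- pdd(df)
  expect_length(fit$spaces, 0)
  expect_length(fit$patterns, 0)
  expect_true(all(fit$entity_space$final_status == "OL"))
  dir <- withr::local_tempdir()
  paths <- export_kb(fit, dir)
  expect_true(all(file.exists(paths)))
  es <- utils::read.delim(file.path(dir, "entity_space.tsv"))
  expect_equal(nrow(es), 4)
})

test_that("flipped labels on implant carriers are readjusted to the true class", {
  rates <- vapply(1:20, function(s) {
    g <- synth_generate(synth_spec(label_flip_rate = 0.10), seed = 600 + s)
    fit <- pdd(g$data, class_col = "class", eid_col = "eid")
    implant_eids <- unique(g$manifest$implanted_cells$eid)
    flipped <- intersect(g$manifest$flipped_eids, implant_eids)
    if (length(flipped) == 0) return(NA_real_)
    es <- fit$entity_space
    ok <- vapply(flipped, function(e) {
      row <- es[es$eid == e, ]
      identical(row$final_status, "Cra") &&
        identical(row$final_class, g$manifest$true_class[e])
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_gte(mean(rates, na.rm = TRUE), 0.90)
  # integration never lowers the class-association accuracy
  g <- synth_generate(synth_spec(label_flip_rate = 0.10), seed = 900)
  fit <- pdd(g$data, class_col = "class", eid_col = "eid")
  expect_gte(fit$accuracy["after"], fit$accuracy["before"])
})

test_that("model methods print, plot, and predict on held-out rows", {
  r <- fit_replica(seed = 37)
  fit <- r$fit
  expect_output(print(fit), "disentanglement")
  expect_output(print(summary(fit)), "DSU")
  expect_silent({
    pdf(NULL)
    plot(fit)
    dev.off()
  })
  expect_equal(dim(residuals(fit)), c(nrow(fit$sr$av), nrow(fit$sr$av)))

  # predictions on the implant rows themselves recover the implant class
  g <- r$g
  implant_rows <- g$data[g$data$eid %in% 80:99, ]
  pred <- predict(fit, implant_rows)
  expect_true(mean(pred == "C1", na.rm = TRUE) > 0.9)
})
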