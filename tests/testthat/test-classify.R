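test_that("templates are elementwise class means", {
  tpl <- build_templates(rbind(c(1, 2, 3), c(3, 4, 5), c(10, 10, 10)),
                         c("AD", "AD", "HC"))
  expect_equal(tpl$AD$values, c(2, 3, 4))
  expect_equal(tpl$AD$n_train, 2L)
  # single-sample class: template equals that sample
  expect_equal(tpl$HC$values, c(10, 10, 10))
  expect_equal(names(tpl), c("AD", "HC"))  # fixed class order
  expect_error(build_templates(list(1:3, 1:4), c("AD", "AD")),
               "mismatched lengths")
  expect_error(build_templates(rbind(c(1, 2)), c("AD", "HC")),
               "one label per")
})

test_that("classification picks the most similar template, ties break AD < FTD < HC", {
  set.seed(61)
  tplv <- list(AD = rnorm(21), FTD = rnorm(21), HC = rnorm(21))
  templates <- lapply(names(tplv), function(cl)
    structure(list(label = cl, values = tplv[[cl]], n_train = 3L),
              class = c("class_template", "mefc_vector")))
  names(templates) <- names(tplv)
  # exact match under DTW: distance 0 to its own template
  fr <- classify_sample(tplv$HC, templates, measure_spec("DTW"))
  expect_equal(fr$predicted_label, "HC")
  expect_equal(unname(fr$scores["HC"]), 0)
  fr2 <- classify_sample(tplv$AD, templates, measure_spec("PCC"))
  expect_equal(fr2$predicted_label, "AD")
  expect_equal(unname(fr2$scores["AD"]), 1, tolerance = 1e-12)
  # engineered three-way tie: every template identical
  same <- templates
  for (cl in names(same)) same[[cl]]$values <- tplv$AD
  expect_warning(tie <- classify_sample(rnorm(21), same, measure_spec("PCC")),
                 "tie")
  expect_equal(tie$predicted_label, "AD")
})

test_that("accuracy is trace over total, in percent", {
  expect_equal(accuracy_from_confusion(diag(c(10, 10, 10))), 100)
  expect_equal(accuracy_from_confusion(matrix(5, 2, 2)), 50)
  cm <- rbind(c(30, 3, 3), c(4, 15, 4), c(5, 5, 19))
  expect_equal(accuracy_from_confusion(cm), 100 * 64 / 88)
  expect_error(accuracy_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("LOOCV is leakage-free with one fold per subject", {
  sep <- separable_features(n_per_class = 5L)
  res <- loocv(sep$X, sep$labels, measure_spec("PCC"),
               keep_fold_train = TRUE)
  expect_length(res$folds, 15L)
  expect_equal(sum(res$confusion), 15L)
  expect_equal(res$accuracy, 100)  # separable by construction
  ids <- vapply(res$folds, function(f) f$subject_id, "")
  expect_equal(sort(ids), sort(paste0("S", 1:15)))  # each predicted once
  for (k in seq_along(res$folds)) {
    f <- res$folds[[k]]
    # held-out subject absent from the training roster
    expect_false(f$subject_id %in% f$train_subjects)
    # and numerically absent from its own class template: the fold's
    # template must equal the mean over the other subjects only
    cl <- f$true_label
    others <- setdiff(which(sep$labels == cl), k)
    expect_equal(f$templates[[cl]],
                 colMeans(sep$X[others, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # determinism
  res2 <- loocv(sep$X, sep$labels, measure_spec("PCC"))
  expect_identical(res$confusion, res2$confusion)
  expect_error(loocv(sep$X[1:6, ], c("AD", "AD", "AD", "AD", "AD", "HC"),
                     measure_spec("PCC")), ">= 2 subjects")
})

test_that("the evaluation grid covers every cell with consistent summaries", {
  records <- small_cohort(seed = 3L, separation = 2, n = 3L,
                          channels = c("FP1", "FP2", "CZ"))
  feats <- suppressMessages(extract_features(records))
  grid <- evaluate_grid(feats, measures = c("PCC", "DTW"))
  expect_equal(nrow(grid$table), 3 * 5 * 2)  # channels x rhythms x measures
  expect_length(grid$confusions, 30L)
  for (cm in grid$confusions) expect_equal(sum(cm), 9L)
  # summary MAD recomputes from the table
  for (i in seq_len(nrow(grid$summary))) {
    row <- grid$summary[i, ]
    acc <- grid$table$accuracy[grid$table$rhythm == row$rhythm &
                               grid$table$measure == row$measure]
    expect_equal(row$mad_accuracy, mean(abs(acc - mean(acc))))
    expect_equal(row$best_accuracy, max(acc))
  }
  # hand case for the MAD definition
  expect_equal(mean(abs(c(50, 60, 70) - mean(c(50, 60, 70)))), 20 / 3)
  # tidy CSV output
  csv <- file.path(tempdir(), "grid.csv")
  write_grid(grid, csv)
  expect_equal(nrow(read.csv(csv)), 30L)
})
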