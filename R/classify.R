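#' Build per-class mean templates
#'
#' The prototype of each class is the elementwise arithmetic mean of the
#' training feature vectors of that class (a median alternative is
#' exposed but the mean is the default).
#'
#' @param vectors list of `mefc_vector` objects, or a numeric matrix with
#'   one row per training sample.
#' @param labels character vector of class labels, one per sample.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return Named list of `class_template` objects (fields `label`,
#'   `values`, `n_train`, plus `channel`/`rhythm` when available), in
#'   fixed class order AD, FTD, HC (other labels follow alphabetically).
#' @export
build_templates <- function(vectors, labels, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  X <- as_value_matrix(vectors)
  labels <- as.character(labels)
  if (nrow(X) != length(labels))
    stop("need one label per training vector")
  classes <- intersect(MEFC_CLASSES, unique(labels))
  classes <- c(classes, sort(setdiff(unique(labels), MEFC_CLASSES)))
  meta <- vector_meta(vectors)
  templates <- lapply(classes, function(cl) {
    rows <- which(labels == cl)
    if (length(rows) == 0L)
      stop("validation error: class '", cl, "' has no training samples")
    vals <- if (statistic == "mean") colMeans(X[rows, , drop = FALSE])
            else apply(X[rows, , drop = FALSE], 2L, stats::median)
    structure(list(label = cl, values = as.numeric(vals),
                   n_train = length(rows),
                   channel = meta$channel, rhythm = meta$rhythm,
                   mode = meta$mode, n_windows = meta$n_windows),
              class = c("class_template", "mefc_vector"))
  })
  names(templates) <- classes
  templates
}

as_value_matrix <- function(vectors) {
  if (is.matrix(vectors)) return(vectors)
  if (inherits(vectors, "mefc_vector")) vectors <- list(vectors)
  lens <- vapply(vectors, function(v)
    length(if (inherits(v, "mefc_vector")) v$values else v), 0L)
  if (length(unique(lens)) != 1L)
    stop("validation error: feature vectors have mismatched lengths: ",
         paste(unique(lens), collapse = ", "))
  do.call(rbind, lapply(vectors, function(v)
    if (inherits(v, "mefc_vector")) v$values else as.numeric(v)))
}

vector_meta <- function(vectors) {
  if (is.list(vectors) && length(vectors) &&
      inherits(vectors[[1]], "mefc_vector")) {
    v <- vectors[[1]]
    list(channel = v$channel, rhythm = v$rhythm, mode = v$mode,
         n_windows = v$n_windows)
  } else list(channel = NA_character_, rhythm = NA_character_,
              mode = NA_character_, n_windows = NA_integer_)
}

#' Classify one sample against class templates
#'
#' Scores the sample against every template with the chosen measure and
#' predicts the most similar class (largest similarity, or smallest
#' distance for DTW). Exact score ties are broken by the fixed class
#' order AD < FTD < HC, with a warning.
#'
#' @param sample an `mefc_vector` (or numeric vector).
#' @param templates named list from [build_templates].
#' @param spec a [measure_spec].
#' @param subject_id identifier recorded in the result.
#' @param true_label known label recorded in the result (optional).
#' @return A `fold_result` list: `subject_id`, `true_label`,
#'   `predicted_label`, `scores` (named per class).
#' @export
classify_sample <- function(sample, templates, spec = measure_spec("PCC"),
                            subject_id = NA_character_,
                            true_label = NA_character_) {
  if (length(templates) == 0L) stop("no templates supplied")
  scores <- vapply(templates, function(tpl)
    compare_mefc(sample, tpl, spec)$score, 0)
  ranked <- if (spec$orientation == "distance") scores else -scores
  best <- which(ranked == min(ranked))
  if (length(best) > 1L) {
    warning("score tie between classes ",
            paste(names(scores)[best], collapse = ", "),
            "; broken by fixed class order")
    best <- best[1L]
  }
  structure(list(subject_id = subject_id, true_label = true_label,
                 predicted_label = names(scores)[best], scores = scores),
            class = "fold_result")
}

#' Overall accuracy from a confusion matrix
#'
#' @param cm square nonnegative integer matrix (rows: true class,
#'   columns: predicted).
#' @return Percentage, `100 * trace / total`.
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0))
    stop("confusion matrix must be square and nonnegative")
  total <- sum(cm)
  if (total == 0) stop("validation error: empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Leave-one-out cross-validated template classification
#'
#' Each subject is held out once; the per-class mean templates are built
#' from all remaining subjects only, and the held-out feature vector is
#' classified by its similarity to them. Pooling the per-fold predictions
#' yields the confusion matrix and the overall (micro) accuracy; with one
#' sample per fold this coincides with the mean of per-fold accuracies.
#'
#' @param vectors list of `mefc_vector` objects (or numeric matrix, one
#'   row per subject).
#' @param labels class label per subject; every class must have >= 2
#'   subjects so that each fold keeps at least one training sample per
#'   class.
#' @param spec a [measure_spec].
#' @param subject_ids optional identifiers (defaults to `S1`, `S2`, ...).
#' @param keep_fold_train if `TRUE`, each fold result also records the
#'   subject indices averaged into its templates (instrumentation for
#'   leakage auditing).
#' @return An `loocv_result` list: `folds`, `confusion` (true x
#'   predicted), `accuracy` (percent), `measure`.
#' @export
loocv <- function(vectors, labels, spec = measure_spec("PCC"),
                  subject_ids = NULL, keep_fold_train = FALSE) {
  X <- as_value_matrix(vectors)
  labels <- as.character(labels)
  n <- nrow(X)
  if (n != length(labels)) stop("need one label per subject")
  if (n < 2L) stop("validation error: LOOCV needs >= 2 subjects")
  tab <- table(labels)
  if (any(tab < 2L))
    stop("validation error: every class needs >= 2 subjects for LOOCV; ",
         "short: ", paste(names(tab)[tab < 2L], collapse = ", "))
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  classes <- intersect(MEFC_CLASSES, unique(labels))
  classes <- c(classes, sort(setdiff(unique(labels), MEFC_CLASSES)))

  # per-class column sums allow O(1) hold-one-out template updates
  sums <- lapply(classes, function(cl)
    colSums(X[labels == cl, , drop = FALSE]))
  names(sums) <- classes
  counts <- vapply(classes, function(cl) sum(labels == cl), 0L)
  names(counts) <- classes

  folds <- vector("list", n)
  for (i in seq_len(n)) {
    templates <- lapply(classes, function(cl) {
      s <- sums[[cl]]; k <- counts[[cl]]
      if (labels[i] == cl) { s <- s - X[i, ]; k <- k - 1L }
      structure(list(label = cl, values = s / k, n_train = k),
                class = c("class_template", "mefc_vector"))
    })
    names(templates) <- classes
    fr <- classify_sample(X[i, ], templates, spec,
                          subject_id = subject_ids[i],
                          true_label = labels[i])
    if (keep_fold_train) {
      fr$train_subjects <- subject_ids[-i]
      fr$templates <- lapply(templates, `[[`, "values")
    }
    folds[[i]] <- fr
  }
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (fr in folds)
    confusion[fr$true_label, fr$predicted_label] <-
      confusion[fr$true_label, fr$predicted_label] + 1L
  structure(list(folds = folds, confusion = confusion,
                 accuracy = accuracy_from_confusion(confusion),
                 measure = spec$name),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s: accuracy %.2f%% over %d folds\n",
              x$measure, x$accuracy, length(x$folds)))
  print(x$confusion)
  invisible(x)
}

#' Extract MEFC features for a whole cohort
#'
#' Runs the rhythm decomposition and entropy concatenation for every
#' subject, channel, and rhythm, producing the feature store consumed by
#' [evaluate_grid] and [loocv].
#'
#' @param records list of [eeg_record] objects sharing channel set,
#'   sampling rate, and segment length.
#' @param channels channels to process (default: all channels of the
#'   first record).
#' @param entropy_cfg an [entropy_config].
#' @param wavelet_cfg a [wavelet_config].
#' @return A `mefc_features` object: nested list
#'   `features[[channel]][[rhythm]]` = numeric matrix (subjects x
#'   feature length), plus `labels`, `subject_ids`, `channels`,
#'   `rhythms`, and the configs.
#' @export
extract_features <- function(records, channels = NULL,
                             entropy_cfg = entropy_config(),
                             wavelet_cfg = wavelet_config()) {
  stopifnot(length(records) >= 1L)
  if (is.null(channels)) channels <- records[[1]]$channels
  channels <- toupper(channels)
  labels <- vapply(records, function(r) r$label, "")
  ids <- vapply(records, function(r) r$subject_id, "")
  feats <- lapply(channels, function(ch) {
    per_subj <- lapply(records, function(rec) {
      rs <- extract_rhythms(rec, channel = ch, cfg = wavelet_cfg)
      lapply(MEFC_RHYTHMS, function(b)
        build_mefc(rs$bands[[b]], rs$fs, entropy_cfg,
                   channel = ch, band = b)$values)
    })
    out <- lapply(seq_along(MEFC_RHYTHMS), function(bi)
      do.call(rbind, lapply(per_subj, `[[`, bi)))
    names(out) <- MEFC_RHYTHMS
    out
  })
  names(feats) <- channels
  structure(list(features = feats, labels = labels, subject_ids = ids,
                 channels = channels, rhythms = MEFC_RHYTHMS,
                 entropy_cfg = entropy_cfg, wavelet_cfg = wavelet_cfg),
            class = "mefc_features")
}

#' Channel x rhythm x measure evaluation grid
#'
#' Runs LOOCV template classification for every combination of channel,
#' rhythm, and similarity measure, and summarizes per (rhythm, measure)
#' the best channel and the mean absolute deviation (MAD) of accuracy
#' across channels — the inter-channel stability statistic.
#'
#' @param feats a `mefc_features` object from [extract_features].
#' @param measures character vector of measure names (default all four).
#' @param channels,rhythms optional subsets.
#' @return A `grid_result` list: `table` (data.frame with one row per
#'   cell: channel, rhythm, measure, accuracy), `confusions` (list keyed
#'   `channel.rhythm.measure`), `summary` (per rhythm x measure: best
#'   channel, best accuracy, MAD across channels).
#' @export
evaluate_grid <- function(feats, measures = c("DTW", "PCC", "WC", "HTC"),
                          channels = NULL, rhythms = NULL) {
  stopifnot(inherits(feats, "mefc_features"))
  channels <- toupper(channels %||% feats$channels)
  rhythms <- rhythms %||% feats$rhythms
  specs <- lapply(measures, measure_spec)
  names(specs) <- toupper(measures)

  rows <- list(); confusions <- list()
  for (ch in channels) for (b in rhythms) {
    X <- feats$features[[ch]][[b]]
    for (ms in names(specs)) {
      res <- loocv(X, feats$labels, specs[[ms]],
                   subject_ids = feats$subject_ids)
      key <- paste(ch, b, ms, sep = ".")
      confusions[[key]] <- res$confusion
      rows[[key]] <- data.frame(channel = ch, rhythm = b, measure = ms,
                                accuracy = res$accuracy,
                                stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  summ <- do.call(rbind, lapply(rhythms, function(b)
    do.call(rbind, lapply(names(specs), function(ms) {
      sub <- tab[tab$rhythm == b & tab$measure == ms, ]
      best <- which.max(sub$accuracy)
      data.frame(rhythm = b, measure = ms,
                 best_channel = sub$channel[best],
                 best_accuracy = sub$accuracy[best],
                 mad_accuracy = mean(abs(sub$accuracy - mean(sub$accuracy))),
                 stringsAsFactors = FALSE)
    }))))
  rownames(summ) <- NULL
  structure(list(table = tab, confusions = confusions, summary = summ),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d cells (%d channels x %d rhythms x %d measures)\n",
              nrow(x$table), length(unique(x$table$channel)),
              length(unique(x$table$rhythm)),
              length(unique(x$table$measure))))
  cat("per rhythm x measure summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a grid result to tidy CSV and JSON confusions
#'
#' @param grid a `grid_result`.
#' @param csv_path output path for the tidy per-cell accuracy table.
#' @param json_path optional output path for the confusion matrices.
#' @return `csv_path`, invisibly.
#' @export
write_grid <- function(grid, csv_path, json_path = NULL) {
  write.csv(grid$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(grid$confusions, json_path, matrix = "rowmajor")
  invisible(csv_path)
}
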