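#' Classification accuracy from confusion counts
#'
#' \code{(TP + TN) / (TP + TN + FP + FN)}, computed exactly.
#'
#' @param counts Named list or vector with non-negative entries \code{TP},
#'   \code{TN}, \code{FP}, \code{FN}.
#' @return Accuracy in [0, 1].
#' @export
accuracy <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("confusion counts are all zero")
  (tp + tn) / total
}

#' Leave-one-out cross-validated accuracy of a panel on one dataset
#'
#' Resolves the panel onto the test dataset's platform, then for each
#' sample refits the sibling logit coefficients on the remaining N-1
#' samples and predicts the held-out sample (probability >= \code{threshold}
#' calls tumor).  Folds whose training half loses one class entirely are
#' skipped with a warning and counted.  The panel identifiers come from
#' training elsewhere; only the coefficients are re-estimated, since
#' coefficients are dataset-specific by design.  Setting \code{refit =
#' FALSE} instead fits the coefficients once on the full test dataset and
#' scores every sample with that single model (no folds).
#'
#' @param test_dataset Expression dataset to evaluate on.
#' @param EI Identifier table (the trained panel).
#' @param M Similarity matrix.
#' @param platforms Named platform list.
#' @param threshold Tumor-call probability threshold.
#' @param refit Refit coefficients per fold (leave-one-out) or once.
#' @return A list: \code{confusion} (TP/TN/FP/FN), \code{accuracy},
#'   \code{predictions} (per-sample data frame with probability, call,
#'   label), \code{resolved}, \code{n_skipped}.
#' @export
loocv_accuracy <- function(test_dataset, EI, M, platforms,
                           threshold = 0.5, refit = TRUE) {
  stopifnot(inherits(test_dataset, "ab_dataset"))
  pf <- .get_platform(platforms, test_dataset$platform_id)
  resolved <- resolve_panel(EI, pf, M)
  X <- t(test_dataset$intensities[match(resolved$probe_id,
                                        rownames(test_dataset$intensities)),
                                  , drop = FALSE])
  y <- test_dataset$labels
  n <- length(y)
  prob <- rep(NA_real_, n)
  n_skipped <- 0L
  if (refit) {
    if (min(table(y)) < 2L)
      stop("leave-one-out evaluation needs >= 2 samples per class")
    for (i in seq_len(n)) {
      y_tr <- y[-i]
      if (length(unique(y_tr)) < 2L) {
        n_skipped <- n_skipped + 1L
        warning("fold ", i, " skipped: training half lost one class")
        next
      }
      fit_i <- fit_lm(X[-i, , drop = FALSE], y_tr)
      prob[i] <- predict_prob(fit_i, X[i, , drop = FALSE])
    }
  } else {
    fit <- fit_lm(X, y)
    prob <- predict_prob(fit, X)
  }
  eval_i <- which(!is.na(prob))
  call <- as.integer(prob[eval_i] >= threshold)
  yy <- y[eval_i]
  confusion <- list(TP = sum(call == 1L & yy == 1L),
                    TN = sum(call == 0L & yy == 0L),
                    FP = sum(call == 1L & yy == 0L),
                    FN = sum(call == 0L & yy == 1L))
  list(confusion = confusion,
       accuracy = accuracy(confusion),
       predictions = data.frame(sample_id = test_dataset$sample_ids,
                                probability = prob,
                                call = ifelse(is.na(prob), NA_integer_,
                                              as.integer(prob >= threshold)),
                                label = y, stringsAsFactors = FALSE),
       resolved = resolved,
       n_skipped = n_skipped)
}

#' Reciprocal test: train on all-but-one dataset, score on the held-out
#'
#' One dataset is set aside as the testing dataset; the genetic algorithm
#' mines an improved common logit model from the remaining (training)
#' datasets; the mined panel is then scored on the held-out dataset by
#' leave-one-out cross-validation.
#'
#' @param datasets Named or unnamed list of >= 2 expression datasets.
#' @param M Similarity matrix.
#' @param platforms Named platform list.
#' @param config \code{\link{ga_config}} for the mining step.
#' @param held_out_id \code{dataset_id} of the testing dataset.
#' @param IDF Identifier universe for the search (defaults to all probes).
#' @param refit Per-fold coefficient refitting (see
#'   \code{\link{loocv_accuracy}}).
#' @return A list of class \code{ab_reciprocal}: \code{held_out_dataset_id},
#'   \code{clm} (the mined model), plus the \code{\link{loocv_accuracy}}
#'   fields.
#' @export
reciprocal_test <- function(datasets, M, platforms, config, held_out_id,
                            IDF = identifier_universe(platforms),
                            refit = TRUE) {
  ids <- vapply(datasets, `[[`, character(1L), "dataset_id")
  if (!held_out_id %in% ids)
    stop("held-out dataset '", held_out_id, "' not among the datasets")
  if (length(datasets) < 2L) stop("at least two datasets required")
  training <- datasets[ids != held_out_id]
  test <- datasets[[which(ids == held_out_id)]]
  clm <- run_ga(training, M, platforms, config, IDF = IDF)
  res <- loocv_accuracy(test, clm$EI, M, platforms, refit = refit)
  structure(c(list(held_out_dataset_id = held_out_id, clm = clm), res),
            class = "ab_reciprocal")
}

#' @export
print.ab_reciprocal <- function(x, ...) {
  cat("<reciprocal test> held out ", x$held_out_dataset_id,
      ": accuracy ", sprintf("%.3f", x$accuracy), " (TP ",
      x$confusion$TP, " TN ", x$confusion$TN, " FP ", x$confusion$FP,
      " FN ", x$confusion$FN, ")\n", sep = "")
  invisible(x)
}

#' Leave-one-biomarker-out ("defective model") ablation
#'
#' Removes each panel gene in turn and re-scores the k resulting (k-1)-gene
#' defective panels on the held-out dataset by leave-one-out
#' cross-validation, alongside the intact panel's accuracy.  When every
#' biomarker carries signal, defective panels score lower on average --
#' the panel acts through the combination of its genes, not any single one.
#'
#' @param clm Mined \code{ab_clm} with a panel of >= 2 genes.
#' @param datasets List of datasets containing the held-out one.
#' @param M,platforms As elsewhere.
#' @param held_out_id \code{dataset_id} to evaluate on.
#' @return A list: \code{improved_accuracy}, \code{defective} (data frame:
#'   removed_gene, accuracy), \code{mean_defective_accuracy}.
#' @export
defective_test <- function(clm, datasets, M, platforms, held_out_id) {
  k <- nrow(clm$EI)
  if (k < 2L) stop("defective test needs a panel of >= 2 biomarkers")
  ids <- vapply(datasets, `[[`, character(1L), "dataset_id")
  test <- datasets[[which(ids == held_out_id)]]
  full <- loocv_accuracy(test, clm$EI, M, platforms)
  acc <- vapply(seq_len(k), function(j)
    loocv_accuracy(test, clm$EI[-j, , drop = FALSE], M,
                   platforms)$accuracy,
    numeric(1L))
  list(improved_accuracy = full$accuracy,
       defective = data.frame(removed_gene = clm$EI$gene_id,
                              accuracy = acc, stringsAsFactors = FALSE),
       mean_defective_accuracy = mean(acc))
}
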