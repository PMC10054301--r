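# Nearest-centroid ripening-stage classifier.
#
# Deliberately simple and fully specified: features are standardized by their
# global median and interquartile range, each stage gets the mean of its
# standardized rows as centroid, and rows are assigned to the nearest centroid
# in Euclidean distance. Deterministic, dependency-free, and serializable.

#' Fit a nearest-centroid stage model
#'
#' Standardizes each feature by its global median and IQR (a feature with zero
#' IQR gets scale 1 and is flagged), then takes the per-stage mean of the
#' standardized features as that stage's centroid. Standardization makes the
#' classifier invariant to any affine rescaling of a raw feature.
#'
#' @param features A feature data frame (from [extract_features()] or
#'   [cohort_features()]) with a non-missing `stage` column; at least 2 stages
#'   and at least 2 rows per stage.
#' @param feature_cols Feature columns to use (default all six).
#' @return An object of class `centroid_model`: feature names, centers,
#'   scales, flagged degenerate features and the per-stage centroid matrix.
#' @export
fit_centroids <- function(features, feature_cols = feature_names()) {
  if (!is.data.frame(features) || !"stage" %in% names(features)) {
    stop_electrome("invalid_input", "features must have a stage column")
  }
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols) > 0L) {
    stop_electrome("feature_mismatch",
                   sprintf("missing feature column(s): %s",
                           paste(missing_cols, collapse = ", ")))
  }
  rows <- features[!is.na(features$stage), , drop = FALSE]
  x <- as.matrix(rows[, feature_cols, drop = FALSE])
  if (!all(is.finite(x))) {
    stop_electrome("nonfinite_input", "features contain non-finite values")
  }
  tab <- table(rows$stage)
  if (length(tab) < 2L) {
    stop_electrome("invalid_input", "need at least 2 stages to fit a model")
  }
  if (any(tab < 2L)) {
    bad <- names(tab)[tab < 2L][1L]
    stop_electrome("invalid_input",
                   sprintf("stage %s has fewer than 2 rows", bad))
  }
  center <- apply(x, 2L, stats::median)
  iqr <- apply(x, 2L, stats::IQR)
  flagged <- feature_cols[iqr == 0]
  scale <- ifelse(iqr > 0, iqr, 1)
  z <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  stages <- intersect(stage_levels(), unique(rows$stage))
  centroids <- do.call(rbind, lapply(stages, function(st) {
    colMeans(z[rows$stage == st, , drop = FALSE])
  }))
  rownames(centroids) <- stages
  colnames(centroids) <- feature_cols
  structure(
    list(features = feature_cols, center = center, scale = scale,
         flagged = flagged, centroids = centroids, stages = stages),
    class = "centroid_model"
  )
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("<centroid_model> stages %s over features %s\n",
              paste(x$stages, collapse = ", "),
              paste(x$features, collapse = ", ")))
  if (length(x$flagged) > 0L) {
    cat(sprintf("  degenerate (IQR = 0) features kept at scale 1: %s\n",
                paste(x$flagged, collapse = ", ")))
  }
  invisible(x)
}

#' Classify windows by nearest stage centroid
#'
#' Standardizes the rows with the model's centers and scales and assigns each
#' to the stage of the nearest centroid (Euclidean distance in standardized
#' space); ties break toward the earlier stage in canonical ripening order.
#' When the table carries stage labels, a confusion matrix and accuracy are
#' reported.
#'
#' @param model A [centroid_model][fit_centroids].
#' @param features A feature data frame with the model's feature columns.
#' @return An object of class `stage_classification`: `predictions` (the
#'   input with a `predicted_stage` column), plus `confusion` and `accuracy`
#'   when true labels are present (`NULL` otherwise).
#' @export
classify_stages <- function(model, features) {
  if (!inherits(model, "centroid_model")) {
    stop_electrome("invalid_input", "model must be a centroid_model")
  }
  missing_cols <- setdiff(model$features, names(features))
  if (length(missing_cols) > 0L) {
    stop_electrome("feature_mismatch",
                   sprintf("feature table lacks model feature(s): %s",
                           paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(features[, model$features, drop = FALSE])
  if (!all(is.finite(x))) {
    stop_electrome("nonfinite_input", "features contain non-finite values")
  }
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  # Centroid rows are already in canonical stage order, so which.min's
  # earliest-tie rule implements the canonical tie-break.
  d2 <- vapply(seq_len(nrow(model$centroids)), function(k) {
    rowSums(sweep(z, 2L, model$centroids[k, ])^2)
  }, numeric(nrow(z)))
  d2 <- matrix(d2, nrow = nrow(z))
  pred <- model$stages[apply(d2, 1L, which.min)]
  out <- features
  out$predicted_stage <- pred
  confusion <- NULL
  accuracy <- NULL
  if ("stage" %in% names(features) && !all(is.na(features$stage))) {
    truth <- features$stage
    keep <- !is.na(truth)
    confusion <- table(truth = factor(truth[keep], levels = model$stages),
                       predicted = factor(pred[keep], levels = model$stages))
    accuracy <- mean(pred[keep] == truth[keep])
  }
  structure(list(predictions = out, confusion = confusion,
                 accuracy = accuracy),
            class = "stage_classification")
}

#' @export
print.stage_classification <- function(x, ...) {
  cat(sprintf("<stage_classification> %d rows", nrow(x$predictions)))
  if (!is.null(x$accuracy)) {
    cat(sprintf(", accuracy %.3f\n", x$accuracy))
    print(x$confusion)
  } else cat("\n")
  invisible(x)
}

#' Serialize / restore a centroid model as JSON
#'
#' @param model A `centroid_model`.
#' @param path Output (or input) JSON path.
#' @return `write_centroid_model()` returns `path` invisibly;
#'   `read_centroid_model()` returns the model.
#' @export
write_centroid_model <- function(model, path) {
  if (!inherits(model, "centroid_model")) {
    stop_electrome("invalid_input", "model must be a centroid_model")
  }
  payload <- list(features = model$features,
                  center = as.list(stats::setNames(model$center, model$features)),
                  scale = as.list(stats::setNames(model$scale, model$features)),
                  flagged = model$flagged,
                  stages = model$stages,
                  centroids = stats::setNames(
                    lapply(model$stages, function(st) {
                      as.numeric(model$centroids[st, ])
                    }), model$stages))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_centroid_model
#' @export
read_centroid_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.character(p$features)
  centroids <- do.call(rbind, lapply(p$stages, function(st) {
    as.numeric(p$centroids[[st]])
  }))
  rownames(centroids) <- p$stages
  colnames(centroids) <- feats
  structure(
    list(features = feats,
         center = stats::setNames(as.numeric(p$center[feats]), feats),
         scale = stats::setNames(as.numeric(p$scale[feats]), feats),
         flagged = as.character(p$flagged),
         centroids = centroids,
         stages = as.character(p$stages)),
    class = "centroid_model"
  )
}
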