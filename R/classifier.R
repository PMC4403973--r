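#' Pearson VII universal kernel
#'
#' `K(x, y) = 1 / (1 + (2 * sqrt(2^(1/omega) - 1) * ||x - y|| / sigma)^2)^omega`.
#' The kernel is 1 at zero distance, strictly decreasing in `||x - y||`,
#' and interpolates between Gaussian-like and Lorentzian-like shapes as
#' `omega` varies.
#'
#' @param x,y Equal-length numeric vectors.
#' @param omega,sigma Positive shape and width parameters.
#' @return Kernel value in (0, 1].
#' @export
puk_kernel <- function(x, y, omega = 1, sigma = 1) {
  if (omega <= 0 || sigma <= 0) stop("omega and sigma must be positive")
  if (length(x) != length(y)) stop("vectors must have equal length")
  d <- sqrt(sum((x - y)^2))
  1 / (1 + (2 * sqrt(2^(1 / omega) - 1) * d / sigma)^2)^omega
}

# PUK kernel matrix between the rows of X and Y.
puk_matrix <- function(X, Y, omega = 1, sigma = 1) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  1 / (1 + (4 * (2^(1 / omega) - 1) * d2 / sigma^2))^omega
}

error_classes <- c("clean", "insertion", "deletion", "substitution")

#' Build balanced training and held-out evaluation sets
#'
#' Labelled instances are dereplicated on exact (feature vector, label)
#' equality, split stratified-by-label into subset A (training) and subset B
#' (held-out) at a 1:9 ratio, and subset A is then rebalanced by uniform
#' random selection without replacement to the requested per-class counts
#' (default 132 per error type and 700 clean). When a class has fewer
#' instances than its target, all targets are scaled down proportionally
#' with a warning. Subset B keeps the native class ratio.
#'
#' @param instances Data.frame with the 13 attribute columns plus `label`.
#' @param balance Named integer vector of subset-A class targets.
#' @param a_fraction Fraction of each class assigned to subset A before
#'   balancing (1:9 split).
#' @param seed Integer seed for the split and the balancing draws.
#' @return List of class `training_sets`: `subset_a`, `subset_b`
#'   (data.frames), `native_clean_error_ratio`, `seed`.
#' @export
prepare_training_sets <- function(instances,
                                  balance = c(insertion = 132L,
                                              deletion = 132L,
                                              substitution = 132L,
                                              clean = 700L),
                                  a_fraction = 0.1, seed = 1L) {
  missing_cls <- setdiff(error_classes, unique(instances$label))
  if (length(missing_cls))
    stop("class absent from instances: ", paste(missing_cls, collapse = ", "))
  key <- do.call(paste, c(instances[c(feature_columns(), "label")],
                          sep = "\r"))
  derep <- instances[!duplicated(key), , drop = FALSE]

  n_err <- sum(derep$label != "clean")
  n_clean <- sum(derep$label == "clean")
  native_ratio <- n_clean / n_err

  set.seed(seed)
  in_a <- logical(nrow(derep))
  for (cls in unique(derep$label)) {
    idx <- which(derep$label == cls)
    n_a <- max(1L, round(length(idx) * a_fraction))
    in_a[sample(idx, n_a)] <- TRUE
  }
  subset_a <- derep[in_a, , drop = FALSE]
  subset_b <- derep[!in_a, , drop = FALSE]

  avail <- table(subset_a$label)[names(balance)]
  avail[is.na(avail)] <- 0L
  scale <- min(1, as.numeric(avail) / as.numeric(balance))
  if (scale < 1) {
    warning("subset A smaller than balance targets; scaling targets by ",
            signif(scale, 3), call. = FALSE)
    balance <- stats::setNames(pmax(1L, as.integer(floor(balance * scale))),
                               names(balance))
  }
  pick <- unlist(lapply(names(balance), function(cls) {
    idx <- which(subset_a$label == cls)
    sample(idx, min(balance[[cls]], length(idx)))
  }))
  subset_a <- subset_a[sort(pick), , drop = FALSE]
  rownames(subset_a) <- rownames(subset_b) <- NULL

  structure(list(subset_a = subset_a, subset_b = subset_b,
                 native_clean_error_ratio = native_ratio,
                 seed = as.integer(seed)),
            class = "training_sets")
}

#' Train the per-position error classifier (SVM, PUK kernel)
#'
#' Features are one-hot encoded (homopolymer codes over their 9 levels) and
#' min--max normalized to [0, 1] with statistics frozen from subset A. A
#' one-vs-one soft-margin SVM is trained for every pair of the four classes
#' by sequential minimal optimization (via \pkg{kernlab}) on the PUK kernel
#' matrix; each binary machine's support vectors, dual coefficients and
#' offset are extracted into a plain, serializable model, and all
#' predictions are computed from that support set (pairwise voting with a
#' deterministic tie-break in the order clean < insertion < deletion <
#' substitution).
#'
#' @param sets A `training_sets` object from [prepare_training_sets].
#' @param omega,sigma PUK kernel parameters.
#' @param C Soft-margin cost.
#' @return Object of class `error_classifier`.
#' @export
train_error_classifier <- function(sets, omega = 1, sigma = 1, C = 1) {
  df <- sets$subset_a
  if (!nrow(df)) stop("empty training set")
  X <- encode_features(df)
  cmin <- apply(X, 2, min)
  cmax <- apply(X, 2, max)
  rng <- cmax - cmin
  rng[rng == 0] <- 1
  Xn <- sweep(sweep(X, 2, cmin), 2, rng, "/")
  y <- df$label

  present <- error_classes[error_classes %in% unique(y)]
  pair_idx <- utils::combn(present, 2, simplify = FALSE)
  pairs <- lapply(pair_idx, function(pr) {
    rows <- which(y %in% pr)
    Xp <- Xn[rows, , drop = FALSE]
    yp <- factor(y[rows], levels = pr)
    K <- puk_matrix(Xp, Xp, omega, sigma)
    m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yp,
                       type = "C-svc", C = C)
    svi <- kernlab::alphaindex(m)[[1]]
    co <- kernlab::coef(m)[[1]]
    bb <- kernlab::b(m)
    dec <- as.numeric(K[, svi, drop = FALSE] %*% co - bb)
    fit <- as.character(kernlab::fitted(m))
    # orient the sign of the decision function against kernlab's labels
    agree <- mean((dec > 0) == (fit == pr[1]))
    if (agree >= 0.5) {
      class_pos <- pr[1]; class_neg <- pr[2]
    } else {
      class_pos <- pr[2]; class_neg <- pr[1]
    }
    list(class_pos = class_pos, class_neg = class_neg,
         sv = Xp[svi, , drop = FALSE], coef = co, b = bb,
         train_error = kernlab::error(m))
  })

  structure(list(pairs = pairs, omega = omega, sigma = sigma, C = C,
                 norm = list(min = cmin, range = rng),
                 feature_names = colnames(X), classes = error_classes,
                 version = "denoise454-classifier-1"),
            class = "error_classifier")
}

#' @export
print.error_classifier <- function(x, ...) {
  cat("<error_classifier> SVM with PUK kernel (omega=", x$omega,
      ", sigma=", x$sigma, ", C=", x$C, ")\n", sep = "")
  cat("  ", length(x$pairs), " one-vs-one machines over classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  nsv <- sum(vapply(x$pairs, function(p) nrow(p$sv), 0L))
  cat("  ", nsv, " support vectors, ", length(x$feature_names),
      " encoded features\n", sep = "")
  invisible(x)
}

# Normalize an encoded feature matrix with the model's frozen stats.
normalize_with_model <- function(model, X) {
  if (!identical(colnames(X), model$feature_names))
    stop("feature schema mismatch: expected ",
         length(model$feature_names), " encoded columns")
  Xn <- sweep(sweep(X, 2, model$norm$min), 2, model$norm$range, "/")
  Xn
}

#' Pairwise decision values of the classifier
#'
#' Evaluates each one-vs-one machine's decision function
#' `sum_i coef_i K(sv_i, x) - b` from the stored support set.
#'
#' @param model An `error_classifier`.
#' @param features Data.frame of raw features (13 attribute columns).
#' @return Numeric matrix, one column per class pair.
#' @export
decision_values <- function(model, features) {
  Xn <- normalize_with_model(model, encode_features(features))
  # evaluate in row blocks to bound the kernel-matrix memory footprint
  blocks <- split(seq_len(nrow(Xn)), ceiling(seq_len(nrow(Xn)) / 5000))
  out <- vapply(model$pairs, function(p) {
    unlist(lapply(blocks, function(ix) {
      as.numeric(puk_matrix(Xn[ix, , drop = FALSE], p$sv,
                            model$omega, model$sigma) %*% p$coef - p$b)
    }), use.names = FALSE)
  }, numeric(nrow(Xn)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(Xn))
  colnames(out) <- vapply(model$pairs,
                          function(p) paste(p$class_pos, p$class_neg,
                                            sep = "/"), "")
  out
}

#' Predict the error class of feature-table rows
#'
#' @param object An `error_classifier`.
#' @param newdata Data.frame of raw features (13 attribute columns).
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.error_classifier <- function(object, newdata, ...) {
  dec <- decision_values(object, newdata)
  votes <- matrix(0L, nrow(dec), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (k in seq_along(object$pairs)) {
    p <- object$pairs[[k]]
    winner <- ifelse(dec[, k] > 0, p$class_pos, p$class_neg)
    ij <- cbind(seq_len(nrow(dec)), match(winner, object$classes))
    votes[ij] <- votes[ij] + 1L
  }
  object$classes[max.col(votes, ties.method = "first")]
}

#' Evaluate the classifier on a held-out labelled set
#'
#' Collapses the four classes to a binary error/clean call (any error class
#' is a positive) and reports sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and the full 4x4 confusion matrix.
#'
#' @param model An `error_classifier`.
#' @param subset_b Labelled data.frame (feature columns + `label`).
#' @return List: `sensitivity`, `specificity`, `confusion` (true x
#'   predicted).
#' @export
evaluate_classifier <- function(model, subset_b) {
  if (!nrow(subset_b)) stop("empty evaluation set")
  pred <- predict(model, subset_b)
  truth <- subset_b$label
  confusion <- table(factor(truth, levels = error_classes),
                     factor(pred, levels = error_classes),
                     dnn = c("true", "predicted"))
  tp <- sum(truth != "clean" & pred != "clean")
  fn <- sum(truth != "clean" & pred == "clean")
  tn <- sum(truth == "clean" & pred == "clean")
  fp <- sum(truth == "clean" & pred != "clean")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       confusion = confusion)
}

#' Flag likely-erroneous positions on new reads
#'
#' Extracts features, normalizes with the model's frozen statistics and
#' classifies every position; any non-clean prediction enters the read's
#' mask set.
#'
#' @param model An `error_classifier`.
#' @param reads List of basic-trimmed [flow_read] objects.
#' @return Named list mapping read id to an integer vector of flagged
#'   1-based positions.
#' @export
predict_mask <- function(model, reads) {
  feats <- extract_features_set(reads)
  pred <- predict(model, feats)
  flagged <- pred != "clean"
  out <- lapply(split(feats$position[flagged],
                      factor(feats$read_id[flagged],
                             levels = vapply(reads, function(r) r$read_id, ""))),
                as.integer)
  names(out) <- vapply(reads, function(r) r$read_id, "")
  out
}

#' Serialize an error classifier to a versioned JSON document
#'
#' @param model An `error_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  doc <- list(
    version = model$version, omega = model$omega, sigma = model$sigma,
    C = model$C, feature_names = model$feature_names,
    classes = model$classes,
    norm = list(min = unname(model$norm$min), range = unname(model$norm$range)),
    pairs = lapply(model$pairs, function(p) list(
      class_pos = p$class_pos, class_neg = p$class_neg,
      b = p$b, coef = p$coef, n_sv = nrow(p$sv),
      sv = as.numeric(t(p$sv))
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized error classifier
#'
#' @param path Path to a JSON model written by [write_classifier].
#' @return An `error_classifier` giving predictions identical to the saved
#'   model.
#' @export
read_classifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$version, "denoise454-classifier-1"))
    stop("unrecognized classifier model version in ", path)
  nf <- length(doc$feature_names)
  pairs <- lapply(seq_len(nrow(doc$pairs)), function(i) {
    p <- doc$pairs[i, ]
    sv <- matrix(unlist(p$sv), ncol = nf, byrow = TRUE)
    colnames(sv) <- doc$feature_names
    list(class_pos = p$class_pos, class_neg = p$class_neg,
         sv = sv, coef = unlist(p$coef), b = p$b)
  })
  norm_min <- doc$norm$min
  norm_range <- doc$norm$range
  names(norm_min) <- names(norm_range) <- doc$feature_names
  structure(list(pairs = pairs, omega = doc$omega, sigma = doc$sigma,
                 C = doc$C,
                 norm = list(min = norm_min, range = norm_range),
                 feature_names = doc$feature_names, classes = doc$classes,
                 version = doc$version),
            class = "error_classifier")
}
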