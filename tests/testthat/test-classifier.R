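# PUK kernel, balanced training sets, SVM training and masking

test_that("the PUK kernel obeys its closed forms", {
  set.seed(91)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(puk_kernel(x, x), 1)
  expect_equal(puk_kernel(x, y), puk_kernel(y, x))
  # at distance sigma / (2 sqrt(2^(1/omega) - 1)) with omega = 1: K = 1/2
  d <- 1 / (2 * sqrt(2^1 - 1))
  expect_equal(puk_kernel(c(0, 0), c(d, 0), omega = 1, sigma = 1), 0.5)
  # strictly decreasing in distance
  ds <- seq(0.1, 3, by = 0.1)
  ks <- vapply(ds, function(di) puk_kernel(0, di), 0)
  expect_true(all(diff(ks) < 0))
  expect_error(puk_kernel(x, y, omega = 0), "positive")
  expect_error(puk_kernel(x, c(y, 1)), "equal length")
})

test_that("the PUK Gram matrix is symmetric positive semidefinite", {
  set.seed(92)
  X <- matrix(rnorm(50 * 8), 50, 8)
  K <- denoise454:::puk_matrix(X, X, omega = 1, sigma = 1)
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(1, 50))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # matrix form agrees with the scalar kernel
  for (i in c(1, 7)) for (j in c(2, 50))
    expect_equal(K[i, j], puk_kernel(X[i, ], X[j, ]))
})

# Synthetic labelled instance table: the informative attributes (phred,
# flow intensity) are well separated per class; the remaining attributes
# are held essentially constant so the toy isolates the decision surface.
make_instances <- function(n_per_class, seed = 1) {
  set.seed(seed)
  centers <- list(clean = c(35, 1.0), insertion = c(8, 0.55),
                  deletion = c(12, 1.45), substitution = c(20, 0.75))
  rows <- lapply(names(centers), function(cls) {
    n <- n_per_class[[cls]]
    data.frame(
      position = sample(1:400, n, replace = TRUE),
      phred = as.integer(pmin(40, pmax(2, round(
        centers[[cls]][1] + rnorm(n, 0, 1.5))))),
      homopolymer_code = "N",
      carry_forward = FALSE,
      flow_intensity = centers[[cls]][2] + rnorm(n, 0, 0.03),
      prev_phred = 30L,
      prev_homopolymer_code = "N",
      prev_flow_intensity = 1.0,
      prev_max_uncalled = 0.1,
      next_phred = 30L,
      next_homopolymer_code = "N",
      next_flow_intensity = 1.0,
      next_max_uncalled = 0.1,
      label = cls,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

test_that("prepare_training_sets balances subset A to the exact targets", {
  inst <- make_instances(list(clean = 30000, insertion = 1500,
                              deletion = 1500, substitution = 1500),
                         seed = 93)
  sets <- prepare_training_sets(inst, seed = 94)
  tab <- table(sets$subset_a$label)
  expect_equal(as.integer(tab[c("insertion", "deletion", "substitution")]),
               c(132L, 132L, 132L))
  expect_equal(as.integer(tab["clean"]), 700L)
  # A and B are disjoint on exact feature-vector identity
  key <- function(df) do.call(paste, df[feature_columns()])
  expect_length(intersect(key(sets$subset_a), key(sets$subset_b)), 0)
  # determinism
  sets2 <- prepare_training_sets(inst, seed = 94)
  expect_identical(sets$subset_a, sets2$subset_a)
  expect_identical(sets$subset_b, sets2$subset_b)
})

test_that("prepare_training_sets reports the native ratio and guards inputs", {
  inst <- make_instances(list(clean = 4000, insertion = 40, deletion = 30,
                              substitution = 30), seed = 95)
  sets <- suppressWarnings(prepare_training_sets(inst, seed = 96))
  expect_equal(sets$native_clean_error_ratio,
               sum(!duplicated(do.call(paste, inst[c(feature_columns(),
                                                     "label")])) &
                     inst$label == "clean") /
                 sum(!duplicated(do.call(paste, inst[c(feature_columns(),
                                                       "label")])) &
                       inst$label != "clean"),
               tolerance = 1e-12)
  expect_warning(prepare_training_sets(inst, seed = 96), "scaling")
  expect_error(prepare_training_sets(inst[inst$label != "deletion", ]),
               "deletion")
})

test_that("training separates a linearly separable toy exactly", {
  inst <- make_instances(list(clean = 900, insertion = 200, deletion = 200,
                              substitution = 200), seed = 97)
  sets <- suppressWarnings(prepare_training_sets(inst, seed = 98))
  model <- train_error_classifier(sets)
  pred <- predict(model, sets$subset_a)
  expect_gte(mean(pred == sets$subset_a$label), 0.97)
  # binary collapse on held-out data is near perfect for separated classes
  ev <- evaluate_classifier(model, sets$subset_b)
  expect_gte(ev$sensitivity, 0.95)
  expect_gte(ev$specificity, 0.95)
  # sensitivity/specificity equal hand-computed values from the confusion
  cm <- ev$confusion
  tp <- sum(cm[-1, -1]); fn <- sum(cm[-1, 1])
  tn <- cm[1, 1]; fp <- sum(cm[1, -1])
  expect_equal(ev$sensitivity, tp / (tp + fn))
  expect_equal(ev$specificity, tn / (tn + fp))
})

test_that("decision values equal a brute-force kernel sum over the support set", {
  inst <- make_instances(list(clean = 300, insertion = 80, deletion = 80,
                              substitution = 80), seed = 99)
  sets <- suppressWarnings(prepare_training_sets(inst, seed = 100))
  model <- train_error_classifier(sets)
  test_rows <- sets$subset_b[1:25, ]
  dec <- decision_values(model, test_rows)
  Xn <- denoise454:::normalize_with_model(
    model, denoise454:::encode_features(test_rows))
  for (k in seq_along(model$pairs)) {
    p <- model$pairs[[k]]
    manual <- vapply(seq_len(nrow(Xn)), function(i) {
      acc <- 0
      for (s in seq_len(nrow(p$sv)))
        acc <- acc + p$coef[s] * puk_kernel(p$sv[s, ], Xn[i, ],
                                            model$omega, model$sigma)
      acc - p$b
    }, 0)
    expect_equal(unname(dec[, k]), manual, tolerance = 1e-10)
  }
})

test_that("serialization round-trips to identical predictions", {
  inst <- make_instances(list(clean = 300, insertion = 80, deletion = 80,
                              substitution = 80), seed = 101)
  sets <- suppressWarnings(prepare_training_sets(inst, seed = 102))
  model <- train_error_classifier(sets)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(model, path)
  model2 <- read_classifier(path)
  expect_identical(predict(model2, sets$subset_b),
                   predict(model, sets$subset_b))
  expect_equal(decision_values(model2, sets$subset_b[1:10, ]),
               decision_values(model, sets$subset_b[1:10, ]))
  # version guard
  doc <- jsonlite::read_json(path)
  doc$version <- "other"
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_classifier(path), "version")
})

test_that("retraining on the same data gives identical predictions", {
  inst <- make_instances(list(clean = 300, insertion = 80, deletion = 80,
                              substitution = 80), seed = 103)
  sets <- suppressWarnings(prepare_training_sets(inst, seed = 104))
  m1 <- train_error_classifier(sets)
  m2 <- train_error_classifier(sets)
  expect_identical(predict(m1, sets$subset_b), predict(m2, sets$subset_b))
})

test_that("predict_mask flags in-range positions and rejects bad schemas", {
  sc <- get_scenario()
  reads <- sc$kept[1:40]
  lab <- label_reads(reads, sc$refs$records)
  sets <- suppressWarnings(prepare_training_sets(lab$instances, seed = 105))
  model <- train_error_classifier(sets)
  masks <- predict_mask(model, reads)
  expect_named(masks, vapply(reads, function(r) r$read_id, ""))
  for (i in seq_along(reads))
    expect_true(all(masks[[i]] >= 1 & masks[[i]] <= length(reads[[i]])))
  # schema mismatch
  bad <- model
  bad$feature_names <- bad$feature_names[-1]
  expect_error(predict(bad, lab$instances[1:5, ]), "schema")
})
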