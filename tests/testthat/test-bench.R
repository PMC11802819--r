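test_that("subject-dependent splits stratify classes exactly", {
  ds <- balanced_epochs(k = 48L, n_subjects = 1L)
  sp <- split_subject_dependent(ds, 1L, test_frac = 0.25, seed = 1L)
  expect_equal(unname(table(ds$labels[sp$test])), rep(12L, 4L),
               ignore_attr = TRUE)
  # train and test proportions agree within one trial per class
  tr_tab <- table(factor(ds$labels[c(sp$train, sp$dev)], levels = 0:3))
  expect_true(all(abs(tr_tab / sum(tr_tab) - 0.25) < 1 / sum(tr_tab)))
  # determinism and disjointness
  sp2 <- split_subject_dependent(ds, 1L, test_frac = 0.25, seed = 1L)
  expect_identical(sp, sp2)
  expect_equal(anyDuplicated(c(sp$train, sp$dev, sp$test)), 0L)
  expect_true(all(ds$subjects[c(sp$train, sp$dev, sp$test)] == 1L))

  expect_error(split_subject_dependent(ds, 99L),
               class = "eegseek_validation_error")
  tiny <- subset_trials(ds, which(!(ds$labels == 3L))[1:50])
  expect_error(split_subject_dependent(tiny, 1L),
               class = "eegseek_validation_error")
})

test_that("subject-independent splits share no subject between train and test", {
  ds <- generate_epochs(synth_config(n_subjects = 5L, n_channels = 4L,
                                     sfreq = 64, epoch_seconds = 0.25,
                                     trials_per_class_range = c(6L, 8L),
                                     seed = 2L))
  sp <- split_subject_independent(ds, test_subjects = c(4L, 5L), seed = 9L)
  expect_setequal(unique(ds$subjects[sp$test]), c(4L, 5L))
  expect_true(length(intersect(unique(ds$subjects[c(sp$train, sp$dev)]),
                               c(4L, 5L))) == 0L)
  expect_equal(length(sp$train) + length(sp$dev) + length(sp$test),
               n_trials(ds))
  expect_error(split_subject_independent(ds, integer(0)),
               class = "eegseek_validation_error")
  expect_error(split_subject_independent(ds, 1:5),
               class = "eegseek_validation_error")
})

test_that("split JSON round trips", {
  ds <- generate_epochs(small_cfg())
  sp <- split_subject_independent(ds, 2L, seed = 4L)
  f <- withr::local_tempfile(fileext = ".json")
  write_split(sp, f)
  sp2 <- read_split(f)
  expect_equal(sp2$train, sp$train)
  expect_equal(sp2$dev, sp$dev)
  expect_equal(sp2$test, sp$test)
  expect_equal(sp2$mode, sp$mode)
})

test_that("accuracy is the fraction of correct predictions", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy(c(1, 2, 3, 0), c(1, 2, 0, 1)), 0.5)
  expect_equal(accuracy(0L, 1L), 0)
  expect_error(accuracy(1:3, 1:2), class = "eegseek_validation_error")
  # uniform-random 4-class prediction hovers at chance
  set.seed(1)
  accs <- vapply(1:6, function(i) {
    accuracy(sample(0:3, 4000, replace = TRUE),
             sample(0:3, 4000, replace = TRUE))
  }, numeric(1))
  expect_equal(mean(accs), 0.25, tolerance = 0.03)
})

test_that("the benchmark grid is complete, flagged, and at chance for a dummy", {
  ds <- generate_epochs(small_cfg(seed = 6L))
  failing_model <- list(name = "Broken",
                        fit = function(train, dev, seed) stop("boom"))
  grid <- run_benchmark(
    ds, list(majority_class_model(), single_tree_model(), failing_model),
    methods = c("raw", "csp_pair"), mode = "subject_dependent", seed = 5L)
  expect_equal(nrow(grid), 3L * 2L * 2L)     # models x methods x subjects
  expect_true(all(grid$status[grid$model == "Broken"] != "ok"))
  expect_true(all(grid$status[grid$model != "Broken"] == "ok"))
  # balanced test set -> majority-class accuracy ~ 1/4 (exact when counts tie
  # to class 0; here within one trial of balance)
  maj <- grid$test_acc[grid$model == "MajorityClass"]
  expect_true(all(maj >= 0.1 & maj <= 0.45))
  expect_s3_class(summarize_grid(grid), "tbl_df")
  expect_equal(nrow(summarize_grid(grid)), 4L)  # failed cells dropped
})

test_that("identical master seeds give byte-identical CSV output", {
  ds <- generate_epochs(small_cfg(seed = 8L))
  models <- list(single_tree_model(), majority_class_model())
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  g1 <- run_benchmark(ds, models, methods = "csp_ova", seed = 11L)
  g2 <- run_benchmark(ds, models, methods = "csp_ova", seed = 11L)
  write_results_csv(g1, f1)
  write_results_csv(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different master seed changes the grid
  g3 <- run_benchmark(ds, models, methods = "csp_ova", seed = 12L)
  expect_false(identical(g1$test_acc, g3$test_acc))
  # metadata carries provenance for reproduction
  expect_identical(attr(g1, "dataset_hash"), rlang::hash(ds))
  expect_identical(attr(g1, "master_seed"), 11L)
})

test_that("per-subject CSV layout mirrors the subject-by-method heatmap", {
  ds <- generate_epochs(small_cfg(seed = 9L))
  g <- run_benchmark(ds, list(single_tree_model()), methods = "raw",
                     seed = 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(g, f, by = "subject")
  got <- utils::read.csv(f)
  expect_identical(names(got),
                   c("axis1", "axis2", "train_acc", "test_acc", "status",
                     "seed"))
  expect_equal(nrow(got), 2L)
  p <- autoplot(g)
  expect_s3_class(p, "ggplot")
})

test_that("nothing fitted reads development or test rows", {
  ds <- generate_epochs(small_cfg(seed = 13L))
  sp <- split_subject_dependent(ds, 1L, seed = 3L)
  perturbed <- ds
  perturbed$data[sp$test, , ] <- perturbed$data[sp$test, , ] * 3 + 1

  for (method in c("pca", "ica", "csp_pair")) {
    a <- featurize_split(ds, method, sp)
    b <- featurize_split(perturbed, method, sp)
    expect_identical(a$fits, b$fits)
    expect_identical(a$train$values, b$train$values)
    # but the pipelines do see the perturbation where they should
    expect_false(identical(a$test$values, b$test$values))
  }
  a <- featurize_split(ds, "csp_pair", sp)
  b <- featurize_split(perturbed, "csp_pair", sp)
  nza <- normalize_fit(a$train)
  nzb <- normalize_fit(b$train)
  expect_identical(nza, nzb)
  ra <- brute_fit(normalize_apply(nza, a$train), normalize_apply(nza, a$dev),
                  m = 20L, seed0 = 0L, audit = FALSE)
  rb <- brute_fit(normalize_apply(nzb, b$train), normalize_apply(nzb, b$dev),
                  m = 20L, seed0 = 0L, audit = FALSE)
  expect_identical(ra$best_seed, rb$best_seed)

  # sentinel: fitting on train+test must change the fitted transformer
  leaky <- split_subject_dependent(ds, 1L, seed = 3L)
  leaky$train <- c(leaky$train, leaky$test)
  leaky$test <- leaky$dev[1]                # keep spec nonempty
  c <- featurize_split(ds, "pca", sp)
  d <- featurize_split(ds, "pca", leaky)
  expect_false(identical(c$fits$pca$rotation, d$fits$pca$rotation))
})
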