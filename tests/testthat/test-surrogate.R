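# Surrogate stage: table assembly, LOOCV, permutation importance.

fake_estimate <- function(t_end, no_crossing = FALSE) {
  structure(list(t_end = t_end, no_crossing = no_crossing,
                 crossed_in_observed = FALSE),
            class = "endpoint_estimate")
}

test_that("assemble_table keeps resolved runs and logs exclusions", {
  runs <- lapply(1:12, function(i) {
    list(params = material_process_params(rpm = 10 + i),
         estimate = fake_estimate(100 / i, no_crossing = i > 10),
         provenance = "synthetic")
  })
  # only rpm varies in this fixture, so the zero-variance warning is expected
  expect_message(tab <- suppressWarnings(assemble_table(runs)),
                 "2 run\\(s\\) without")
  expect_equal(nrow(tab), 10)
  expect_equal(attr(tab, "n_excluded"), 2)
  expect_true(all(descriptor_names() %in% names(tab)))
  ds <- attr(tab, "design_summary")
  expect_equal(ds$min[ds$descriptor == "rpm"], 11)
})

test_that("zero-variance descriptors trigger a named warning", {
  runs <- lapply(1:10, function(i)
    list(params = material_process_params(), estimate = fake_estimate(i)))
  expect_warning(assemble_table(runs), "particle_radius")
})

test_that("feature tables round-trip through CSV", {
  tab <- synthetic_design_table(n_rows = 15, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(back$t_end_s, tab$t_end_s)
  expect_equal(back$cake_height, tab$cake_height)
  expect_equal(back$provenance, tab$provenance)
})

test_that("a noiseless linear response is recovered exactly by the elastic net", {
  tab <- synthetic_design_table(n_rows = 40, response = "linear",
                                noise_sd = 0, seed = 5)
  rep <- fit_and_crossvalidate(tab, methods = "elastic_net", seed = 1)
  expect_gt(rep$methods$elastic_net$r_squared, 0.99)
})

test_that("LOOCV is honest: no method scores a pure-noise response", {
  tab <- synthetic_design_table(n_rows = 40, response = "noise",
                                noise_sd = 1, seed = 6)
  rep <- fit_and_crossvalidate(tab, seed = 2, tune = small_tune())
  for (m in names(rep$methods)) {
    expect_false(rep$methods[[m]]$skipped)
    expect_lte(rep$methods[[m]]$r_squared, 0.2)
  }
})

test_that("every LOOCV fold provably excludes its own row", {
  tab <- synthetic_design_table(n_rows = 12, response = "linear", seed = 7)
  rep <- fit_and_crossvalidate(tab, methods = "elastic_net", seed = 3)
  rows <- rep$methods$elastic_net$fold_train_rows
  expect_length(rows, 12)
  for (i in seq_along(rows)) {
    expect_false(i %in% rows[[i]])
    expect_length(rows[[i]], 11)
  }
})

test_that("constant responses are skipped with a reason", {
  tab <- synthetic_design_table(n_rows = 12, response = "noise",
                                noise_sd = 0, seed = 8)
  tab$t_end_s <- 5
  rep <- fit_and_crossvalidate(tab, methods = "rf", seed = 1,
                               tune = small_tune())
  expect_true(rep$methods$rf$skipped)
  expect_match(rep$methods$rf$reason, "constant")
})

test_that("reports are reproducible under a fixed master seed", {
  tab <- synthetic_design_table(n_rows = 14, response = "linear",
                                noise_sd = 0.5, seed = 9)
  r1 <- fit_and_crossvalidate(tab, methods = c("rf", "svr"), seed = 11,
                              tune = small_tune())
  r2 <- fit_and_crossvalidate(tab, methods = c("rf", "svr"), seed = 11,
                              tune = small_tune())
  expect_identical(r1$methods$rf$loocv_predictions,
                   r2$methods$rf$loocv_predictions)
  expect_identical(r1$methods$svr$loocv_predictions,
                   r2$methods$svr$loocv_predictions)
})

test_that("rf predictions are invariant under monotone descriptor rescaling", {
  tab <- synthetic_design_table(n_rows = 20, response = "ranking",
                                noise_sd = 0.3, seed = 10)
  X <- as.matrix(tab[descriptor_names()])
  y <- tab$t_end_s
  fit1 <- granumix:::with_local_seed(5,
    randomForest::randomForest(x = X, y = y, ntree = 200))
  X2 <- X
  X2[, "cake_height"] <- X2[, "cake_height"]^3  # strictly monotone on > 0
  fit2 <- granumix:::with_local_seed(5,
    randomForest::randomForest(x = X2, y = y, ntree = 200))
  # split memberships are preserved under a monotone transform; tiny
  # floating-point tie-breaks in the split search keep this from being exact
  p1 <- predict(fit1, X)
  p2 <- predict(fit2, X2)
  expect_lt(max(abs(p1 - p2)) / diff(range(y)), 0.02)
  expect_gt(cor(p1, p2), 0.999)
})

test_that("descriptors absent from the generating function have importance near zero", {
  tab <- synthetic_design_table(n_rows = 40, response = "ranking",
                                noise_sd = 0.2, seed = 12)
  imp <- permutation_importance(tab, n_permutations = 15, seed = 2,
                                tune = small_tune())
  inert <- setdiff(descriptor_names(),
                   c("cake_height", "rpm", "particle_radius"))
  planted_min <- min(imp$importance[imp$descriptor %in%
                                      c("cake_height", "rpm")])
  for (nm in inert) {
    row <- imp[imp$descriptor == nm, ]
    # spurious small-sample correlations leave a little residue; inert
    # descriptors must sit far below the planted signals
    expect_lt(abs(row$importance), 0.25 * planted_min)
  }
})

test_that("a duplicated descriptor splits its importance with its copy", {
  tab <- synthetic_design_table(n_rows = 40, response = "ranking",
                                noise_sd = 0.2, seed = 13)
  imp0 <- permutation_importance(tab, n_permutations = 15, seed = 4,
                                 tune = small_tune())
  orig <- imp0$importance[imp0$descriptor == "cake_height"]

  tab2 <- tab
  tab2$cake_height_copy <- tab2$cake_height
  imp2 <- permutation_importance(tab2, n_permutations = 15, seed = 4,
                                 tune = small_tune())
  a <- imp2$importance[imp2$descriptor == "cake_height"]
  b <- imp2$importance[imp2$descriptor == "cake_height_copy"]
  # each copy matters less than the original alone; together they cover it
  expect_lt(max(a, b), orig)
  expect_gt(a + b, 0.3 * orig)
})

test_that("zero-variance descriptors get importance zero and a flag", {
  tab <- synthetic_design_table(n_rows = 20, response = "ranking",
                                noise_sd = 0.2, seed = 14)
  tab$density <- 1100
  imp <- permutation_importance(tab, n_permutations = 10, seed = 5,
                                tune = small_tune())
  row <- imp[imp$descriptor == "density", ]
  expect_equal(row$importance, 0)
  expect_true(row$zero_variance)
})

test_that("surrogate reports serialize to JSON", {
  tab <- synthetic_design_table(n_rows = 12, response = "linear", seed = 15)
  rep <- fit_and_crossvalidate(tab, methods = "elastic_net", seed = 1)
  rep$importances <- permutation_importance(tab, n_permutations = 10,
                                            seed = 1, tune = small_tune())
  f <- withr::local_tempfile(fileext = ".json")
  write_surrogate_report(rep, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$n_rows, 12)
  expect_length(js$methods$elastic_net$loocv_predictions, 12)
  expect_length(js$importances, 9)
})
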