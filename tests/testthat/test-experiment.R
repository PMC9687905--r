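test_that("stratified 4:1 splits preserve class proportions", {
  d <- density_family() # 60 + 60
  sp <- stratified_split(d, seed = 1)
  expect_length(sp$test, 24L)
  expect_length(sp$train, 96L)
  expect_equal(sort(c(sp$train, sp$test)), 1:120)
  expect_equal(as.numeric(table(d$labels[sp$test])), c(12, 12))

  ## a 40-member class yields 32 train / 8 test
  d40 <- graph_dataset(
    small_family()$graphs[rep(1:20, 4)][1:80],
    rep(c("x", "y"), each = 40)
  )
  sp40 <- stratified_split(d40, seed = 3)
  expect_equal(as.numeric(table(d40$labels[sp40$test])), c(8, 8))
  expect_equal(as.numeric(table(d40$labels[sp40$train])), c(32, 32))

  ## uneven classes: proportions within one graph of 4:1
  d37 <- graph_dataset(
    small_family()$graphs[rep(1:20, 4)][1:77],
    c(rep("x", 40), rep("y", 37))
  )
  sp37 <- stratified_split(d37, seed = 5)
  expect_equal(as.numeric(table(d37$labels[sp37$test])), c(8, 7))
})

test_that("splits are deterministic per seed and reject singleton classes", {
  d <- density_family()
  expect_identical(stratified_split(d, seed = 9), stratified_split(d, seed = 9))
  expect_false(identical(
    stratified_split(d, seed = 9)$test, stratified_split(d, seed = 10)$test
  ))
  bad <- graph_dataset(d$graphs[1:3], c("a", "a", "b"))
  expect_error(stratified_split(bad, seed = 1), class = "hb_data_error")
})

test_that("a one-point grid is returned as-is and tuning is seed-deterministic", {
  d <- small_family()
  t1 <- tune_hyperparams(d, grid = list(n_layers = 2L), epochs = 4, seed = 6)
  expect_equal(t1$n_layers, 2L)
  expect_equal(t1$lr, hb_hyperparams()$lr)
  t2 <- tune_hyperparams(d, grid = list(n_layers = 2L), epochs = 4, seed = 6)
  expect_identical(attr(t1, "cv_results"), attr(t2, "cv_results"))
  expect_equal(nrow(attr(t1, "cv_results")), 5L) # 1 combo x 5 folds
})

test_that("tuning selects the depth that the topology requires", {
  ## classes share all 1-hop statistics; only >= 2 layers can separate them
  d <- depth_family()
  tuned <- suppressWarnings(tune_hyperparams(
    d,
    grid = list(n_layers = c(1L, 3L)), epochs = 40, seed = 2, select = "mean"
  ))
  expect_equal(tuned$n_layers, 3L)
  cv <- attr(tuned, "cv_results")
  means <- tapply(cv$accuracy, cv$n_layers, mean)
  expect_lt(means[["1"]], 0.7)
  expect_gt(means[["3"]], 0.9)
})

test_that("small classes reduce the fold count with a warning", {
  d <- small_family()
  d4 <- graph_dataset(d$graphs[c(1:4, 11:14)], rep(c("a", "b"), each = 4))
  expect_warning(
    tune_hyperparams(d4, grid = list(n_layers = 1L), epochs = 2, seed = 1),
    "reducing folds"
  )
})

test_that("evaluation reports one row per split and self-consistent metrics", {
  d <- small_family()
  ev <- evaluate(d, hb_hyperparams(epochs = 8), n_splits = 3, seed = 4)
  expect_equal(nrow(tidy(ev)), 3L)
  expect_equal(tidy(ev)$split, 1:3)
  ## accuracy recomputed from stored confusion counts matches bit-exactly
  for (k in 1:3) {
    conf <- ev$confusions[[k]]
    expect_identical(tidy(ev)$accuracy[k], sum(diag(conf)) / sum(conf))
  }
  gl <- glance(ev)
  expect_equal(gl$accuracy_mean, mean(tidy(ev)$accuracy))
  expect_true(all(tidy(ev)$accuracy >= 0 & tidy(ev)$accuracy <= 1))
})

test_that("test partitions never overlap their training partitions", {
  d <- small_family()
  ev <- evaluate(d, hb_hyperparams(epochs = 2), n_splits = 4, seed = 8)
  for (spl in ev$splits) {
    expect_length(intersect(spl$train, spl$test), 0L)
    expect_setequal(c(spl$train, spl$test), seq_along(d$graphs))
  }
})

test_that("both concatenation modes run end-to-end", {
  d <- small_family()
  ev_cat <- evaluate(d, hb_hyperparams(epochs = 8), n_splits = 2, seed = 3)
  ev_last <- evaluate(d, hb_hyperparams(epochs = 8),
    n_splits = 2, seed = 3,
    concat = FALSE
  )
  expect_equal(nrow(tidy(ev_cat)), 2L)
  expect_equal(nrow(tidy(ev_last)), 2L)
  expect_false(ev_last$concat)
})
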