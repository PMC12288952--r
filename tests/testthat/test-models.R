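# shared desk-scale fixture: fully motif-separable windows
separable_fixture <- function(n_per_class = 150, L = 201, seed = 11) {
  generate_dataset(synth_config(n_pos = n_per_class, n_neg = n_per_class,
                                L = L, motif_prob_pos = 1, motif_prob_neg = 0,
                                seed = seed))
}

test_that("full-scale layer shapes match the published architecture exactly", {
  for (variant in c("SM", "HM", "DHM")) {
    shp <- model_shapes(model_spec(variant, L = 2001))
    get <- function(layer) shp$output_shape[[match(layer, shp$layer)]]
    expect_equal(get("input_onehot"), c(2001L, 4L))
    expect_equal(get("conv1"), c(2001L, 64L))
    expect_equal(get("maxpool1"), c(133L, 64L))
    expect_equal(get("conv2"), c(133L, 128L))
    expect_equal(get("maxpool2"), c(8L, 128L))
    expect_equal(get("flatten_cnn"), 1024L)
    expect_equal(get("dense_sigmoid"), 1L)
  }
  expect_equal(model_spec("SM")$concat_dim, 1024L)
  expect_equal(model_spec("HM")$concat_dim, 2048L)
  hm <- model_shapes(model_spec("HM", L = 2001))
  expect_equal(hm$output_shape[[match("concatenate", hm$layer)]], 2048L)
  dhm <- model_shapes(model_spec("DHM", L = 2001))
  expect_equal(dhm$output_shape[[match("dense_kmer", dhm$layer)]], 64L)
  expect_equal(dhm$output_shape[[match("concatenate", dhm$layer)]], 1088L)
})

test_that("the flatten width follows floor(floor(L/p)/p) * filters", {
  expect_equal(model_spec("SM", L = 2001)$flatten_dim,
               ((2001L %/% 15L) %/% 15L) * 128L)
  s <- model_spec_fast("SM")
  expect_equal(s$flatten_dim, ((201L %/% 5L) %/% 5L) * 32L)
})

test_that("degenerate length chains raise an architecture error", {
  expect_error(model_spec("SM", L = 201), "collapses to zero")
  expect_error(model_spec("SM", L = 23, pool_size = 15), "collapses to zero")
  expect_error(model_spec("SM", L = 2001, conv1_kernel = 24), "odd")
})

test_that("parameter count is a pure function of the spec", {
  m1 <- build_model(model_spec("DHM"))
  m2 <- build_model(model_spec("DHM"))
  expect_identical(m1$n_params, m2$n_params)
  expect_gt(build_model(model_spec("HM"))$n_params,
            build_model(model_spec("SM"))$n_params)
})

test_that("training is deterministic under a seed and aborts on bad domains", {
  ds <- separable_fixture(40, L = 51, seed = 3)
  fb <- encode_dataset(ds, scheme = "both", k = 2)
  spec <- model_spec_fast("SM", L = 51, kmer_k = 2)
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 42)
  f1 <- train_model(build_model(spec), fb, cfg)
  f2 <- train_model(build_model(spec), fb, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  f3 <- train_model(build_model(spec), fb, train_config(epochs = 2,
                                                        batch_size = 16,
                                                        seed = 43))
  expect_false(identical(f1$history$loss[1], f3$history$loss[1]))
  expect_error(train_config(epochs = 0), "at least 1")
})

test_that("shape mismatches are reported with expected vs received", {
  ds <- separable_fixture(10, L = 51, seed = 3)
  fb <- encode_dataset(ds, scheme = "both", k = 2)
  spec_wrong_L <- model_spec_fast("SM", L = 101, kmer_k = 2)
  expect_error(train_model(build_model(spec_wrong_L), fb, train_config(epochs = 1)),
               "expected \\(\\*, 101, 4\\)")
  spec_wrong_k <- model_spec_fast("HM", L = 51, kmer_k = 3)
  expect_error(train_model(build_model(spec_wrong_k), fb, train_config(epochs = 1)),
               "k-mer width mismatch")
  fb_oh <- encode_dataset(ds, scheme = "onehot")
  expect_error(train_model(build_model(model_spec_fast("HM", L = 51, kmer_k = 2)),
                           fb_oh, train_config(epochs = 1)),
               "needs k-mer features")
})

test_that("each variant learns the separable fixture and orders the classes", {
  ds <- separable_fixture(150, L = 201, seed = 21)
  fb <- encode_dataset(ds, scheme = "both", k = 3)
  plan <- random_split(ds, seed = 2)
  tr <- subset_features(fb, c(plan$folds$train[[1]], plan$folds$validation[[1]]))
  te <- subset_features(fb, plan$folds$test[[1]])
  for (variant in c("SM", "HM", "DHM")) {
    fit <- train_model(build_model(model_spec_fast(variant)), tr,
                       train_config_fast(seed = 7, epochs = 6))
    expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
    p <- predict(fit, te)
    expect_length(p, length(te$id))
    expect_true(all(p > 0 & p < 1))
    expect_gt(mean(p[te$label == 1]), mean(p[te$label == 0]))
  }
})

test_that("embedding taps expose the documented widths and guard variants", {
  ds <- separable_fixture(20, L = 51, seed = 9)
  fb <- encode_dataset(ds, scheme = "both", k = 2)
  cfg <- train_config(epochs = 1, batch_size = 16, seed = 1)
  sm <- train_model(build_model(model_spec_fast("SM", L = 51, kmer_k = 2)), fb, cfg)
  expect_equal(dim(extract_features(sm, fb, "cnn")),
               c(40L, sm$spec$flatten_dim))
  expect_error(extract_features(sm, fb, "fused"), "hybrid variant")
  expect_error(extract_features(sm, fb, "kmer_deep"), "DHM")
  hm <- train_model(build_model(model_spec_fast("HM", L = 51, kmer_k = 2)), fb, cfg)
  expect_equal(ncol(extract_features(hm, fb, "fused")), hm$spec$concat_dim)
  dhm <- train_model(build_model(model_spec_fast("DHM", L = 51, kmer_k = 2)), fb, cfg)
  expect_equal(ncol(extract_features(dhm, fb, "kmer_deep")), 64L)
  expect_equal(ncol(extract_features(dhm, fb, "kmer_raw")), 16L)
})

test_that("tidy/glance/checkpoint round-trip preserve the fit", {
  ds <- separable_fixture(15, L = 51, seed = 13)
  fb <- encode_dataset(ds, scheme = "onehot")
  fit <- train_model(build_model(model_spec_fast("SM", L = 51)), fb,
                     train_config(epochs = 3, batch_size = 8, seed = 5))
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_named(td, c("epoch", "loss"))
  gl <- glance(fit)
  expect_equal(gl$epochs, 3L)
  expect_equal(gl$variant, "SM")
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_equal(predict(back, fb), predict(fit, fb))
})
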