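test_that("sub-model configs carry the published architecture defaults", {
  m <- submodel_config("M")
  expect_identical(m$conv_kernel_sizes, c(3L, 5L))
  expect_identical(m$kernels_per_branch, 20L)
  expect_identical(m$recurrent_layers, 2L)
  expect_identical(m$recurrent_hidden, 25L)
  expect_identical(m$head_sizes, c(80L, 20L, 1L))
  d <- submodel_config("D")
  expect_identical(d$recurrent_layers, 1L)
  expect_identical(d$recurrent_hidden, 20L)
  expect_error(submodel_config("M", head_sizes = c(10L, 2L)), "head size")
})

test_that("embedding initialization is bit-exact and builds are seed-deterministic", {
  s <- tiny_training_setup()
  m1 <- build_submodel(s$small_cfg, s$mtp, seed = 11)
  expect_identical(m1$params$emb, unname(s$mtp$matrix))
  m2 <- build_submodel(s$small_cfg, s$mtp, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_submodel(s$small_cfg, s$mtp, seed = 12)
  expect_false(identical(m1$params, m3$params))
})

test_that("kind/prior pairing and DRICS normalization are enforced", {
  s <- tiny_training_setup()
  raw_drics <- build_drics_init(gen_prior_table("DRICS", 1), s$conv)
  expect_error(build_submodel(submodel_config("D"), raw_drics),
               "normalized")
  expect_error(build_submodel(submodel_config("D"), s$mtp), "requires")
  expect_error(build_submodel(submodel_config("M"), s$drics), "requires")
})

test_that("predictions are probabilities, batch-invariant and order-preserving", {
  s <- tiny_training_setup()
  model <- build_submodel(s$small_cfg, s$mtp, seed = 5)
  X <- s$tr$cols[1:40, ]
  p <- predict(model, X)
  expect_length(p, 40)
  expect_true(all(p > 0 & p < 1))
  # duplicated input -> identical outputs
  Xdup <- X[c(1, 1, 2), ]
  pd <- predict(model, Xdup)
  expect_identical(pd[1], pd[2])
  # single pair vs inside a batch
  p1 <- predict(model, X[1, , drop = FALSE])
  expect_equal(p1, p[1], tolerance = 1e-6)
  expect_error(predict(model, X[, 1:20]), class = "crispr_length_error")
})

test_that("mean fusion is the arithmetic mean with length checking", {
  expect_equal(ensemble_predict(c(0.2), c(0.4)), 0.3)
  expect_equal(ensemble_predict(c(1e-9, 1 - 1e-9), c(1 - 1e-9, 1e-9)),
               c(0.5, 0.5))
  x <- runif(5)
  expect_equal(ensemble_predict(x, x), x)
  expect_error(ensemble_predict(runif(3), runif(4)), "length")
})

test_that("ablated architectures strictly drop the removed block's parameters", {
  s <- tiny_training_setup()
  full <- build_submodel(submodel_config("M"), s$mtp, seed = 1)
  no_inc <- build_submodel(submodel_config("M", use_inception = FALSE),
                           s$mtp, seed = 1)
  no_rnn <- build_submodel(submodel_config("M", use_bilstm = FALSE),
                           s$mtp, seed = 1)
  expect_lt(n_parameters(no_inc), n_parameters(full))
  expect_lt(n_parameters(no_rnn), n_parameters(full))
  expect_false(any(grepl("^conv", names(no_inc$params))))
  expect_false(any(grepl("^W[xh]", names(no_rnn$params))))
  expect_error(submodel_config("M", use_inception = FALSE,
                               use_bilstm = FALSE), "ablated")
})

test_that("gradient reaches the embedding iff it is trainable", {
  s <- tiny_training_setup()
  X <- s$tr$cols[1:30, ]
  y <- s$tr$label[1:30]
  y[1:3] <- 1L  # both classes
  for (trainable in c(TRUE, FALSE)) {
    cfg <- submodel_config("M", kernels_per_branch = 4L,
                           recurrent_layers = 1L, recurrent_hidden = 6L,
                           head_sizes = c(8L, 1L),
                           embedding_trainable = trainable)
    model <- build_submodel(cfg, s$mtp, seed = 2)
    ccfg <- crisprembed:::.cpp_cfg(cfg, s$conv$L, 1)
    res <- crisprembed:::cpp_train_epoch(
      unname(model$params),
      lapply(unname(model$params), function(p) p * 0),
      lapply(unname(model$params), function(p) p * 0),
      0L, X, as.numeric(y), seq_len(nrow(X)), 16L, 1e-3, ccfg)
    emb_after <- res$params[[1]]
    if (trainable) {
      expect_false(identical(emb_after, unname(s$mtp$matrix)))
    } else {
      expect_identical(emb_after, unname(s$mtp$matrix))
    }
    # downstream weights always move
    expect_false(identical(res$params[[2]], unname(model$params)[[2]]))
  }
})
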