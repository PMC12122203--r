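test_that("class weights are reciprocal frequencies with min-class weight 1", {
  expect_equal(compute_class_weights(rep(c(1, 2), each = 7)), c(1, 1))
  expect_equal(compute_class_weights(rep(c(1, 2, 3), c(10, 5, 5))),
               c(0.5, 1, 1))
  expect_equal(compute_class_weights(rep(1, 4)), 1)
  # absent classes get neutral weight 1
  expect_equal(compute_class_weights(rep(3, 6), n_classes = 3), c(1, 1, 1))
  expect_error(compute_class_weights(integer(0)), "empty")
})

test_that("coordinate noise is zero-mean Gaussian with the requested sd", {
  x <- make_helix(10)
  expect_identical(add_coordinate_noise(x, 0), x)
  expect_error(add_coordinate_noise(x, -1), ">= 0")
  set.seed(99)
  big <- matrix(0, 34000, 3)
  draws <- add_coordinate_noise(big, 1.5)
  expect_equal(sd(draws), 1.5, tolerance = 0.02 / 1.5)
  set.seed(5); a <- add_coordinate_noise(x, 1)
  set.seed(5); b <- add_coordinate_noise(x, 1)
  expect_identical(a, b)
})

test_that("initialization: N(0, 1e-3) blocks, seeded determinism", {
  cfg <- toy_config()
  m <- initialize_model(cfg, fc_train_config(), seed = 31)
  ws <- unlist(lapply(m$blocks, function(b) unlist(b)))
  expect_gt(length(ws), 1e4)
  expect_equal(sd(ws), 1e-3, tolerance = 0.1)
  expect_lt(abs(mean(ws)), 1e-4)
  # heads use the fan-in-scaled uniform scheme
  expect_true(all(abs(m$heads$CAT$W) <= 1 / sqrt(cfg$embed_dim)))
  m2 <- initialize_model(cfg, fc_train_config(), seed = 31)
  expect_identical(m, m2)
  m3 <- initialize_model(cfg, fc_train_config(), seed = 32)
  expect_false(identical(m$blocks[[1]]$We1, m3$blocks[[1]]$We1))
})

test_that("loss at initialization is about log(n_classes) per head", {
  cfg <- toy_config()
  m <- initialize_model(cfg, fc_train_config(), seed = 41)
  tpl <- make_fold_templates(8, n_res = 20, seed = 6)
  data <- family_dataset(4, tpl, seed_base = 300)
  w <- list(C = rep(1, 2), CA = rep(1, 4), CAT = rep(1, 8))
  dl <- foldsearch:::dataset_loss(m, data, w)
  expect_equal(unname(dl$per_head["C"]), log(2), tolerance = 0.1)
  expect_equal(unname(dl$per_head["CA"]), log(4), tolerance = 0.1)
  expect_equal(unname(dl$per_head["CAT"]), log(8), tolerance = 0.1)
})

test_that("analytic backpropagation matches finite differences", {
  cfg <- fc_config(n_blocks = 2, node_dim = 4, hidden_dim = 5, out_dim = 6,
                   embed_dim = 4, n_classes = c(C = 2, CA = 3, CAT = 4),
                   max_len = 64)
  model <- initialize_model(cfg, fc_train_config(egnn_init_sd = 0.05),
                            seed = 9)
  set.seed(3)
  coords <- list(matrix(rnorm(15), 5, 3) * 5, matrix(rnorm(21), 7, 3) * 5)
  labels <- rbind(c(C = 1L, CA = 2L, CAT = 3L), c(C = 2L, CA = 1L, CAT = 4L))
  weights <- list(C = c(1, 0.5), CA = c(1, 1, 1), CAT = c(0.7, 1, 1, 1))
  sw <- list(C = 1.5, CA = 2, CAT = 1.7)
  fw <- foldsearch:::fc_forward_multi
  fwv <- fw(coords, model, cache = TRUE)
  lg <- foldsearch:::batch_loss_grad(fwv, labels, weights, sw)
  g <- foldsearch:::fc_backward(model, fwv, lg$dlogits)
  flat <- foldsearch:::params_flatten(model)
  lossfn <- function(flat) {
    m <- foldsearch:::params_unflatten(model, flat)
    foldsearch:::batch_loss_grad(fw(coords, m), labels, weights, sw)$loss
  }
  for (nm in names(flat)) {
    for (ii in sample(length(flat[[nm]]), min(3, length(flat[[nm]])))) {
      eps <- 1e-4
      f1 <- flat; f1[[nm]][ii] <- f1[[nm]][ii] + eps
      f2 <- flat; f2[[nm]][ii] <- f2[[nm]][ii] - eps
      num <- (lossfn(f1) - lossfn(f2)) / (2 * eps)
      expect_equal(g[[nm]][ii], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("duplicating a non-minimal class halves its weight and leaves the
           loss unchanged", {
  tpl <- make_fold_templates(8, n_res = 20, seed = 6)
  data <- family_dataset(3, tpl, seed_base = 400)
  m <- initialize_model(toy_config(), fc_train_config(), seed = 51)
  lab <- function(d, nm) vapply(d, function(s) s$labels[[nm]], integer(1))
  mk_weights <- function(d) lapply(c(C = "C", CA = "CA", CAT = "CAT"),
                                   function(nm) {
                                     nc <- c(C = 2, CA = 4, CAT = 8)[[nm]]
                                     compute_class_weights(lab(d, nm), nc)
                                   })
  # duplicate every example of CAT class 2 (C and CA class counts double
  # for the containing classes too, so weights halve at every level)
  dup <- c(data, data[lab(data, "CAT") == 2])
  w1 <- mk_weights(data)
  w2 <- mk_weights(dup)
  expect_equal(w2$CAT[2], w1$CAT[2] / 2)
  l1 <- foldsearch:::dataset_loss(m, data, w1)
  l2 <- foldsearch:::dataset_loss(m, dup, w2)
  expect_equal(l2$loss, l1$loss, tolerance = 1e-10)
})

test_that("training is deterministic under a fixed seed and noise is only
           applied on the training path", {
  tpl <- make_fold_templates(4, n_res = 20, seed = 61)
  data <- family_dataset(6, tpl[1:4], seed_base = 500)
  # relabel to 4 CAT classes so the tiny run is fast
  data <- lapply(seq_along(data), function(i) {
    s <- data[[i]]
    labeled_domain(s$domain, C = ((s$labels["CAT"] - 1) %% 2) + 1,
                   CA = s$labels["CAT"], CAT = s$labels["CAT"])
  })
  cfg <- fc_config(n_blocks = 2, node_dim = 8, hidden_dim = 8, out_dim = 8,
                   embed_dim = 8, n_classes = c(C = 2, CA = 4, CAT = 4),
                   max_len = 64)
  tc <- fc_train_config(max_epochs = 2, val_size = 4, seed = 77,
                        batch_size = 8)
  calls <- new.env(); calls$n <- 0
  hook <- function(coords, sd) { calls$n <- calls$n + 1
    add_coordinate_noise(coords, sd) }
  f1 <- train(data, cfg, tc, noise_fun = hook)
  # noise touched exactly the training examples, each epoch, never the
  # validation set
  expect_equal(calls$n, 2 * (length(data) - 4))
  f2 <- train(data, cfg, tc)
  expect_equal(f1$model$blocks, f2$model$blocks, tolerance = 1e-12)
  expect_equal(f1$history, f2$history)
  tc3 <- fc_train_config(max_epochs = 2, val_size = 4, seed = 78,
                         batch_size = 8)
  f3 <- train(data, cfg, tc3)
  expect_false(identical(f1$model$blocks, f3$model$blocks))
})

test_that("training loss trends downward from the start", {
  fit <- get_toy_training()$fit
  d <- diff(fit$history$train_loss[1:10])
  expect_lt(median(d), 0)
})
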