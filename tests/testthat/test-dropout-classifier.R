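test_that("model construction is deterministic and well-formed", {
  m1 <- tiny_model(seed = 3)
  m2 <- tiny_model(seed = 3)
  m3 <- tiny_model(seed = 4)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  expect_gte(dropout_sites(m1), 1L)
  expect_error(model_config(dropout_rate = 1), "dropout_rate")
  expect_error(model_config(dropout_rate = -0.1), "dropout_rate")
})

test_that("the compiled forward pass matches the pure-R oracle exactly", {
  m <- tiny_model(seed = 3, input_size = 32L)
  x <- random_patch(5)

  # deterministic path (no dropout), stem pooling included
  pr <- predict_deterministic(m, x)
  expect_equal(dim(pr), c(1L, 2L))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
  po <- oracle_forward(m$params, x - 0.5, stem = m$config$stem_pool)
  expect_equal(as.vector(pr), po, tolerance = 1e-13)

  # stochastic path: replay the seeded masks independently
  p_mc <- slideuq:::local_seed(11,
    slideuq:::.cpp_forward_mc(m$params, x - 0.5, m$config$dropout_rate, 1L,
                              m$config$stem_pool))
  masks <- slideuq:::local_seed(11, oracle_masks(m$config, c(32L, 32L)))
  expect_equal(as.vector(p_mc),
               oracle_forward(m$params, x - 0.5, masks,
                              stem = m$config$stem_pool),
               tolerance = 1e-13)
})

test_that("the training step follows the numeric gradient", {
  # one Adam step with unit moments reduces to -lr * sign(gradient);
  # compare signs against central differences of the oracle loss
  cfg <- model_config(conv_channels = c(2L, 3L), input_size = 16L,
                      dropout_rate = 0, stem_pool = 0L, seed = 3)
  m <- build_model(cfg)
  xs <- list(random_patch(1, 16L) - 0.5, random_patch(2, 16L) - 0.5)
  ys <- c(0L, 1L)
  loss_of <- function(params) {
    l <- 0
    for (i in 1:2) {
      pr <- oracle_forward(params, xs[[i]])
      l <- l - log(pr[ys[i] + 1])
    }
    l / 2
  }
  st <- slideuq:::.cpp_train_batch(
    m$params, xs, ys, -1, 0.001,
    list(m = slideuq:::zero_params(cfg), v = slideuq:::zero_params(cfg)),
    1L, 0L)
  eps <- 1e-6
  for (probe in list(c("Wc", 1), c("Wd", NA))) {
    par <- if (probe[1] == "Wc") m$params$Wc[[1]] else m$params$Wd
    new <- if (probe[1] == "Wc") st$params$Wc[[1]] else st$params$Wd
    idx <- cbind(c(1, 2), c(1, 3)) # a few entries
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      bump <- function(h) {
        pp <- m$params
        if (probe[1] == "Wc") pp$Wc[[1]][i, j] <- pp$Wc[[1]][i, j] + h
        else pp$Wd[i, j] <- pp$Wd[i, j] + h
        pp
      }
      g <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
      if (abs(g) > 1e-8) {
        expect_equal(sign(par[i, j] - new[i, j]), sign(g))
      }
    }
  }
})

make_toy_patchsets <- function(n_slides_per_class = 2, seed_base = 40) {
  sets <- list()
  k <- 0
  for (cl in c("A", "B")) for (i in seq_len(n_slides_per_class)) {
    k <- k + 1
    spec <- slide_spec(paste0(cl, "_toy", i), cl, base_size = c(640, 640),
                       seed = seed_base + k)
    pyr <- quantize_levels(generate_slide(spec, n_levels = 1))
    sets[[spec$slide_id]] <- label_patches(
      extract_patches(pyr, 0, max_patches = 4, seed = 1), cl)
  }
  sets
}

test_that("training is seeded, validated, and rejects degenerate splits", {
  sets <- make_toy_patchsets()
  cfg <- model_config(seed = 5, max_iterations = 30L, eval_every = 15L)
  m1 <- train_model(build_model(cfg), sets[c(1, 3)], sets[c(2, 4)], cfg)
  m2 <- train_model(build_model(cfg), sets[c(1, 3)], sets[c(2, 4)], cfg)
  expect_identical(m1$learning_curve, m2$learning_curve)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$learning_curve$iteration, c(15L, 30L))
  expect_true(m1$trained)

  # single-class training set is a degenerate objective
  expect_error(train_model(build_model(cfg), sets[c(1, 2)], sets[c(2, 4)], cfg),
               "both contain classes")
})

test_that("label-permuted training stays at chance level", {
  sets <- make_toy_patchsets()
  # destroy the signal: each pseudo-slide holds half class-A and half
  # class-B patches, so its weak label carries no information
  mix <- function(ia, ib, label) {
    ps <- sets[[ia]]
    ps$patches <- c(sets[[ia]]$patches[1:2], sets[[ib]]$patches[1:2])
    ps$coords <- rbind(sets[[ia]]$coords[1:2, ], sets[[ib]]$coords[1:2, ])
    label_patches(ps, label)
  }
  train <- list(mix(1, 3, "A"), mix(3, 1, "B"))
  val <- list(mix(2, 4, "A"), mix(4, 2, "B"))
  accs <- sapply(1:3, function(sd) {
    cfg <- model_config(seed = 100 + sd, max_iterations = 60L, eval_every = 60L)
    m <- train_model(build_model(cfg), train, val, cfg)
    tail(m$learning_curve$val_accuracy, 1)
  })
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("training on separable patches reaches high validation accuracy", {
  curve <- world_clean(1)$curve
  expect_gt(tail(curve$val_accuracy, 1), 0.9)
})

test_that("deterministic prediction is repeatable and is the zero-dropout limit", {
  m <- tiny_model(seed = 6, dropout_rate = 1e-6)
  x <- random_patch(9)
  p1 <- predict_deterministic(m, x)
  p2 <- predict_deterministic(m, x)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), 1, tolerance = 1e-9, ignore_attr = TRUE)

  mc <- mc_predict_patch(m, x, T = 8, seed = 2)
  expect_equal(mc$mu, p1[1, ], tolerance = 1e-3, ignore_attr = TRUE)

  expect_error(predict_deterministic(m, array(0.5, c(8, 8, 2))), "H x W x 3")
})
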