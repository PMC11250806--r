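# Two well-separated Gaussian clusters: every family should fit the
# training data perfectly and expose the same train/score contract.
separable_toy <- function(n = 60, p = 5, seed = 61) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(n * p, 0, 0.3), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
  x <- x + outer(ifelse(y == 1, 2, -2), rep(1, p))
  list(x = x, y = y)
}

all_families <- c("logreg_none", "logreg_l1", "logreg_l2",
                  "logreg_elasticnet", "decision_tree", "random_forest",
                  "svm_linear", "svm_rbf", "adaboost", "simple_dnn",
                  "joint_ae", "joint_vae")

deep_hyper <- list(epochs = 60, lr = 0.01, batch_size = 32)

test_that("every family separates the linearly separable toy", {
  toy <- separable_toy()
  for (fam in all_families) {
    h <- if (fam %in% c("simple_dnn", "joint_ae", "joint_vae"))
      deep_hyper else list()
    spec <- model_spec(fam, hyper = h, seed = 3)
    model <- train_classifier(spec, toy$x, toy$y)
    sc <- score_samples(model, toy$x)
    expect_length(sc, nrow(toy$x))
    expect_true(all(sc >= 0 & sc <= 1), label = fam)
    expect_equal(mean((sc >= 0.5) == (toy$y == 1)), 1,
                 label = paste(fam, "training accuracy"))
  }
})

test_that("probabilistic families score near prevalence on constant features", {
  set.seed(63)
  x <- matrix(1, 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(1, 0), c(35, 15))
  for (fam in c("logreg_none", "decision_tree", "random_forest")) {
    model <- train_classifier(model_spec(fam, seed = 1), x, y)
    expect_equal(mean(score_samples(model, x)), 0.7, tolerance = 0.05,
                 label = fam)
  }
})

test_that("training is reproducible from the seed", {
  toy <- separable_toy(seed = 67)
  for (fam in c("random_forest", "adaboost", "simple_dnn", "joint_ae",
                "joint_vae")) {
    h <- if (fam %in% c("simple_dnn", "joint_ae", "joint_vae"))
      list(epochs = 15, lr = 0.01, batch_size = 32) else list()
    s1 <- score_samples(train_classifier(model_spec(fam, h, seed = 11),
                                         toy$x, toy$y), toy$x)
    s2 <- score_samples(train_classifier(model_spec(fam, h, seed = 11),
                                         toy$x, toy$y), toy$x)
    expect_equal(s1, s2, tolerance = 1e-12, label = fam)
  }
})

test_that("input validation rejects NaN features and single-class labels", {
  toy <- separable_toy()
  xx <- toy$x
  xx[1, 1] <- NA
  expect_error(train_classifier(model_spec("logreg_l2"), xx, toy$y), "NaN")
  expect_error(train_classifier(model_spec("logreg_l2"), toy$x,
                                rep(1, nrow(toy$x))), "both classes")
  expect_error(model_spec("boosted_cnn"), "unknown family")
})

test_that("joint losses evaluate their closed forms", {
  expect_equal(joint_ae_total_loss(1, 1, 0.3), 1)
  expect_equal(joint_ae_total_loss(0.2, 0.6, 0.5), 0.4)
  expect_equal(joint_ae_total_loss(0.2, 0.6, 1), 0.2)   # pure autoencoder
  expect_error(joint_ae_total_loss(1, 1, 1.4), "\\[0, 1\\]")
  # VAE loss and the Gaussian KL
  expect_equal(kl_gaussian(matrix(0, 1, 32), matrix(0, 1, 32)), 0)
  expect_equal(kl_gaussian(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)
  expect_equal(vae_total_loss(0.3, 0.2, 0.5, c = 0.001),
               0.5 + 0.001 * 0.5)
  expect_equal(vae_total_loss(0.3, 0.2, 10, c = 1e-9), 0.5,
               tolerance = 1e-6)                         # c -> 0 boundary
  expect_error(vae_total_loss(1, -0.1, 1), "kl")
})

test_that("reconstruction quality behaves across training stages", {
  set.seed(69)
  n <- 80
  p <- 5
  z <- matrix(rnorm(n * 2), n)
  x <- z %*% matrix(rnorm(2 * p), 2) + matrix(rnorm(n * p, 0, 0.05), n)
  y <- as.integer(z[, 1] > 0)
  trained <- train_joint_ae(x, y, scale = "M", epochs = 400, lr = 0.01,
                            batch_size = 32, seed = 5)
  expect_gt(reconstruction_quality(trained, x), 0.99)
  # an untrained (0-epoch equivalent: 1 epoch, tiny lr) model reconstructs poorly
  raw <- train_joint_ae(x, y, scale = "M", epochs = 1, lr = 1e-9,
                        batch_size = 32, seed = 5)
  expect_lt(abs(reconstruction_quality(raw, x)), 0.5)
  expect_true(abs(reconstruction_quality(trained, x)) <= 1)
  # non-AE models have no decoder
  dnn <- train_classifier(model_spec("simple_dnn", deep_hyper, seed = 1),
                          x, y)
  expect_error(reconstruction_quality(dnn$fit, x), "decoder")
})

test_that("reconstruction loss wiring follows the feature scale", {
  set.seed(71)
  x <- matrix(rnorm(40 * 6), 40)
  y <- rep(0:1, 20)
  m_model <- train_joint_ae(x, y, scale = "M", epochs = 3, lr = 1e-3,
                            batch_size = 16, seed = 2)
  expect_equal(m_model$nets$decoder[[length(m_model$nets$decoder)]]$act,
               "linear")   # squared-error pairing
  b_model <- train_joint_ae(m_to_beta(x), y, scale = "beta", epochs = 3,
                            lr = 1e-3, batch_size = 16, seed = 2)
  expect_equal(b_model$nets$decoder[[length(b_model$nets$decoder)]]$act,
               "sigmoid")  # cross-entropy pairing
  expect_true(all(dl_reconstruct(b_model, m_to_beta(x)) >= 0 &
                    dl_reconstruct(b_model, m_to_beta(x)) <= 1))
})

test_that("model manifests serialize the reproduction recipe", {
  toy <- separable_toy()
  model <- train_classifier(model_spec("logreg_l1",
                                       hyper = list(lambda = 0.05),
                                       seed = 9, scale = "beta"),
                            toy$x, toy$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_manifest(model, path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(man$family, "logreg_l1")
  expect_equal(man$hyper$lambda, 0.05)
  expect_equal(man$seed, 9)
  expect_equal(man$scale, "beta")
  expect_equal(man$features, paste0("f", 1:5))
})
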