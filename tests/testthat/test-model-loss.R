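# s2f_model: composite loss arithmetic, schedule, predict contracts,
# gradient correctness, seeded training, multi-gene scheme.

test_that("composite loss matches the stated formula", {
  expect_equal(composite_loss(c(1, 2), c(1, 3), 0.5), 0.75)
  # decomposition: alpha = 1 is the MSE, alpha = 0 the pairwise term
  set.seed(1)
  p <- rnorm(9); o <- rnorm(9)
  expect_equal(composite_loss(p, o, 1), mean((p - o)^2))
  pair_brute <- mean(combn(9, 2, function(ij)
    ((p[ij[1]] - p[ij[2]]) - (o[ij[1]] - o[ij[2]]))^2))
  expect_equal(composite_loss(p, o, 0), pair_brute)
  expect_equal(composite_loss(p, o, 0.3),
               0.3 * mean((p - o)^2) + 0.7 * pair_brute)
  # perfect fit and constant-shift invariance of the pairwise term
  expect_equal(composite_loss(p, p, 0.5), 0)
  expect_equal(composite_loss(o + 2.5, o, 0), 0)
  expect_equal(composite_loss(o + 2.5, o, 0.4), 0.4 * 2.5^2)
  expect_error(composite_loss(1, 1, 0.5), "at least 2")
})

test_that("loss gradient matches finite differences", {
  set.seed(2)
  p <- rnorm(6); o <- rnorm(6)
  for (a in c(0, 0.5, 1)) {
    g <- seq2expr:::.composite_loss_grad(p, o, a)
    gn <- vapply(1:6, function(i) {
      e <- 1e-6; p2 <- p; p2[i] <- p2[i] + e
      p3 <- p; p3[i] <- p3[i] - e
      (composite_loss(p2, o, a) - composite_loss(p3, o, a)) / (2 * e)
    }, numeric(1))
    expect_equal(g, gn, tolerance = 1e-6)
  }
})

test_that("learning-rate schedule: linear warm-up, cosine decay to exactly 0", {
  expect_equal(lr_schedule(50, 1000, peak = 1e-4, warmup = 0.1), 0.5e-4)
  expect_equal(lr_schedule(100, 1000, peak = 1e-4, warmup = 0.1), 1e-4)
  expect_lt(lr_schedule(1000, 1000, peak = 1e-4, warmup = 0.1), 1e-9)
  expect_equal(lr_schedule(550, 1000, peak = 2e-3, warmup = 0.1), 1e-3)
  lr <- lr_schedule(1:1000, 1000)
  expect_true(all(diff(lr[1:100]) > 0) && all(diff(lr[101:1000]) < 0))
})

test_that("network gradients match finite differences through every layer", {
  cfg <- model_config(L = 64, cov_dim = 2,
                      trunk = list(channels = c(6L, 8L), kernels = c(5L, 3L),
                                   dilations = c(1L, 2L), pools = c(4L, 1L)),
                      head_hidden = 16L, seed = 5)
  set.seed(5)
  p <- seq2expr:::.init_params(cfg)
  B <- 3
  X <- matrix(0, B * 64, 4)
  X[cbind(seq_len(B * 64), sample(4, B * 64, TRUE))] <- 1
  cv <- matrix(rnorm(B * 2), B)
  obs <- rnorm(B)
  fw <- seq2expr:::.nn_forward(p, cfg, X, B, cv, keep_cache = TRUE)
  g <- seq2expr:::.nn_backward(p, cfg, fw$cache,
                               seq2expr:::.composite_loss_grad(fw$out, obs,
                                                               0.5))
  lossfun <- function(pp) {
    composite_loss(seq2expr:::.nn_forward(pp, cfg, X, B, cv)$out, obs, 0.5)
  }
  set.seed(6)
  for (nm in names(p)) {
    i <- sample(length(p[[nm]]), 1)
    e <- 1e-5
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + e
    p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - e
    num <- (lossfun(p2) - lossfun(p3)) / (2 * e)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("predict enforces the mode contracts and per-item independence", {
  d <- tiny_gene(seed = 12, n = 30)
  cfg <- model_config(L = 512, scale = "desk", seed = 1,
                      trunk = list(channels = c(8L, 16L), kernels = c(7L, 3L),
                                   dilations = c(1L, 2L), pools = c(4L, 1L)),
                      head_hidden = 32L)
  cfg$cov_dim <- 14L
  set.seed(1)
  params <- seq2expr:::.init_params(cfg)
  m <- seq2expr:::.new_predictor(cfg, params, "single",
                                 list(y_center = 0, y_scale = 1,
                                      cov_center = rep(0, 14),
                                      cov_scale = rep(1, 14)))
  enc <- encode_cohort(d$ref, d$vt, rownames(d$vt$dosages)[1:6])
  expect_error(predict(m, enc), "requires covariates")
  pr <- predict(m, enc, covariates = d$covariates[1:6, ])
  # permuting the batch permutes predictions identically
  perm <- c(4, 2, 6, 1, 3, 5)
  pr2 <- predict(m, enc[, , perm], covariates = d$covariates[perm, ])
  expect_equal(pr2, pr[perm], tolerance = 1e-12)
  # zeroed final layer predicts exactly 0 (plus the y offset)
  params0 <- params
  params0[["fc2.W"]][] <- 0; params0[["fc2.b"]] <- 0
  m0 <- m; m0$params <- params0
  expect_equal(predict(m0, enc, covariates = d$covariates[1:6, ]),
               rep(0, 6))
  mm <- m; mm$mode <- "multi"; mm$cfg$cov_dim <- 0L
  expect_error(predict(mm, enc, covariates = d$covariates[1:6, ]),
               "multi-gene")
})

test_that("an affine predictor equals its closed form", {
  d <- tiny_gene(seed = 13, n = 20)
  set.seed(3)
  W <- matrix(rnorm(512 * 4, sd = 0.1), 512, 4)
  mod <- affine_predictor(W, b = 0.7)
  enc <- encode_cohort(d$ref, d$vt, rownames(d$vt$dosages)[1:5])
  pr <- predict(mod, enc)
  manual <- vapply(1:5, function(i) sum(W * enc[, , i]) + 0.7, numeric(1))
  expect_equal(pr, manual, tolerance = 1e-12)
})

test_that("seeded single-gene training is bit-reproducible and learns an easy gene", {
  d <- simulate_gene_dataset(L = 512, n = 600, n_sites = 12, n_causal = 6,
                             h2 = 0.9, rare_var_share = 0,
                             with_covariates = FALSE, seed = 2)
  dataset <- list(ref = d$ref, vt = d$vt, expression = d$cohort$expression,
                  covariates = NULL, split = d$cohort$split)
  tk <- list(channels = c(24L, 48L), kernels = c(7L, 3L),
             dilations = c(1L, 2L), pools = c(4L, 1L))
  cfg <- model_config(L = 512, trunk = tk, epochs = 10L, lr_peak = 3e-3,
                      accum = 1L, batch_size = 16L, seed = 1,
                      head_warmstart = FALSE, patience = 20L)
  m1 <- train_single_gene(dataset, cfg)
  m2 <- train_single_gene(dataset, cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$history$val_loss, m2$history$val_loss)
  # gradient training alone makes real progress on an easy gene
  ev <- evaluate(m1, dataset)
  expect_gt(ev$pcc, 0.6)
  # the structured warm start reaches the linear baseline's level
  cfgw <- model_config(L = 512, trunk = tk, epochs = 0L, seed = 7)
  mw <- train_single_gene(dataset, cfgw)
  expect_gt(evaluate(mw, dataset)$pcc, 0.8)
})

test_that("non-finite losses abort with diagnostics", {
  d <- tiny_gene(seed = 14, n = 40)
  dataset <- list(ref = d$ref, vt = d$vt,
                  expression = d$cohort$expression,
                  covariates = NULL, split = d$cohort$split)
  cfg <- model_config(L = 512,
                      trunk = list(channels = c(4L, 4L), kernels = c(3L, 3L),
                                   dilations = c(1L, 1L), pools = c(4L, 1L)),
                      head_hidden = 8L, epochs = 1L, lr_peak = Inf,
                      accum = 1L, seed = 1, head_warmstart = FALSE,
                      clip = Inf)
  expect_error(train_single_gene(dataset, cfg), "non-finite loss")
})

test_that("multi-gene training is pairwise-only, shift-invariant and gene-agnostic", {
  genes <- lapply(1:2, function(s) {
    d <- simulate_gene_dataset(L = 256, n = 60, n_sites = 20, n_causal = 3,
                               h2 = 0.6, rare_var_share = 0,
                               with_covariates = FALSE, seed = 30 + s)
    list(ref = d$ref, vt = d$vt, expression = d$cohort$expression,
         covariates = NULL, split = d$cohort$split)
  })
  tk <- list(channels = c(8L, 8L), kernels = c(5L, 3L),
             dilations = c(1L, 2L), pools = c(4L, 1L))
  cfg <- model_config(L = 256, trunk = tk, head_hidden = 16L, epochs = 1L,
                      lr_peak = 1e-3, batch_size = 8L, accum = 2L, seed = 4,
                      head_warmstart = FALSE)
  m <- train_multi_gene(genes, cfg)
  expect_identical(m$mode, "multi")
  expect_equal(m$cfg$alpha, 0)             # pairwise term only
  expect_equal(m$cfg$accum, 2L * cfg$accum) # accumulation doubled
  # per-gene constant offsets in observations do not change the loss
  pr <- rnorm(8); ob <- genes[[1]]$expression[1:8]
  expect_equal(composite_loss(pr, ob, 0), composite_loss(pr, ob + 100, 0))
  # unseen gene: finite predictions from a gene-agnostic architecture
  d3 <- simulate_gene_dataset(L = 256, n = 20, n_sites = 8, n_causal = 3,
                              h2 = 0.5, rare_var_share = 0,
                              with_covariates = FALSE, seed = 99)
  enc <- encode_cohort(d3$ref, d3$vt, rownames(d3$vt$dosages)[1:5])
  pr <- predict(m, enc)
  expect_true(all(is.finite(pr)))
  # contract violations
  genes_cov <- genes
  genes_cov[[1]]$covariates <- matrix(rnorm(120), 60)
  expect_error(train_multi_gene(genes_cov, cfg), "covariates")
  expect_error(train_multi_gene(genes[1], cfg), ">= 2 genes")
})
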