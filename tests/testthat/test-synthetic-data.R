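# synthetic_data: generators are pure functions of (parameters, seed);
# planted architecture is calibrated; the MAF spectrum grows its rare tail
# with cohort size.

test_that("simulate_reference is deterministic, GC-calibrated, and validates input", {
  expect_identical(simulate_reference(8, 0.5, seed = 1)$seq,
                   simulate_reference(8, 0.5, seed = 1)$seq)
  r <- simulate_reference(4096, 0.4, seed = 7)
  gc_obs <- mean(strsplit(r$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.4), 0.03)     # binomial 95% bound at n=4096
  expect_identical(r$tss_offset, 2048L)
  expect_error(simulate_reference(-1, 0.5), "positive")
  expect_error(simulate_reference(10, 1.0), "gc")
  expect_error(simulate_reference(10, 0), "gc")
})

test_that("simulate_cohort yields polymorphic biallelic SNVs with consistent MAF", {
  ref <- simulate_reference(2048, seed = 2)
  vt <- simulate_cohort(ref, n = 200, n_sites = 60, seed = 5)
  expect_false(anyDuplicated(vt$records$pos) > 0)
  # ref allele matches the reference sequence
  expect_identical(substring(ref$seq, vt$records$pos, vt$records$pos),
                   vt$records$ref)
  expect_true(all(vt$records$ref != vt$records$alt))
  # no monomorphic records; stored af equals column mean / 2 exactly
  expect_true(all(vt$maf > 0))
  expect_equal(colMeans(vt$dosages) / 2, vt$af, tolerance = 1e-12)
  expect_true(all(vt$maf <= 0.5))
  expect_error(simulate_cohort(ref, n = 1, n_sites = 10), "2 individuals")
  expect_error(simulate_cohort(ref, n = 10, n_sites = 3000), "smaller")
})

test_that("rare-variant count grows with cohort size and cohorts are nested", {
  ref <- simulate_reference(2048, seed = 3)
  for (seed in 1:5) {
    small <- simulate_cohort(ref, n = 300, n_sites = 250, seed = seed)
    big <- simulate_cohort(ref, n = 3000, n_sites = 250, seed = seed)
    expect_gt(sum(big$maf < 0.01), sum(small$maf < 0.01))
    # nesting: the first 300 individuals of the big cohort carry identical
    # genotypes at the shared sites
    shared <- intersect(small$records$pos, big$records$pos)
    js <- match(shared, small$records$pos)
    jb <- match(shared, big$records$pos)
    expect_identical(unname(small$dosages[, js]),
                     unname(big$dosages[1:300, jb]))
  }
})

test_that("block-LD mode induces strong adjacent-site correlation", {
  ref <- simulate_reference(2048, seed = 4)
  vt <- simulate_cohort(ref, n = 1000, n_sites = 40, seed = 2,
                        maf_mix = list(w_rare = 0, beta = c(0.2, 8),
                                       unif = c(0.2, 0.5)),
                        ld = list(block = 5, flip = 0.03))
  r2 <- cor(vt$dosages)^2
  adj <- r2[cbind(seq_len(ncol(r2) - 1), seq_len(ncol(r2) - 1) + 1)]
  expect_gt(mean(adj > 0.8), 0.5)
})

test_that("plant_effects hits the target heritability and rare-variance share", {
  d <- simulate_gene_dataset(L = 2048, n = 2000, n_sites = 120,
                             n_causal = 20, h2 = 0.5, rare_var_share = 0.5,
                             seed = 11)
  g <- genetic_component(d$truth, d$vt)
  y <- d$cohort$expression
  expect_lt(abs(var(g) / var(y) - 0.5), 0.05)
  # rare causal subset carries ~half the additive genetic variance
  rare <- d$truth$causal_indices[d$vt$maf[d$truth$causal_indices] < 0.05]
  g_r <- as.vector(d$vt$dosages[, rare] %*% d$truth$beta[rare])
  expect_lt(abs(var(g_r) / var(g) - 0.5), 0.1)
  expect_error(plant_effects(d$vt, n_causal = 1e5, h2 = 0.5), "exceeds")
  expect_error(plant_effects(d$vt, 5, h2 = 1), "h2")
})

test_that("h2 = 0 zeroes all effects", {
  d <- tiny_gene(seed = 2)
  t0 <- plant_effects(d$vt, 5, h2 = 0, seed = 1)
  expect_true(all(t0$beta == 0))
})

test_that("heritability calibration: mean realized h2 within 0.03 over 10 seeds", {
  h2s <- vapply(1:10, function(s) {
    d <- simulate_gene_dataset(L = 1024, n = 2000, n_sites = 100,
                               n_causal = 15, h2 = 0.4, seed = s)
    g <- genetic_component(d$truth, d$vt)
    var(g) / var(d$cohort$expression)
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.4), 0.03)
})

test_that("explicit interaction pairs enter the phenotype exactly as products", {
  d <- tiny_gene(seed = 3)
  int <- data.frame(i = 1L, j = 2L, coef = 0.7)
  tr <- plant_effects(d$vt, 4, h2 = 0.3, interactions = int, seed = 1)
  g <- genetic_component(tr, d$vt)
  tr0 <- tr; tr0$interactions <- NULL
  g0 <- genetic_component(tr0, d$vt)
  expect_equal(g - g0, 0.7 * d$vt$dosages[, 1] * d$vt$dosages[, 2],
               ignore_attr = TRUE)
})

test_that("simulate_expression separates genetic signal from seeded noise", {
  d <- tiny_gene(seed = 4)
  # sigma_e = 0, no covariates: expression is exactly linear in dosages
  c0 <- simulate_expression(d$truth, d$vt, covariates = NULL, sigma_e = 0,
                            seed = 9)
  g <- genetic_component(d$truth, d$vt)
  expect_equal(unname(c0$expression), g, tolerance = 1e-12)
  # different seeds share the genetic component
  c1 <- simulate_expression(d$truth, d$vt, d$covariates, seed = 1)
  c2 <- simulate_expression(d$truth, d$vt, d$covariates, seed = 2)
  expect_false(isTRUE(all.equal(c1$expression, c2$expression)))
  expect_error(simulate_expression(d$truth, d$vt, sigma_e = -1),
               "sigma_e")
})

test_that("protein-altering carrier fraction is binomially calibrated", {
  d <- tiny_gene(seed = 5, n = 400)
  fr <- vapply(1:6, function(s) {
    co <- simulate_expression(d$truth, d$vt, seed = s, pa_fraction = 0.1)
    length(unique(co$consequence_table$individual[
      co$consequence_table$consequence %in%
        c("missense", "stop_gained", "stop_lost", "start_lost",
          "frameshift")])) / 400
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.1), 0.03)
})

test_that("simulate_annotations builds a valid tiling, coverage-true tracks and PWMs", {
  ref <- simulate_reference(4096, seed = 6)
  ann <- simulate_annotations(ref, state_config = c(EnhA = 0.5),
                              seed = 2, segment = 128L)
  iv <- ann$chromhmm$intervals
  expect_equal(iv$start[1], 0)
  expect_equal(iv$end[nrow(iv)], 4096)
  expect_true(all(iv$start[-1] == iv$end[-nrow(iv)]))   # disjoint tiling
  cov <- track_coverage(ann$chromhmm)
  expect_lt(abs(cov[["EnhA"]] - 0.5), 128 / 4096 + 1e-9)
  for (pw in ann$pwms)
    expect_equal(colSums(pw$mat), rep(1, pw$w), tolerance = 1e-9)
  expect_error(simulate_annotations(ref, state_config = c(A = 0.7, B = 0.5)),
               "sum")
  # determinism
  ann2 <- simulate_annotations(ref, state_config = c(EnhA = 0.5),
                               seed = 2, segment = 128L)
  expect_identical(ann$chromhmm$intervals, ann2$chromhmm$intervals)
})

test_that("infeasible rare_var_share errors", {
  ref <- simulate_reference(1024, seed = 7)
  vt <- simulate_cohort(ref, n = 500, n_sites = 20, seed = 1,
                        maf_mix = list(w_rare = 0, beta = c(0.2, 8),
                                       unif = c(0.25, 0.5)))
  expect_true(all(vt$maf >= 0.05))
  expect_error(plant_effects(vt, 5, h2 = 0.5, rare_var_share = 0.5),
               "rare")
})
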