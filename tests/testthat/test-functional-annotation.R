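# functional_annotation: enrichment, cCRE overlap, PWM scanning with exact
# p-values, LD redundancy.

hsv_at <- function(pos, maf = rep(0.1, length(pos))) {
  structure(list(members = data.frame(idx = seq_along(pos), pos = pos,
                                      score = rep(1, length(pos)),
                                      rank = seq_along(pos), maf = maf),
                 n_target = length(pos), source = "ism"),
            class = "hsv_set")
}

test_that("ChromHMM enrichment: observed/expected worked examples", {
  # one gene, one state covering 50% of a 1000 bp window, 10 HSVs
  track <- annotation_track(data.frame(start = c(0, 500),
                                       end = c(500, 1000),
                                       label = c("EnhA", "Quies")),
                            type = "tiling", L = 1000)
  hsv5 <- hsv_at(c(seq(50, 450, length.out = 5),
                   seq(550, 950, length.out = 5)))
  res <- chromhmm_enrichment(list(hsv5), list(track))
  expect_equal(res$ratio[res$state == "EnhA"], 1.0)
  hsv8 <- hsv_at(c(seq(50, 450, length.out = 8), 600, 700))
  res8 <- chromhmm_enrichment(list(hsv8), list(track))
  expect_equal(res8$ratio[res8$state == "EnhA"], 1.6)
  expect_equal(sum(res8$observed), 10)
  # aggregation across genes: sums before the ratio
  res2 <- chromhmm_enrichment(list(hsv5, hsv8), list(track, track))
  expect_equal(res2$observed[res2$state == "EnhA"], 13)
  expect_equal(res2$expected[res2$state == "EnhA"], 10)
  expect_equal(res2$ratio[res2$state == "EnhA"], 1.3)
  # state groups
  resg <- chromhmm_enrichment(list(hsv5), list(track),
                              groups = c(EnhA = "enhancer"))
  expect_equal(resg$group[resg$state == "EnhA"], "enhancer")
  expect_equal(resg$group[resg$state == "Quies"], "other")
  expect_error(chromhmm_enrichment(list(hsv_at(2000)), list(track)),
               "outside")
})

test_that("uniform random HSVs give calibrated enrichment (Monte-Carlo null)", {
  ref <- simulate_reference(4096, seed = 31)
  ann <- simulate_annotations(ref, state_config = c(EnhA = 0.3, Tx = 0.25),
                              seed = 3)
  cov <- track_coverage(ann$chromhmm)
  set.seed(99)
  ratios <- vapply(1:300, function(i) {
    hs <- hsv_at(sample.int(4096, 25))
    r <- chromhmm_enrichment(list(hs), list(ann$chromhmm))
    r$ratio[r$state == "EnhA"]
  }, numeric(1))
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})

test_that("cCRE overlap fractions and class priority", {
  # no elements -> 0
  empty <- annotation_track(data.frame(start = integer(0), end = integer(0),
                                       label = character(0)), L = 1000)
  expect_equal(ccre_overlap_fraction(list(hsv_at(c(10, 20))),
                                     list(empty))$overall, 0)
  # all HSVs inside one pELS interval -> 1
  t1 <- annotation_track(data.frame(start = 100, end = 200,
                                    label = "pELS"), L = 1000)
  r1 <- ccre_overlap_fraction(list(hsv_at(c(150, 160, 170))), list(t1))
  expect_equal(r1$overall, 1)
  expect_equal(unname(r1$by_class[["pELS"]]), 1)
  # overlapping classes resolved by priority with a warning
  t2 <- annotation_track(data.frame(start = c(100, 150), end = c(300, 250),
                                    label = c("dELS", "PLS")), L = 1000)
  expect_warning(r2 <- ccre_overlap_fraction(list(hsv_at(200)), list(t2)),
                 "priority")
  expect_equal(unname(r2$by_class[["PLS"]]), 1)
  # random placement recovers the coverage fraction
  ref <- simulate_reference(4096, seed = 32)
  ann <- simulate_annotations(ref, seed = 5)
  cov_tot <- sum(track_coverage(ann$ccre))
  set.seed(42)
  fr <- vapply(1:200, function(i)
    ccre_overlap_fraction(list(hsv_at(sample.int(4096, 30))),
                          list(ann$ccre))$overall, numeric(1))
  expect_lt(abs(mean(fr) - cov_tot), 0.02)
})

test_that("PWM scanner: exact p-values, hand-computed deltaS, classes", {
  # width-3 PWM with a unique consensus ACG, no pseudocount needed
  mat <- matrix(0.05 / 3, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  mat["A", 1] <- 0.95; mat["C", 2] <- 0.95; mat["G", 3] <- 0.95
  mat <- sweep(mat, 2, colSums(mat), `/`)
  pw <- pwm("CONS", mat, pseudocount = 0)
  is_ <- seq2expr:::.pwm_int_scores(pw, rep(0.25, 4))
  null <- seq2expr:::.pwm_null_dist(is_$int, rep(0.25, 4))
  expect_equal(sum(null$probs), 1, tolerance = 1e-12)
  cons_int <- sum(is_$int[cbind(c(1, 2, 3), 1:3)])
  expect_equal(seq2expr:::.pwm_pvalue(null, cons_int), 1 / 64,
               tolerance = 1e-12)
  # DP null equals exhaustive enumeration for width <= 6
  set.seed(7)
  for (w in c(2L, 4L)) {
    m2 <- matrix(rgamma(4 * w, 1), 4)
    m2 <- sweep(m2, 2, colSums(m2), `/`)
    rownames(m2) <- c("A", "C", "G", "T")
    pw2 <- pwm(sprintf("R%d", w), m2)
    bg <- c(0.3, 0.2, 0.3, 0.2)
    is2 <- seq2expr:::.pwm_int_scores(pw2, bg)
    null2 <- seq2expr:::.pwm_null_dist(is2$int, bg)
    kmers <- as.matrix(expand.grid(rep(list(1:4), w)))
    sc <- apply(kmers, 1, function(k) sum(is2$int[cbind(k, seq_len(w))]))
    pr <- apply(kmers, 1, function(k) prod(bg[k]))
    enum <- tapply(pr, sc, sum)
    dp <- setNames(null2$probs, null2$lo + seq_along(null2$probs) - 1L)
    dp <- dp[dp > 0]
    expect_equal(sort(as.integer(names(enum))),
                 sort(as.integer(names(dp))))
    expect_lt(sum(abs(enum[names(dp)] - dp)), 1e-9)
  }
})

test_that("motif_effects classifies loss and computes deltaS in bits", {
  # toy column: A = 0.85, C = 0.05 (uniform background, no pseudocount);
  # width 8 so the consensus can clear the 1e-4 raw-p prefilter
  w <- 8L
  mat <- matrix(0.05, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  mat["A", ] <- 0.85
  pw <- pwm("POLYA", mat, pseudocount = 0)
  ref <- reference_window("chrT", 0, paste0(strrep("C", 30), strrep("A", 8),
                                            strrep("C", 30)), 30)
  # variant at window position 35 (1-based): A -> C inside the A-run
  rec <- data.frame(pos = 35L, ref = "A", alt = "C")
  vt <- variant_table(rec, matrix(1L, 1, 1, dimnames = list("I1", NULL)),
                      ref)
  hs <- hsv_at(35L)
  hs$members$idx <- 1L
  res <- motif_effects(hs, ref, vt, list(pw), bg = rep(0.25, 4))
  expect_equal(nrow(res$calls), 1L)
  expect_lt(abs(res$calls$deltaS - log2(0.05 / 0.85)), 0.02)
  expect_equal(res$calls$class, "loss")   # ref hit significant, alt not
  expect_equal(res$fraction_with_effect, 1)
  # variant far from any motif match: class none, fraction 0
  rec2 <- data.frame(pos = 10L, ref = "C", alt = "G")
  vt2 <- variant_table(rec2, matrix(1L, 1, 1, dimnames = list("I1", NULL)),
                       ref)
  res2 <- motif_effects(hsv_at(10L), ref, vt2, list(pw),
                        bg = rep(0.25, 4))
  expect_equal(res2$calls$class, "none")
  expect_equal(res2$fraction_with_effect, 0)
})

test_that("zero-probability PWM cells without pseudocount are rejected", {
  mat <- matrix(0.25, 4, 3); mat[1, 1] <- 0; mat[2, 1] <- 0.5
  expect_error(pwm("BAD", mat, pseudocount = 0), "pseudocount")
})

test_that("LD redundancy equals brute-force squared correlation", {
  set.seed(8)
  n <- 500
  d1 <- rbinom(n, 2, 0.3)
  dos <- cbind(d1, d1, rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  rownames(dos) <- sprintf("I%04d", 1:n)
  rec <- data.frame(pos = c(5L, 15L, 25L, 35L), ref = "A", alt = "G")
  vt <- variant_table(rec, dos)
  hs <- hsv_at(rec$pos); hs$members$idx <- 1:4
  res <- ld_redundancy(hs, vt)
  brute <- outer(1:4, 1:4, Vectorize(function(i, j)
    cor(dos[, i], dos[, j])^2))
  expect_equal(res$per_gene[[1]]$r2, brute, tolerance = 1e-10,
               ignore_attr = TRUE)
  # identical columns -> redundancy for that pair only
  expect_equal(res$per_gene[[1]]$qualifying, c(TRUE, TRUE, FALSE, FALSE),
               ignore_attr = TRUE)
  expect_equal(res$fraction, 0.5)
  # independent common variants at n = 10,000: no strong LD
  set.seed(9)
  dos2 <- cbind(rbinom(10000, 2, 0.3), rbinom(10000, 2, 0.4))
  rownames(dos2) <- sprintf("I%05d", 1:10000)
  vt2 <- variant_table(data.frame(pos = c(1L, 2L), ref = "A", alt = "G"),
                       dos2)
  hs2 <- hsv_at(c(1L, 2L)); hs2$members$idx <- 1:2
  res2 <- ld_redundancy(hs2, vt2)
  expect_lt(max(res2$per_gene[[1]]$r2[1, 2]), 0.01)
  expect_equal(res2$fraction, 0)
  # zero-variance column warns and is treated as r2 = 0
  dos3 <- cbind(rep(1L, 20), rbinom(20, 2, 0.4))
  rownames(dos3) <- sprintf("I%02d", 1:20)
  vt3 <- list(dosages = dos3)
  hs3 <- hsv_at(c(1L, 2L)); hs3$members$idx <- 1:2
  expect_warning(res3 <- ld_redundancy(hs3, vt3), "zero-variance")
  expect_equal(res3$fraction, 0)
})

test_that("block-LD cohorts make the redundancy statistic respond", {
  ref <- simulate_reference(2048, seed = 33)
  vt <- simulate_cohort(ref, n = 500, n_sites = 30, seed = 3,
                        maf_mix = list(w_rare = 0, beta = c(0.2, 8),
                                       unif = c(0.2, 0.5)),
                        ld = list(block = 5, flip = 0.02))
  hs <- hsv_at(vt$records$pos)
  hs$members$idx <- seq_len(n_variants(vt))
  res <- ld_redundancy(hs, vt)
  expect_gt(res$fraction, 0.5)
})

test_that("with block LD, elastic-net HSVs are more redundant than the surrogate's", {
  fr <- t(vapply(1:5, function(s) {
    d <- simulate_gene_dataset(L = 1024, n = 800, n_sites = 60,
                               n_causal = 8, h2 = 0.5,
                               rare_var_share = 0.2, seed = 60 + s,
                               ld = list(block = 5, flip = 0.05))
    ds <- list(ref = d$ref, vt = d$vt, expression = d$cohort$expression,
               covariates = d$covariates, split = d$cohort$split)
    en <- fit_elastic_net(d$vt, d$cohort$expression, d$cohort$split)
    sur <- train_single_gene(ds, model_config(L = 1024, epochs = 0L,
                                              seed = 60 + s))
    im <- ism_map(sur, reference_onehot(d$ref),
                  covariates = colMeans(d$covariates),
                  positions = d$vt$records$pos)
    c(sur = ld_redundancy(select_hsv(im, d$vt, en$n_nonzero),
                          d$vt)$fraction,
      en = ld_redundancy(hsv_from_en(en, d$vt), d$vt)$fraction)
  }, numeric(2)))
  expect_gte(sum(fr[, "en"] >= fr[, "sur"]), 4L)
  expect_gt(mean(fr[, "en"]), mean(fr[, "sur"]))
})
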