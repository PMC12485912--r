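# Metrics and the headline experiments: held-out evaluation, rare-variant
# masking, nested downsampling, and effect-size agreement against the
# planted (simulated) truth.

#' Coefficient of determination against the observed mean
#'
#' `R^2 = 1 - SSE / SST`, with SST taken against the mean of the observed
#' values in the evaluated split.
#'
#' @param pred,obs numeric vectors
#' @return scalar R^2 (can be negative for predictions worse than the mean)
#' @export
r_squared <- function(pred, obs) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Pearson correlation coefficient (0 for constant input, with a flag)
#' @param pred,obs numeric vectors
#' @return correlation; attribute `constant` is TRUE when either vector is
#'   constant and the value was set to 0
#' @export
pcc <- function(pred, obs) {
  if (sd(pred) == 0 || sd(obs) == 0)
    return(structure(0, constant = TRUE))
  cor(pred, obs)
}

#' Spearman rank correlation
#' @param pred,obs numeric vectors
#' @return rank correlation (0 with flag for constant input)
#' @export
spearman <- function(pred, obs) {
  if (sd(pred) == 0 || sd(obs) == 0)
    return(structure(0, constant = TRUE))
  cor(pred, obs, method = "spearman")
}

# predictions for a dataset split, dispatching on the model class
.split_predictions <- function(model, dataset, split, vt = dataset$vt) {
  ids <- names(dataset$split)[dataset$split == split]
  obs <- dataset$expression[ids]
  if (inherits(model, "en_model")) {
    pred <- predict(model, vt$dosages[ids, , drop = FALSE])
  } else {
    cov <- if (model$cfg$cov_dim > 0L)
      dataset$covariates[ids, , drop = FALSE] else NULL
    pred <- as.numeric(.predict_ids(model, reference_onehot(dataset$ref),
                                    .variant_info(vt), vt$dosages, ids,
                                    cov_std = if (is.null(cov)) NULL else
                                      sweep(sweep(dataset$covariates, 2,
                                                  model$std$cov_center),
                                            2, model$std$cov_scale, `/`)))
    pred <- pred * model$std$y_scale + model$std$y_center
  }
  list(ids = ids, pred = unname(pred), obs = unname(obs))
}

#' Evaluate a model on a held-out split
#'
#' @param model an `en_model` or `expression_predictor`
#' @param dataset list(ref, vt, expression, covariates, split)
#' @param split which split to evaluate ("test" by default)
#' @return object of class `metrics_report`: r2, pcc, spearman, n,
#'   model id, split; `constant_predictions` flags a degenerate model
#' @export
evaluate <- function(model, dataset, split = "test") {
  sp <- .split_predictions(model, dataset, split)
  p <- pcc(sp$pred, sp$obs)
  structure(list(model = class(model)[1], split = split, n = length(sp$ids),
                 r2 = r_squared(sp$pred, sp$obs), pcc = as.numeric(p),
                 spearman = as.numeric(spearman(sp$pred, sp$obs)),
                 constant_predictions = isTRUE(attr(p, "constant"))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s on %s (n=%d): R2=%.3f PCC=%.3f rho=%.3f%s\n",
              x$model, x$split, x$n, x$r2, x$pcc, x$spearman,
              if (x$constant_predictions) " [constant]" else ""))
  invisible(x)
}

#' Paired full-genome vs rare-masked evaluation
#'
#' Evaluates the same trained model on the same test individuals twice:
#' once with the full personal genomes and once with encodings built after
#' [mask_by_maf()] zeroed all variants with cohort MAF below the threshold.
#' Because model and individuals are unchanged, any difference reflects
#' the masked variants' contribution.
#'
#' @param model a trained model
#' @param dataset the gene dataset
#' @param maf_threshold masking threshold in (0, 0.5]
#' @param split evaluated split
#' @return list(full, masked = `metrics_report`s, delta_pcc)
#' @export
masked_evaluation <- function(model, dataset, maf_threshold = 0.05,
                              split = "test") {
  vt_masked <- mask_by_maf(dataset$vt, maf_threshold)
  full <- evaluate(model, dataset, split)
  ds2 <- dataset
  ds2$vt <- vt_masked
  masked <- evaluate(model, ds2, split)
  if (masked$n != full$n) stop("masking changed the evaluated individuals")
  list(full = full, masked = masked, delta_pcc = full$pcc - masked$pcc)
}

#' Downsampling experiment over nested cohorts
#'
#' Trains the surrogate and the elastic-net baseline on nested training
#' subsets of the stated sizes; the validation and test sets are fixed, so
#' every configuration is evaluated on identical individuals. To keep the
#' optimization comparable, the surrogate's gradient-accumulation factor is
#' scaled with the subset size so the number of optimizer updates per run
#' matches the largest cohort.
#'
#' @param dataset the gene dataset
#' @param sizes nested training-subset sizes
#' @param config surrogate [model_config()]
#' @param seed seed for the nested draw
#' @return data.frame with one row per (size, model): pcc, r2, n_train
#' @export
downsampling_experiment <- function(dataset, sizes = c(200L, 500L, 1000L),
                                    config = model_config(), seed = 1L) {
  subs <- nested_subsets(dataset$split, sizes, seed)
  s_max <- max(sizes)
  out <- list()
  for (s in names(subs)) {
    ids <- subs[[s]]
    ds <- dataset
    ds$split <- dataset$split
    ds$split[dataset$split == "train"] <- "unused"
    ds$split[ids] <- "train"
    en <- fit_elastic_net(ds$vt, ds$expression, ds$split)
    cfg <- config
    cfg$accum <- max(1L, as.integer(round(config$accum *
                                            as.integer(s) / s_max)))
    cfg$seed <- config$seed
    sur <- train_single_gene(ds, cfg)
    for (m in list(en = en, surrogate = sur)) {
      ev <- evaluate(m, ds, "test")
      out[[length(out) + 1L]] <- data.frame(
        size = as.integer(s),
        model = if (inherits(m, "en_model")) "elastic_net" else "surrogate",
        pcc = ev$pcc, r2 = ev$r2, n_updates = NA)
    }
  }
  do.call(rbind, out)
}

#' Effect-size agreement with the planted truth
#'
#' For each planted causal variant, the model's predicted delta
#' (alternate allele substituted into the reference) is compared with the
#' planted per-allele additive effect.
#'
#' @param model a trained predictor
#' @param truth a `synthetic_truth`
#' @param ref the `reference_window`
#' @param vt the `variant_table`
#' @param covariates fixed covariate vector for prediction (cohort mean),
#'   or NULL
#' @return list(spearman, sign_concordance, deltas, betas)
#' @export
effect_size_agreement <- function(model, truth, ref, vt,
                                  covariates = NULL) {
  idx <- truth$causal_indices
  if (!length(idx)) stop("no causal variants in the truth object")
  ref_oh <- reference_onehot(ref)
  # per-variant delta for the actual alt allele (not the 3-base average)
  deltas <- vapply(idx, function(j)
    predict_variant_effect(model, ref_oh, vt$records$pos[j],
                           vt$records$alt[j], covariates), numeric(1))
  betas <- truth$beta[idx]
  list(spearman = as.numeric(spearman(deltas, betas)),
       sign_concordance = mean(sign(deltas) == sign(betas)),
       deltas = deltas, betas = betas)
}
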