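# Elastic-net baseline on the dosage design matrix. Supplies the
# cis-heritability proxy (held-out R^2), the comparison PCC/R^2, and the
# nonzero-coefficient support whose size calibrates HSV sets.

#' Fit the elastic-net dosage baseline
#'
#' Fits glmnet with a fixed L1 ratio (`alpha` in glmnet's parameterization)
#' of 0.5 on the unstandardized 0/1/2 dosage matrix, over a 50-value
#' log-spaced penalty grid; the penalty is chosen by best validation R^2.
#' Dosage columns are left unstandardized so coefficients live in
#' per-alt-allele phenotype units, directly comparable to planted effects.
#'
#' @param vt a `variant_table`
#' @param expression named numeric vector of phenotype values
#' @param split named split vector ("train"/"val"/"test")
#' @param l1_ratio elastic-net mixing parameter (fixed at 0.5)
#' @param n_lambda size of the penalty grid
#' @param lambda_min_ratio smallest grid value relative to lambda_max
#' @return object of class `en_model` with coefficients, intercept, chosen
#'   penalty, `n_nonzero`, and val/test metrics
#' @export
fit_elastic_net <- function(vt, expression, split, l1_ratio = 0.5,
                            n_lambda = 50L, lambda_min_ratio = 1e-4) {
  ids_tr <- names(split)[split == "train"]
  ids_va <- names(split)[split == "val"]
  ids_te <- names(split)[split == "test"]
  X <- vt$dosages
  y <- expression[rownames(X)]
  if (sd(y[ids_tr]) == 0) stop("constant expression vector in training split")
  if (n_lambda < 1) stop("empty penalty grid")

  xtr <- X[ids_tr, , drop = FALSE]
  ytr <- y[ids_tr]
  # glmnet's own lambda_max for unstandardized predictors
  yc <- ytr - mean(ytr)
  lam_max <- max(abs(crossprod(xtr, yc))) / (length(ytr) * max(l1_ratio, 1e-3))
  grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                  length.out = n_lambda))
  fit <- glmnet::glmnet(xtr, ytr, alpha = l1_ratio, lambda = grid,
                        standardize = FALSE, thresh = 1e-10)
  pv <- predict(fit, X[ids_va, , drop = FALSE])
  val_r2 <- apply(pv, 2, function(p) r_squared(p, y[ids_va]))
  k <- which.max(val_r2)

  beta <- as.numeric(coef(fit, s = grid[k]))
  intercept <- beta[1]
  beta <- beta[-1]
  pte <- as.numeric(X[ids_te, , drop = FALSE] %*% beta + intercept)
  structure(list(coefficients = beta, intercept = intercept,
                 l1_ratio = l1_ratio, lambda = grid[k],
                 lambda_grid = grid, val_r2_path = unname(val_r2),
                 n_nonzero = sum(beta != 0),
                 val_r2 = unname(val_r2[k]),
                 test_r2 = r_squared(pte, y[ids_te]),
                 test_pcc = pcc(pte, y[ids_te]),
                 split = split),
            class = "en_model")
}

#' @export
print.en_model <- function(x, ...) {
  cat(sprintf("<en_model> l1_ratio=%.2f lambda=%.4g n_nonzero=%d val_R2=%.3f test_R2=%.3f test_PCC=%.3f\n",
              x$l1_ratio, x$lambda, x$n_nonzero, x$val_r2, x$test_r2,
              x$test_pcc))
  invisible(x)
}

#' Predict from an elastic-net model
#' @param object an `en_model`
#' @param newx dosage matrix (individuals x variants)
#' @param ... unused
#' @return numeric predictions
#' @export
predict.en_model <- function(object, newx, ...) {
  as.numeric(newx %*% object$coefficients + object$intercept)
}

#' Elastic-net cis-heritability proxy
#'
#' Held-out (test) R^2 of the fitted baseline, clipped to [0, 1]; used as
#' the cis-heritability estimate and the gene-ranking key.
#'
#' @param en_model a fitted `en_model`
#' @return numeric scalar in [0, 1]
#' @export
estimate_cis_h2 <- function(en_model) {
  min(max(en_model$test_r2, 0), 1)
}

#' Nonzero-coefficient variant support of the baseline
#' @param en_model a fitted `en_model`
#' @return integer indices into the variant table
#' @export
en_support <- function(en_model) which(en_model$coefficients != 0)
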