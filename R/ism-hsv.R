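# In silico mutagenesis: systematically substitute each of the three
# non-reference bases at each position of the *reference* sequence, record
# the change in predicted expression, and average the three substitutions
# into a per-position score. High-scoring variants (HSVs) are the top-n
# observed variants by absolute ISM score, with n matched to the
# elastic-net nonzero-coefficient count.

#' Compute an in-silico mutagenesis map
#'
#' For every requested position p and each non-reference base b, the
#' reference row is replaced by the one-hot of b, the model is evaluated,
#' and the row restored; `score(p) = mean_b [f(mut) - f(ref)]` (signed
#' mean; absolute values are applied only at ranking time). ISM is defined
#' on the reference sequence: personal encodings (rows off the one-hot
#' vertices) are rejected. Mutant predictions are batched for throughput
#' but numerically identical to the one-at-a-time loop.
#'
#' @param model a predictor with a `predict` method (surrogate or affine)
#' @param ref_encoding L x 4 pure one-hot reference encoding
#' @param covariates a single covariate vector held fixed for every mutant
#'   (conventionally the cohort mean), or NULL
#' @param positions 1-based positions to score (default: all L); restricting
#'   to observed variant positions makes HSV selection cheap
#' @param chunk mutant sequences per forward pass
#' @return object of class `ismap`: full-length `score` vector (NA at
#'   unscored positions), `positions`, `f_ref`
#' @export
ism_map <- function(model, ref_encoding, covariates = NULL,
                    positions = NULL, chunk = 96L) {
  L <- nrow(ref_encoding)
  if (!all(ref_encoding %in% c(0, 1)) ||
      any(abs(rowSums(ref_encoding) - 1) > 1e-12))
    stop("ism_map requires a pure one-hot reference encoding")
  if (is.null(positions)) positions <- seq_len(L)
  ref_base <- max.col(ref_encoding[positions, , drop = FALSE])
  cov1 <- if (is.null(covariates)) NULL else matrix(covariates, nrow = 1)
  f_ref <- predict(model, ref_encoding, covariates = cov1)

  # enumerate (position, mutant base) jobs
  jobs <- data.frame(pos = rep(positions, each = 3L),
                     base = unlist(lapply(ref_base, function(rb)
                       setdiff(1:4, rb))))
  deltas <- numeric(nrow(jobs))
  for (s in seq(1L, nrow(jobs), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(jobs))
    sel <- s:e
    arr <- array(ref_encoding, c(L, 4L, length(sel)))
    for (k in seq_along(sel)) {
      p <- jobs$pos[sel[k]]
      arr[p, , k] <- 0
      arr[p, jobs$base[sel[k]], k] <- 1
    }
    cv <- if (is.null(covariates)) NULL else
      matrix(covariates, nrow = length(sel), ncol = length(covariates),
             byrow = TRUE)
    deltas[sel] <- predict(model, arr, covariates = cv) - f_ref
  }
  score <- rep(NA_real_, L)
  score[positions] <- colMeans(matrix(deltas, nrow = 3L))
  structure(list(score = score, positions = positions, f_ref = f_ref),
            class = "ismap")
}

#' @export
print.ismap <- function(x, ...) {
  sc <- x$score[x$positions]
  cat(sprintf("<ismap> %d positions scored, |score| range [%.3g, %.3g], f_ref=%.4g\n",
              length(x$positions), min(abs(sc)), max(abs(sc)), x$f_ref))
  invisible(x)
}

#' Select high-scoring variants from an ISM map
#'
#' Candidates are restricted to positions carrying an observed variant;
#' they are ranked by absolute ISM score (descending), ties broken by
#' genomic position (ascending), and the top `min(n, #variants)` retained.
#'
#' @param ismap an `ismap` covering all variant positions of `vt`
#' @param vt a `variant_table`
#' @param n target set size (the matched elastic-net nonzero count)
#' @return object of class `hsv_set`: data.frame members (variant index,
#'   pos, score, rank) plus `n_target` and the variants' cohort MAF
#' @export
select_hsv <- function(ismap, vt, n) {
  if (n < 0) stop("n must be non-negative")
  pos <- vt$records$pos
  sc <- ismap$score[pos]
  if (anyNA(sc)) stop("ISM map does not cover every observed variant position")
  ord <- order(-abs(sc), pos)
  keep <- ord[seq_len(min(n, length(pos)))]
  members <- data.frame(idx = keep, pos = pos[keep], score = sc[keep],
                        rank = seq_along(keep), maf = vt$maf[keep])
  structure(list(members = members, n_target = as.integer(n),
                 source = "ism"), class = "hsv_set")
}

#' HSV set of the elastic-net baseline (nonzero-coefficient support)
#'
#' @param en_model a fitted `en_model`
#' @param vt the matching `variant_table`
#' @return an `hsv_set` whose scores are the coefficients
#' @export
hsv_from_en <- function(en_model, vt) {
  idx <- en_support(en_model)
  co <- en_model$coefficients[idx]
  ord <- order(-abs(co), vt$records$pos[idx])
  idx <- idx[ord]
  members <- data.frame(idx = idx, pos = vt$records$pos[idx],
                        score = en_model$coefficients[idx],
                        rank = seq_along(idx), maf = vt$maf[idx])
  structure(list(members = members, n_target = length(idx),
                 source = "elastic_net"), class = "hsv_set")
}

#' @export
print.hsv_set <- function(x, ...) {
  cat(sprintf("<hsv_set> %d/%d members (source: %s), mean MAF %.3f\n",
              nrow(x$members), x$n_target, x$source,
              mean(x$members$maf)))
  invisible(x)
}

#' Predicted effect of substituting a single variant into the reference
#'
#' `delta = f(reference with the alternate allele substituted) -
#' f(reference)`; the sign carries the predicted direction of effect.
#'
#' @param model a predictor
#' @param ref_encoding L x 4 reference one-hot
#' @param pos 1-based window position of the variant
#' @param alt alternate base ("A"/"C"/"G"/"T")
#' @param covariates fixed covariate vector or NULL
#' @return scalar predicted expression change
#' @export
predict_variant_effect <- function(model, ref_encoding, pos, alt,
                                   covariates = NULL) {
  L <- nrow(ref_encoding)
  if (pos < 1 || pos > L) stop("variant position outside the window")
  cov1 <- if (is.null(covariates)) NULL else matrix(covariates, nrow = 1)
  mut <- ref_encoding
  mut[pos, ] <- 0
  mut[pos, match(alt, BASES)] <- 1
  predict(model, mut, covariates = cov1) -
    predict(model, ref_encoding, covariates = cov1)
}
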