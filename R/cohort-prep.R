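# Per-gene sample exclusion, protein selection and train/val/test splitting
# shared by the linear baseline and the deep surrogate.

PROTEIN_ALTERING <- c("missense", "stop_gained", "stop_lost", "start_lost",
                      "frameshift")

#' Exclude individuals carrying protein-altering variants in the gene body
#'
#' Olink-style assays are vulnerable to epitope-binding artifacts, so any
#' individual harboring a missense, stop-gained, stop-lost, start-lost or
#' frameshift variant inside the gene body is removed for that gene.
#' Exclusion is per-gene: the same individual may be retained elsewhere.
#'
#' @param cohort a `cohort_dataset`
#' @param gene_body 0-based half-open window-relative interval
#'   (default: the cohort's own annotation)
#' @return object of class `gene_cohort` with fields retained, excluded
#'   (data.frame id/reason) and the inherited split
#' @export
exclude_protein_altering <- function(cohort, gene_body = cohort$gene_body) {
  ct <- cohort$consequence_table
  hit <- ct[ct$consequence %in% PROTEIN_ALTERING &
              ct$pos > gene_body[1] & ct$pos <= gene_body[2], , drop = FALSE]
  excl_ids <- unique(hit$individual)
  retained <- setdiff(cohort$ids, excl_ids)
  if (!length(retained)) stop("all individuals excluded for this gene")
  reason <- vapply(excl_ids, function(id)
    paste(sort(unique(hit$consequence[hit$individual == id])), collapse = ","),
    "")
  structure(list(retained = retained,
                 excluded = data.frame(id = excl_ids, reason = reason,
                                       row.names = NULL),
                 split = cohort$split[retained]),
            class = "gene_cohort")
}

#' @export
print.gene_cohort <- function(x, ...) {
  cat(sprintf("<gene_cohort> %d retained, %d excluded (train/val/test = %d/%d/%d)\n",
              length(x$retained), nrow(x$excluded),
              sum(x$split == "train"), sum(x$split == "val"),
              sum(x$split == "test")))
  invisible(x)
}

#' Select proteins for modeling
#'
#' A gene is kept iff (1) its missing measurement count is strictly below
#' `missingness_threshold` and (2) it has at least one cis signal variant
#' inside the window that is not protein-altering.
#'
#' @param expression numeric matrix individuals x genes (NAs = missing)
#' @param missingness_threshold maximum tolerated missing count (strict `<`)
#' @param pqtl data.frame(gene, pos, consequence) of cis signal variants;
#'   `consequence` may be NA / "non_coding" for regulatory signals
#' @return character vector of retained gene ids
#' @export
select_proteins <- function(expression, missingness_threshold = 2000L,
                            pqtl) {
  miss <- colSums(is.na(expression))
  ok_miss <- miss < missingness_threshold
  has_cis <- vapply(colnames(expression), function(g) {
    rows <- pqtl[pqtl$gene == g, , drop = FALSE]
    any(!(rows$consequence %in% PROTEIN_ALTERING))
  }, logical(1))
  colnames(expression)[ok_miss & has_cis]
}

#' Split a gene cohort into train/validation/test sets
#'
#' Random permutation given the seed; rounding remainders go to the
#' training split. The same split is reused verbatim by the elastic-net
#' baseline and the surrogate model.
#'
#' @param gene_cohort a `gene_cohort` (or any object with `$retained`)
#' @param fractions train/val/test fractions summing to 1
#' @param seed integer seed
#' @return the `gene_cohort` with a fresh `split` assignment
#' @export
split_cohort <- function(gene_cohort, fractions = c(0.6, 0.2, 0.2),
                         seed = 1L) {
  gene_cohort$split <- .assign_split(gene_cohort$retained, fractions, seed)
  gene_cohort
}

#' Nested downsampled training cohorts
#'
#' Draws nested subsets (`sizes[1]` is a subset of `sizes[2]`, ...) from the
#' training split only; validation and test sets are untouched so the
#' held-out individuals are identical across all cohort sizes.
#'
#' @param split named split vector ("train"/"val"/"test")
#' @param sizes increasing training-subset sizes
#' @param seed integer seed
#' @return named list of id vectors, one per size
#' @export
nested_subsets <- function(split, sizes = c(200L, 500L, 1000L, 5000L),
                           seed = 1L) {
  train_ids <- names(split)[split == "train"]
  sizes <- sort(sizes)
  if (max(sizes) > length(train_ids))
    stop(sprintf("requested size %d exceeds the training split (%d)",
                 max(sizes), length(train_ids)))
  set.seed(seed)
  ord <- sample(train_ids)
  setNames(lapply(sizes, function(s) ord[seq_len(s)]), as.character(sizes))
}
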