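# Shared fixtures (all generated in code; nothing on disk).

# a small gene dataset for fast unit tests
tiny_gene <- function(seed = 1L, L = 512L, n = 150L, n_sites = 30L,
                      n_causal = 6L, h2 = 0.5, rare_var_share = 0, ...) {
  # rare_var_share defaults to 0: tiny unit-test cohorts often carry no
  # MAF < 0.05 variant at all
  simulate_gene_dataset(L = L, n = n, n_sites = n_sites,
                        n_causal = n_causal, h2 = h2,
                        rare_var_share = rare_var_share, seed = seed, ...)
}

# naive per-individual encoder: builds the consensus base-by-base and
# one-hot encodes it, handling het sites with the 0/0.5/1 dosage
# convention; the independent oracle for encode_cohort
naive_encode_one <- function(ref, vt, id) {
  L <- ref$length
  m <- matrix(0, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  bases <- strsplit(ref$seq, "")[[1]]
  for (p in seq_len(L)) {
    j <- match(p, vt$records$pos)
    if (!is.na(j)) {
      d <- vt$dosages[id, j]
      m[p, vt$records$ref[j]] <- 1 - d / 2
      m[p, vt$records$alt[j]] <- m[p, vt$records$alt[j]] + d / 2
    } else {
      m[p, bases[p]] <- 1
    }
  }
  m
}

# an affine model whose variant-effect deltas equal a chosen per-variant
# coefficient vector (delta for variant j = coefs[j])
affine_from_coefs <- function(ref, vt, coefs, intercept = 0) {
  W <- matrix(0, ref$length, 4L)
  for (j in seq_len(n_variants(vt))) {
    W[vt$records$pos[j], match(vt$records$alt[j], c("A", "C", "G", "T"))] <-
      coefs[j]
  }
  affine_predictor(W, b = intercept)
}

# a deterministic split vector without touching the RNG
fixed_split <- function(ids, n_train, n_val, n_test) {
  stats::setNames(rep(c("train", "val", "test"),
                      c(n_train, n_val, n_test)), ids)
}
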