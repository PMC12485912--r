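# Dosage-weighted one-hot encoding of personal genomes.
#
# Channel order is (A, C, G, T). A position without a variant is the pure
# one-hot of the reference base. At a biallelic SNV with per-individual
# dosage d in {0, 1, 2}, the alt channel carries d/2 and the ref channel
# 1 - d/2, so every row stays on the simplex (rows always sum to 1).

#' One-hot encode a reference window
#'
#' @param ref a `reference_window`
#' @return L x 4 matrix over channels (A, C, G, T)
#' @export
reference_onehot <- function(ref) {
  idx <- match(strsplit(ref$seq, "")[[1]], BASES)
  m <- matrix(0, ref$length, 4L, dimnames = list(NULL, BASES))
  m[cbind(seq_len(ref$length), idx)] <- 1
  m
}

#' Batch-encode a cohort of personal genomes
#'
#' Reconstructs the L x 4 dosage-weighted one-hot matrix for each requested
#' individual in a single pass over the variant table: for every variant the
#' affected row is rewritten across all individuals at once. Output is
#' bit-identical to building each individual's consensus sequence
#' base-by-base.
#'
#' Non-SNV records (multi-base alleles) are skipped with a warning; a ref
#' allele that does not match the reference sequence is an error.
#'
#' @param ref a `reference_window`
#' @param vt a `variant_table` whose positions are window-relative (1-based)
#' @param individuals character vector of individual ids (default: all)
#' @return 3-d array `[L, 4, n]` with individual ids on the third dimension
#' @export
encode_cohort <- function(ref, vt, individuals = rownames(vt$dosages)) {
  miss <- setdiff(individuals, rownames(vt$dosages))
  if (length(miss))
    stop("unknown individual(s): ", paste(miss, collapse = ", "))
  rec <- vt$records
  if (any(rec$pos < 1L | rec$pos > ref$length))
    stop("variant position outside [1, L]")
  snv <- nchar(rec$ref) == 1L & nchar(rec$alt) == 1L
  if (any(!snv)) {
    warning(sprintf("skipping %d non-SNV record(s)", sum(!snv)))
    rec <- rec[snv, , drop = FALSE]
  }
  base_at <- substring(ref$seq, rec$pos, rec$pos)
  bad <- which(base_at != rec$ref)
  if (length(bad))
    stop(sprintf("ref allele mismatch with reference sequence at window position(s) %s",
                 paste(rec$pos[bad], collapse = ", ")))

  n <- length(individuals)
  L <- ref$length
  arr <- array(reference_onehot(ref), dim = c(L, 4L, n),
               dimnames = list(NULL, BASES, individuals))
  dos <- vt$dosages[individuals, snv, drop = FALSE]
  ref_ch <- match(rec$ref, BASES)
  alt_ch <- match(rec$alt, BASES)
  for (j in seq_len(nrow(rec))) {
    half <- dos[, j] / 2
    arr[rec$pos[j], ref_ch[j], ] <- 1 - half
    arr[rec$pos[j], alt_ch[j], ] <- half
  }
  arr
}

#' Extract a TSS-centred window from a genome FASTA
#'
#' The window is the 0-based half-open interval
#' `[tss - 1 - floor(L/2), tss - 1 - floor(L/2) + L)` on the reference
#' (+) strand, so the TSS sits at offset `floor(L/2)`. VCF/GFF-style
#' coordinates are 1-based; all internal window coordinates are 0-based
#' half-open, and this function is the only place the conversion happens.
#'
#' @param genome a `Biostrings::DNAStringSet` (e.g. from
#'   [Biostrings::readDNAStringSet()]) or the path to a FASTA file
#' @param chrom chromosome name
#' @param tss 1-based TSS position
#' @param length window length in bp
#' @return a `reference_window`
#' @export
extract_window <- function(genome, chrom, tss, length) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  k <- match(chrom, nm)
  if (is.na(k)) stop("unknown chromosome: ", chrom)
  start0 <- tss - 1L - floor(length / 2)          # 0-based
  if (start0 < 0 || start0 + length > Biostrings::width(genome)[k])
    stop(sprintf("window [%d, %d) out of bounds for %s (length %d)",
                 start0, start0 + length, chrom,
                 Biostrings::width(genome)[k]))
  s <- as.character(Biostrings::subseq(genome[[k]], start0 + 1L,
                                       start0 + length))
  reference_window(chrom, start0, toupper(s), tss_offset = floor(length / 2))
}

#' Mask rare variants by minor allele frequency
#'
#' Returns a copy of the variant table in which the dosage columns of all
#' variants with cohort MAF strictly below `threshold` are set to 0 for
#' every individual ("replaced by the reference allele"); variants at or
#' above the threshold are untouched. The stored MAF is the original cohort
#' MAF (masking is an encoding-time intervention, and downstream MAF
#' stratification always refers to the full cohort). Masking is idempotent.
#'
#' @param vt a `variant_table`
#' @param threshold MAF threshold in (0, 0.5]
#' @return a `variant_table` with zeroed dosages at masked sites
#' @export
mask_by_maf <- function(vt, threshold) {
  if (threshold <= 0 || threshold > 0.5)
    stop("threshold must lie in (0, 0.5]")
  out <- vt
  masked <- vt$maf < threshold
  out$dosages[, masked] <- 0L
  out$masked <- masked
  out
}

#' Recover variants from an encoding (round trip)
#'
#' Given one individual's encoding and the reference, returns the window
#' positions whose row is not the pure reference one-hot, with the inferred
#' dosage (1 for a 0.5 alt channel, 2 for a full alt channel).
#'
#' @param enc L x 4 encoding matrix
#' @param ref the `reference_window`
#' @return data.frame(pos, alt, dosage)
#' @export
decode_variants <- function(enc, ref) {
  ref_oh <- reference_onehot(ref)
  diff_rows <- which(rowSums(abs(enc - ref_oh)) > 0)
  if (!length(diff_rows))
    return(data.frame(pos = integer(0), alt = character(0),
                      dosage = integer(0)))
  ref_idx <- max.col(ref_oh[diff_rows, , drop = FALSE])
  out <- lapply(seq_along(diff_rows), function(k) {
    row <- enc[diff_rows[k], ]
    alt_ch <- setdiff(which(row > 0), ref_idx[k])
    data.frame(pos = diff_rows[k], alt = BASES[alt_ch],
               dosage = as.integer(round(2 * row[alt_ch])))
  })
  do.call(rbind, out)
}
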