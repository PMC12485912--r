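# Synthetic cohort generator: reference window, cohort genotypes under a
# rare-heavy site-frequency spectrum, planted cis architecture at a target
# heritability, NPX-like expression with covariates, annotation tracks and
# PWMs. Every generator is a pure function of (parameters, seed).

# -- deterministic per-site sub-seeds (< 2^31, exact in double arithmetic) --
.site_seed <- function(seed, j, k = 0L) {
  as.integer((abs(seed) * 48271 + j * 69621 + k * 16807) %% 2147483563) + 1L
}

#' Construct a reference window object
#'
#' @param chrom chromosome identifier
#' @param start 0-based half-open genomic start of the window
#' @param sequence character string over \{A,C,G,T\}
#' @param tss_offset 0-based index of the TSS within the window
#' @return an object of class `reference_window`
#' @export
reference_window <- function(chrom, start, sequence, tss_offset) {
  L <- nchar(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence contains characters outside {A,C,G,T}")
  if (tss_offset < 0 || tss_offset >= L)
    stop("tss_offset must lie within [0, L)")
  structure(list(chrom = chrom, start = as.integer(start), length = L,
                 tss_offset = as.integer(tss_offset), seq = sequence),
            class = "reference_window")
}

#' @export
print.reference_window <- function(x, ...) {
  cat(sprintf("<reference_window> %s:%d-%d (L=%d, TSS offset %d)\n",
              x$chrom, x$start, x$start + x$length, x$length, x$tss_offset))
  invisible(x)
}

#' Simulate a reference sequence window
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = `gc`; the TSS is placed at
#' index `floor(length/2)` (0-based).
#'
#' @param length window length in bp
#' @param gc target GC fraction, in (0, 1)
#' @param seed integer seed
#' @param chrom chromosome label for the synthetic contig
#' @param start 0-based genomic start
#' @return a `reference_window`
#' @export
simulate_reference <- function(length, gc = 0.41, seed = 1L,
                               chrom = "chrS", start = 100000L) {
  if (length <= 0) stop("length must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly inside (0, 1)")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  reference_window(chrom, start, s, tss_offset = floor(length / 2))
}

#' Construct a variant table
#'
#' @param records data.frame with columns `pos` (1-based index within the
#'   window), `ref`, `alt` (single bases)
#' @param dosages integer matrix individuals x variants with entries 0/1/2;
#'   rownames are individual ids
#' @param ref the `reference_window` the positions refer to (checked)
#' @return an object of class `variant_table`
#' @export
variant_table <- function(records, dosages, ref = NULL) {
  stopifnot(is.data.frame(records), nrow(records) == ncol(dosages))
  if (anyDuplicated(records[, c("pos", "alt")]))
    stop("duplicate (position, alt) records")
  if (anyDuplicated(records$pos))
    stop("two variant records at the same position are not supported")
  if (any(records$ref == records$alt)) stop("ref allele equals alt allele")
  if (!all(dosages %in% 0:2)) stop("dosages must be 0, 1 or 2")
  if (!is.null(ref)) {
    base_at <- substring(ref$seq, records$pos, records$pos)
    bad <- which(base_at != records$ref)
    if (length(bad))
      stop(sprintf("variant ref allele mismatches reference at position(s) %s",
                   paste(records$pos[bad], collapse = ", ")))
  }
  af <- colMeans(dosages) / 2
  structure(list(records = records, dosages = dosages,
                 af = unname(af), maf = unname(pmin(af, 1 - af))),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d biallelic SNVs x %d individuals (%d with MAF < 0.01)\n",
              nrow(x$records), nrow(x$dosages), sum(x$maf < 0.01)))
  invisible(x)
}

#' Number of variants / individuals in a variant table
#' @param vt a `variant_table`
#' @return integer count
#' @export
n_variants <- function(vt) nrow(vt$records)

#' @rdname n_variants
#' @export
n_individuals <- function(vt) nrow(vt$dosages)

#' Simulate cohort genotypes over a reference window
#'
#' Site positions and population alternate-allele frequencies are drawn once
#' from the main seed; frequencies come from a rare-heavy mixture of
#' Beta(0.2, 8) (weight `maf_mix$w_rare`) and Uniform(0.05, 0.5). Per-site
#' dosages are drawn at Hardy-Weinberg proportions from a deterministic
#' per-site RNG stream, so cohorts of different sizes generated with the
#' same seed are nested (the first `n` individuals agree). Sites that are
#' monomorphic in the realized cohort are dropped, so every stored record
#' has MAF > 0. An optional block-LD mode copies each site from its
#' predecessor with a per-individual flip probability.
#'
#' @param ref a `reference_window`
#' @param n number of individuals (>= 2)
#' @param n_sites number of candidate variant sites (< window length)
#' @param maf_mix list(w_rare, beta = c(a, b), unif = c(lo, hi))
#' @param seed integer seed
#' @param ld optional list(block, flip) switching on block-LD mode
#' @return a `variant_table`; individual ids are "I000001", ...
#' @export
simulate_cohort <- function(ref, n, n_sites,
                            maf_mix = list(w_rare = 0.7, beta = c(0.2, 8),
                                           unif = c(0.05, 0.5)),
                            seed = 1L, ld = NULL) {
  if (n < 2) stop("need at least 2 individuals")
  if (n_sites >= ref$length) stop("n_sites must be smaller than the window length")
  set.seed(seed)
  pos <- sort(sample.int(ref$length, n_sites))
  rare <- runif(n_sites) < maf_mix$w_rare
  f <- ifelse(rare,
              rbeta(n_sites, maf_mix$beta[1], maf_mix$beta[2]),
              runif(n_sites, maf_mix$unif[1], maf_mix$unif[2]))
  f <- pmin(f, 0.5)
  ref_base <- substring(ref$seq, pos, pos)
  alt_base <- vapply(ref_base, function(b) sample(setdiff(BASES, b), 1), "")

  dos <- matrix(0L, n, n_sites)
  for (j in seq_len(n_sites)) {
    if (!is.null(ld) && (j - 1L) %% ld$block != 0L) {
      set.seed(.site_seed(seed, j, 1L))
      keep <- runif(n) >= ld$flip
      set.seed(.site_seed(seed, j, 2L))
      fresh <- rbinom(n, 2L, f[j])
      dos[, j] <- ifelse(keep, dos[, j - 1L], fresh)
    } else {
      set.seed(.site_seed(seed, j, 0L))
      dos[, j] <- rbinom(n, 2L, f[j])
    }
  }
  poly <- apply(dos, 2, function(d) length(unique(d)) > 1L)
  dos <- dos[, poly, drop = FALSE]
  rownames(dos) <- sprintf("I%06d", seq_len(n))
  rec <- data.frame(pos = pos[poly], ref = ref_base[poly],
                    alt = unname(alt_base[poly]), stringsAsFactors = FALSE)
  variant_table(rec, dos, ref = ref)
}

#' Compute the genetic component implied by a planted truth
#'
#' @param truth a `synthetic_truth`
#' @param vt the `variant_table` the truth was planted on
#' @return numeric vector, one value per individual
#' @export
genetic_component <- function(truth, vt) {
  g <- as.vector(vt$dosages %*% truth$beta)
  if (!is.null(truth$interactions) && nrow(truth$interactions)) {
    for (r in seq_len(nrow(truth$interactions))) {
      ii <- truth$interactions$i[r]; jj <- truth$interactions$j[r]
      g <- g + truth$interactions$coef[r] * vt$dosages[, ii] * vt$dosages[, jj]
    }
  }
  g
}

#' Plant a cis genetic architecture on a cohort
#'
#' Chooses `n_causal` causal variants, splits them between the rare
#' (MAF < 0.05) and common pools, and scales per-group additive effects so
#' that, empirically on this cohort, Var(genetic)/Var(total) equals `h2`
#' and the rare causal subset contributes `rare_var_share` of the additive
#' genetic variance. Total phenotypic variance is normalized to ~1, so
#' `sigma_e = sqrt(1 - h2 - var_covariates)` is stored on the truth object.
#'
#' Interactions: either pass explicit pairs via
#' `interactions = data.frame(i, j, coef)` (coefficients kept verbatim;
#' additive effects are scaled to make up the remainder of `h2`), or request
#' `n_interactions` pairs carrying `interaction_share` of the genetic
#' variance; pairs are drawn among the most common causal variants so the
#' epistatic term is actually observable in the cohort.
#'
#' @param vt a `variant_table`
#' @param n_causal number of causal variants
#' @param h2 target cis-heritability in [0, 1)
#' @param rare_var_share fraction of additive genetic variance carried by
#'   MAF < 0.05 causal variants
#' @param interactions optional explicit data.frame(i, j, coef)
#' @param n_interactions number of auto-generated interaction pairs
#' @param interaction_share fraction of genetic variance from interactions
#' @param covariate_effects named numeric vector of standardized covariate
#'   coefficients (defaults chosen small so genetic signal dominates)
#' @param seed integer seed
#' @return an object of class `synthetic_truth`
#' @export
plant_effects <- function(vt, n_causal, h2, rare_var_share = 0.5,
                          interactions = NULL, n_interactions = 0L,
                          interaction_share = 0,
                          covariate_effects = NULL, seed = 1L) {
  m <- n_variants(vt)
  if (n_causal > m) stop("n_causal exceeds the number of variants")
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  set.seed(seed)

  if (is.null(covariate_effects))
    covariate_effects <- c(sex = 0.05, age = 0.08, bmi = 0.08,
                           gPC1 = 0.03, gPC2 = 0.03, gPC3 = 0.02,
                           gPC4 = 0.02, gPC5 = 0.02,
                           ePC1 = 0.05, ePC2 = 0.04, ePC3 = 0.03,
                           ePC4 = 0.02, ePC5 = 0.02, egfr = 0.08)
  var_cov <- sum(covariate_effects^2)
  sigma_e <- sqrt(max(1 - h2 - var_cov, 1e-3))

  rare_pool <- which(vt$maf < 0.05)
  common_pool <- which(vt$maf >= 0.05)
  if (rare_var_share > 0 && !length(rare_pool))
    stop("rare_var_share > 0 requested but no MAF < 0.05 variants available")
  if (rare_var_share < 1 && !length(common_pool))
    stop("rare_var_share < 1 requested but no MAF >= 0.05 variants available")

  # interacting variants: pairs within one cis-element (<= 32 bp apart)
  # preferred, among the most common variants, so the epistatic product is
  # both biologically motif-like and observable in the cohort
  int_df <- NULL
  explicit_int <- !is.null(interactions)
  forced <- integer(0)
  if (explicit_int) {
    int_df <- as.data.frame(interactions)
  } else if (n_interactions > 0L) {
    pool <- if (length(common_pool) >= 2L) common_pool else seq_len(m)
    if (length(pool) < 2L * n_interactions)
      stop("not enough variants for the requested interaction pairs")
    cmb <- t(utils::combn(pool, 2L))
    dist <- abs(vt$records$pos[cmb[, 1]] - vt$records$pos[cmb[, 2]])
    score <- vt$maf[cmb[, 1]] * vt$maf[cmb[, 2]]
    ord <- order(dist > 32L, -score)
    pick <- integer(0)
    rows <- integer(0)
    for (r in ord) {
      if (any(cmb[r, ] %in% pick)) next
      rows <- c(rows, r); pick <- c(pick, cmb[r, ])
      if (length(rows) == n_interactions) break
    }
    int_df <- data.frame(i = cmb[rows, 1], j = cmb[rows, 2],
                         coef = rnorm(length(rows)))
    forced <- pick
  }

  n_rare <- if (rare_var_share == 0) 0L else if (rare_var_share == 1) n_causal
            else max(1L, min(round(n_causal / 2), length(rare_pool)))
  n_rare <- min(n_rare, length(rare_pool))
  n_com <- n_causal - n_rare
  if (n_com > length(common_pool)) {
    n_com <- length(common_pool); n_rare <- n_causal - n_com
  }
  com_left <- setdiff(common_pool, forced)
  n_com_draw <- max(n_com - length(forced), 0L)
  ssample <- function(x, k) x[sample.int(length(x), k)]  # length-1 safe
  causal <- c(if (n_rare) ssample(rare_pool, n_rare), forced,
              if (n_com_draw) ssample(com_left, min(n_com_draw,
                                                    length(com_left))))
  causal <- sort(unique(causal))
  is_rare <- vt$maf[causal] < 0.05

  beta <- numeric(m)
  beta[causal] <- rnorm(length(causal))

  g_int <- numeric(nrow(vt$dosages))
  if (!is.null(int_df)) {
    for (r in seq_len(nrow(int_df)))
      g_int <- g_int + int_df$coef[r] *
        vt$dosages[, int_df$i[r]] * vt$dosages[, int_df$j[r]]
  }

  if (h2 == 0) {
    beta[] <- 0
    if (!explicit_int && !is.null(int_df)) int_df$coef <- 0
    truth <- list(causal_indices = causal, beta = beta, interactions = int_df,
                  h2 = h2, sigma_e = sigma_e,
                  covariate_effects = covariate_effects)
    return(structure(truth, class = "synthetic_truth"))
  }

  # scale groups to their variance targets ---------------------------------
  scale_to <- function(x, v) {
    vx <- var(x)
    if (vx < 1e-300) { if (v > 0) stop("degenerate component") else return(0) }
    sqrt(v / vx)
  }
  if (explicit_int) {
    v_int <- if (is.null(int_df)) 0 else var(g_int)
    v_add <- max(h2 - v_int, 0)
    s_int <- NA
  } else {
    s_int <- if (is.null(int_df)) 0 else interaction_share
    v_add <- (1 - s_int) * h2
  }
  X <- vt$dosages
  g_rare <- as.vector(X[, causal[is_rare], drop = FALSE] %*%
                        beta[causal[is_rare]])
  g_com <- as.vector(X[, causal[!is_rare], drop = FALSE] %*%
                       beta[causal[!is_rare]])
  a_r <- if (n_rare) scale_to(g_rare, rare_var_share * v_add) else 0
  a_c <- if (n_com) scale_to(g_com, (1 - rare_var_share) * v_add) else 0
  beta[causal[is_rare]] <- beta[causal[is_rare]] * a_r
  beta[causal[!is_rare]] <- beta[causal[!is_rare]] * a_c

  if (!explicit_int && !is.null(int_df)) {
    a_i <- scale_to(g_int, s_int * h2)
    int_df$coef <- int_df$coef * a_i
  }

  truth <- structure(list(causal_indices = causal, beta = beta,
                          interactions = int_df, h2 = h2, sigma_e = sigma_e,
                          covariate_effects = covariate_effects),
                     class = "synthetic_truth")

  if (!explicit_int) {
    # final rescale so the realized genetic variance hits h2 exactly
    g <- genetic_component(truth, vt)
    s <- sqrt(h2 / var(g))
    truth$beta <- truth$beta * s
    if (!is.null(truth$interactions)) truth$interactions$coef <-
        truth$interactions$coef * s
  }
  truth
}

#' Simulate per-individual covariates
#'
#' Emulates the covariate vector used by the single-gene models: sex, age,
#' BMI, genotype PCs, expression PCs and an eGFR analogue.
#'
#' @param n number of individuals
#' @param n_geno_pc,n_expr_pc numbers of genotype / expression PCs
#' @param seed integer seed
#' @return numeric matrix with rownames "I000001", ...
#' @export
simulate_covariates <- function(n, n_geno_pc = 5L, n_expr_pc = 5L, seed = 1L) {
  set.seed(seed)
  cv <- cbind(sex = rbinom(n, 1, 0.5),
              age = rnorm(n, 57, 8),
              bmi = rnorm(n, 27.4, 4.7))
  g <- matrix(rnorm(n * n_geno_pc), n)
  colnames(g) <- paste0("gPC", seq_len(n_geno_pc))
  e <- matrix(rnorm(n * n_expr_pc), n)
  colnames(e) <- paste0("ePC", seq_len(n_expr_pc))
  cv <- cbind(cv, g, e, egfr = rnorm(n, 90, 13))
  rownames(cv) <- sprintf("I%06d", seq_len(n))
  cv
}

#' Simulate NPX-like expression and assemble a cohort dataset
#'
#' expression = genetic component (from `truth`) + standardized-covariate
#' effects + N(0, sigma_e^2). The genetic component is fully determined by
#' `(truth, vt)`; only noise, the consequence table and the split use the
#' seed, so two seeds share an identical genetic component. A configurable
#' fraction of individuals is flagged as carrying a protein-altering
#' variant inside the gene body (consequence table only; sequences are not
#' edited).
#'
#' @param truth a `synthetic_truth`
#' @param vt a `variant_table`
#' @param covariates matrix from [simulate_covariates()], or NULL
#' @param sigma_e environmental noise SD (default: value stored on `truth`)
#' @param seed integer seed
#' @param pa_fraction fraction of individuals carrying a protein-altering hit
#' @param gene_body 0-based half-open window-relative interval (default:
#'   TSS to TSS + L/4, clipped)
#' @param split train/val/test fractions
#' @return an object of class `cohort_dataset` with fields ids, expression,
#'   covariates, consequence_table, split, gene_body
#' @export
simulate_expression <- function(truth, vt, covariates = NULL,
                                sigma_e = truth$sigma_e, seed = 1L,
                                pa_fraction = 0.05, gene_body = NULL,
                                split = c(0.6, 0.2, 0.2)) {
  if (sigma_e < 0) stop("sigma_e must be non-negative")
  n <- n_individuals(vt)
  ids <- rownames(vt$dosages)
  g <- genetic_component(truth, vt)
  ce <- numeric(n)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    cs <- scale(covariates)
    cs[, attr(cs, "scaled:scale") == 0] <- 0
    gamma <- truth$covariate_effects[colnames(covariates)]
    gamma[is.na(gamma)] <- 0
    ce <- as.vector(cs %*% gamma)
  }
  set.seed(seed)
  y <- g + ce + rnorm(n, 0, sigma_e)
  names(y) <- ids

  L <- max(vt$records$pos)
  if (is.null(gene_body)) {
    tssish <- floor(stats::median(vt$records$pos))
    gene_body <- c(tssish, min(tssish + max(256L, L %/% 4L), L))
  }
  carrier <- runif(n) < pa_fraction
  pa_classes <- c("missense", "stop_gained", "stop_lost", "start_lost",
                  "frameshift")
  cons <- data.frame(individual = character(0), pos = integer(0),
                     consequence = character(0))
  if (any(carrier)) {
    k <- sum(carrier)
    cons <- data.frame(
      individual = ids[carrier],
      pos = sample(seq(gene_body[1] + 1L, gene_body[2]), k, replace = TRUE),
      consequence = sample(pa_classes, k, replace = TRUE))
  }
  syn_ids <- ids[!carrier][runif(sum(!carrier)) < 0.1]
  if (length(syn_ids)) {
    cons <- rbind(cons, data.frame(
      individual = syn_ids,
      pos = sample(seq(gene_body[1] + 1L, gene_body[2]), length(syn_ids),
                   replace = TRUE),
      consequence = "synonymous"))
  }

  spl <- .assign_split(ids, split, seed = seed)
  structure(list(ids = ids, expression = y,
                 covariates = covariates, consequence_table = cons,
                 split = spl, gene_body = gene_body),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d individuals (%d train / %d val / %d test), %d consequence rows\n",
              length(x$ids), sum(x$split == "train"), sum(x$split == "val"),
              sum(x$split == "test"), nrow(x$consequence_table)))
  invisible(x)
}

#' Simulate annotation tracks and PWMs for a window
#'
#' Produces (1) a ChromHMM-style tiling track whose per-state coverage
#' matches `state_config` up to one segment of rounding, with the remainder
#' labeled "Quies"; (2) a sparse cCRE-style track with the five ENCODE
#' classes; (3) `n_pwms` synthetic PWMs.
#'
#' @param ref a `reference_window`
#' @param state_config named list/vector of per-state coverage fractions
#'   (sum must be <= 1)
#' @param ccre_config named vector of per-class coverage fractions
#' @param n_pwms number of PWMs to generate
#' @param seed integer seed
#' @param segment tiling segment size in bp
#' @return list(chromhmm = annotation_track, ccre = annotation_track,
#'   pwms = list of `pwm`)
#' @export
simulate_annotations <- function(ref,
                                 state_config = c(TssA = 0.03, EnhA = 0.07,
                                                  Tx = 0.25, ReprPC = 0.10),
                                 ccre_config = c(PLS = 0.01, pELS = 0.02,
                                                 dELS = 0.04,
                                                 `DNase-H3K4me3` = 0.01,
                                                 `CTCF-only` = 0.01),
                                 n_pwms = 5L, seed = 1L, segment = 128L) {
  state_config <- unlist(state_config)
  if (sum(state_config) > 1) stop("state coverage fractions sum to more than 1")
  if (sum(ccre_config) > 1) stop("cCRE coverage fractions sum to more than 1")
  L <- ref$length
  set.seed(seed)

  n_seg <- ceiling(L / segment)
  counts <- round(state_config * n_seg)
  counts <- pmin(counts, n_seg)
  while (sum(counts) > n_seg) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  lab <- c(rep(names(counts), counts), rep("Quies", n_seg - sum(counts)))
  lab <- sample(lab)
  starts <- (seq_len(n_seg) - 1L) * segment
  ends <- pmin(starts + segment, L)
  keep <- c(TRUE, lab[-1] != lab[-n_seg])
  tile <- data.frame(start = starts[keep],
                     end = ends[c(which(keep)[-1] - 1L, n_seg)],
                     label = lab[keep], stringsAsFactors = FALSE)
  chromhmm <- annotation_track(tile, type = "tiling", L = L)

  # sparse cCRE intervals, non-overlapping, placed greedily
  occupied <- integer(0)
  rows <- list()
  for (cls in names(ccre_config)) {
    budget <- round(ccre_config[[cls]] * L)
    while (budget >= 150L) {
      w <- min(sample(150:350, 1), budget)
      for (try in 1:50) {
        s <- sample.int(L - w, 1) - 1L
        if (!any(occupied >= s & occupied < s + w)) break
      }
      occupied <- c(occupied, s, s + w - 1L)
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = s + w,
                                              label = cls)
      budget <- budget - w
    }
  }
  ccre_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), label = character(0))
  ccre <- annotation_track(ccre_df[order(ccre_df$start), , drop = FALSE],
                           type = "sparse", L = L)

  pwms <- lapply(seq_len(n_pwms), function(i) {
    w <- sample(8:12, 1)
    mat <- vapply(seq_len(w), function(j) {
      dom <- sample.int(4, 1)
      q <- runif(1, 0.7, 0.95)
      p <- rep((1 - q) / 3, 4); p[dom] <- q
      p
    }, numeric(4))
    rownames(mat) <- BASES
    pwm(sprintf("SYN_MOTIF_%02d", i), mat)
  })
  list(chromhmm = chromhmm, ccre = ccre, pwms = pwms)
}

#' Construct an annotation track
#'
#' @param intervals data.frame(start, end, label); 0-based half-open,
#'   window-relative
#' @param type "tiling" (disjoint, covers `[0, L)`) or "sparse"
#' @param L window length (required to validate a tiling track)
#' @return object of class `annotation_track`
#' @export
annotation_track <- function(intervals, type = c("sparse", "tiling"),
                             L = NULL) {
  type <- match.arg(type)
  stopifnot(all(c("start", "end", "label") %in% names(intervals)))
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  if (nrow(intervals) && !is.null(L) &&
      (min(intervals$start) < 0 || max(intervals$end) > L))
    stop("intervals extend outside [0, L)")
  if (type == "tiling") {
    if (is.null(L)) stop("L is required for a tiling track")
    if (nrow(intervals) == 0 || intervals$start[1] != 0 ||
        intervals$end[nrow(intervals)] != L ||
        (nrow(intervals) > 1 &&
         any(intervals$start[-1] != intervals$end[-nrow(intervals)])))
      stop("tiling track must cover [0, L) without gaps or overlap")
  }
  structure(list(intervals = intervals, type = type, L = L),
            class = "annotation_track")
}

#' Per-label coverage fractions of a track
#' @param track an `annotation_track`
#' @param L window length (defaults to the track's)
#' @return named numeric vector of coverage fractions
#' @export
track_coverage <- function(track, L = track$L) {
  iv <- track$intervals
  if (!nrow(iv)) return(setNames(numeric(0), character(0)))
  tapply(iv$end - iv$start, iv$label, sum) / L
}

#' Construct a position weight matrix object
#'
#' @param id motif identifier
#' @param mat 4 x w probability matrix, rows A/C/G/T, columns summing to 1
#' @param bg background base frequencies (length 4, sums to 1)
#' @param pseudocount added to every cell before log-odds scoring
#' @return object of class `pwm`
#' @export
pwm <- function(id, mat, bg = rep(0.25, 4), pseudocount = 1e-3) {
  stopifnot(nrow(mat) == 4)
  if (any(abs(colSums(mat) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  if (abs(sum(bg) - 1) > 1e-9) stop("background must sum to 1")
  if (pseudocount == 0 && any(mat <= 0))
    stop("zero-probability PWM cell without pseudocount")
  rownames(mat) <- BASES
  names(bg) <- BASES
  structure(list(id = id, w = ncol(mat), mat = mat, bg = bg,
                 pseudocount = pseudocount), class = "pwm")
}

# internal: split assignment shared with cohort_prep
.assign_split <- function(ids, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  n <- length(ids)
  if (n < 5) stop("fewer than 5 individuals cannot be split")
  set.seed(seed)
  perm <- sample(n)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test           # remainder goes to training
  lab <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  spl <- character(n)
  spl[perm] <- lab
  setNames(spl, ids)
}

#' Generate a complete synthetic single-gene dataset
#'
#' Convenience wrapper chaining [simulate_reference()], [simulate_cohort()],
#' [plant_effects()], [simulate_covariates()] and [simulate_expression()]
#' with a single master seed (sub-seeds are derived deterministically).
#'
#' @param L window length (desk default 4096)
#' @param n cohort size
#' @param n_sites candidate variant sites
#' @param n_causal causal variants
#' @param h2 target cis-heritability
#' @param rare_var_share additive genetic variance from MAF < 0.05 variants
#' @param n_interactions,interaction_share epistatic pairs (see
#'   [plant_effects()])
#' @param with_covariates include the covariate block
#' @param pa_fraction protein-altering carrier fraction
#' @param seed master seed
#' @param ld optional block-LD parameters for [simulate_cohort()]
#' @return list(ref, vt, truth, covariates, cohort)
#' @export
simulate_gene_dataset <- function(L = 4096L, n = 2000L, n_sites = 160L,
                                  n_causal = 20L, h2 = 0.5,
                                  rare_var_share = 0.5,
                                  n_interactions = 0L, interaction_share = 0,
                                  with_covariates = TRUE,
                                  pa_fraction = 0.05, seed = 1L, ld = NULL) {
  ref <- simulate_reference(L, seed = .site_seed(seed, 1L, 3L))
  vt <- simulate_cohort(ref, n, n_sites, seed = .site_seed(seed, 2L, 3L),
                        ld = ld)
  truth <- plant_effects(vt, n_causal, h2, rare_var_share = rare_var_share,
                         n_interactions = n_interactions,
                         interaction_share = interaction_share,
                         seed = .site_seed(seed, 3L, 3L))
  cov <- if (with_covariates)
    simulate_covariates(n, seed = .site_seed(seed, 4L, 3L)) else NULL
  cohort <- simulate_expression(truth, vt, cov, seed = .site_seed(seed, 5L, 3L),
                                pa_fraction = pa_fraction)
  list(ref = ref, vt = vt, truth = truth, covariates = cov, cohort = cohort)
}
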