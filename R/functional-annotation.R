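# HSV characterization statistics: ChromHMM-state enrichment
# (observed/expected), cCRE overlap fractions, PWM log-odds motif-effect
# classification with exact dynamic-programming p-values, and LD-redundancy
# fractions.

CCRE_CLASSES <- c("PLS", "pELS", "dELS", "DNase-H3K4me3", "CTCF-only")

# label of a tiling track at a set of 1-based window positions
.tiling_label_at <- function(track, pos) {
  iv <- track$intervals
  k <- findInterval(pos - 1L, iv$start)      # positions are 0-based inside
  iv$label[k]
}

#' ChromHMM-state enrichment of HSVs
#'
#' For each gene, the expected count per state is the state's coverage
#' fraction of the window times the gene's HSV count (uniform-placement
#' null). Observed and expected are summed across genes before taking the
#' single observed/expected ratio per state.
#'
#' @param hsv_sets list of `hsv_set`, one per gene
#' @param tracks list of tiling `annotation_track`, parallel to `hsv_sets`
#' @param groups optional named vector mapping state labels to groups
#'   (e.g. c(TssA = "promoter", EnhA = "enhancer"), unmapped -> "other")
#' @return data.frame(state, group, observed, expected, ratio)
#' @export
chromhmm_enrichment <- function(hsv_sets, tracks, groups = NULL) {
  stopifnot(length(hsv_sets) == length(tracks))
  obs <- list(); exp <- list()
  for (g in seq_along(hsv_sets)) {
    track <- tracks[[g]]
    if (track$type != "tiling") stop("enrichment requires tiling tracks")
    pos <- hsv_sets[[g]]$members$pos
    if (length(pos) && (min(pos) < 1 || max(pos) > track$L))
      stop("HSV outside window")
    cov <- track_coverage(track)
    n_hsv <- length(pos)
    o <- table(factor(.tiling_label_at(track, pos), levels = names(cov)))
    for (st in names(cov)) {
      obs[[st]] <- (obs[[st]] %||% 0) + o[[st]]
      exp[[st]] <- (exp[[st]] %||% 0) + cov[[st]] * n_hsv
    }
  }
  states <- names(obs)
  res <- data.frame(state = states,
                    group = if (is.null(groups)) NA_character_ else
                      ifelse(is.na(groups[states]), "other",
                             groups[states]),
                    observed = unlist(obs[states]),
                    expected = unlist(exp[states]),
                    row.names = NULL)
  res$ratio <- ifelse(res$expected > 0, res$observed / res$expected, NA)
  res
}

#' Fraction of HSVs overlapping candidate cis-regulatory elements
#'
#' Each HSV position is assigned to the class of the cCRE interval covering
#' it; if intervals of different classes overlap the position, the
#' higher-priority class wins (PLS > pELS > dELS > DNase-H3K4me3 >
#' CTCF-only) with a warning. Positions covered by no element count as
#' "none". Fractions are aggregated over all genes' HSVs.
#'
#' @param hsv_sets list of `hsv_set` per gene
#' @param ccre_tracks list of sparse `annotation_track` per gene
#' @return list(overall = fraction in any element, by_class = named
#'   fractions incl. "none", n = total HSVs)
#' @export
ccre_overlap_fraction <- function(hsv_sets, ccre_tracks) {
  stopifnot(length(hsv_sets) == length(ccre_tracks))
  counts <- setNames(numeric(length(CCRE_CLASSES) + 1L),
                     c(CCRE_CLASSES, "none"))
  total <- 0L
  warned <- FALSE
  for (g in seq_along(hsv_sets)) {
    iv <- ccre_tracks[[g]]$intervals
    for (p in hsv_sets[[g]]$members$pos) {
      hit <- iv$label[iv$start < p & iv$end >= p]   # p is 1-based
      cls <- "none"
      if (length(hit)) {
        if (length(unique(hit)) > 1L && !warned) {
          warning("overlapping cCRE intervals of different classes; ",
                  "resolving by class priority")
          warned <- TRUE
        }
        cls <- CCRE_CLASSES[min(match(hit, CCRE_CLASSES))]
      }
      counts[cls] <- counts[cls] + 1
      total <- total + 1L
    }
  }
  list(overall = unname(1 - counts[["none"]] / max(total, 1L)),
       by_class = counts / max(total, 1L), n = total)
}

# ---- PWM scanning with exact p-values ----------------------------------

# integer log-odds matrix (units of `step` bits) after pseudocount
.pwm_int_scores <- function(pwm, bg, step = 0.01) {
  p <- sweep(pwm$mat + pwm$pseudocount, 2,
             colSums(pwm$mat + pwm$pseudocount), `/`)
  if (any(p <= 0)) stop("zero-probability PWM cell without pseudocount")
  s <- log2(p / bg)
  list(real = s, int = round(s / step), step = step)
}

# exact null distribution of the integer motif score under an i.i.d.
# background, by dynamic programming (one convolution per column)
.pwm_null_dist <- function(int_scores, bg) {
  w <- ncol(int_scores)
  lo <- sum(apply(int_scores, 2, min))
  hi <- sum(apply(int_scores, 2, max))
  probs <- numeric(hi - lo + 1L)          # index = score - lo + 1
  cur_lo <- 0L
  cur <- 1
  for (j in seq_len(w)) {
    smin <- min(int_scores[, j]); smax <- max(int_scores[, j])
    new <- numeric(length(cur) + smax - smin)
    for (b in 1:4) {
      sh <- int_scores[b, j] - smin
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new
    cur_lo <- cur_lo + smin
  }
  list(lo = cur_lo, probs = cur)          # probs[i] = P(S = lo + i - 1)
}

# P(S >= s_int) under the null
.pwm_pvalue <- function(null, s_int) {
  i <- s_int - null$lo + 1L
  if (i <= 1L) return(1)
  if (i > length(null$probs)) return(0)
  sum(null$probs[i:length(null$probs)])
}

# score all placements of a motif over an integer-coded sequence
.scan_scores <- function(seq_int, int_scores, starts) {
  w <- ncol(int_scores)
  vapply(starts, function(s)
    sum(int_scores[cbind(seq_int[s:(s + w - 1L)], seq_len(w))]), numeric(1))
}

#' Classify motif effects of HSVs
#'
#' For each (variant, motif) pair, every placement of the motif that
#' overlaps the SNP and lies fully inside the +/-`scan_halfwidth` bp scan
#' region (truncated at window edges) is scored on the reference and the
#' alternate sequence with log2-odds against an order-0 background
#' estimated from the reference window. The top-scoring hit per allele is
#' retained; p-values come from the exact null score distribution computed
#' by dynamic programming on a 0.01-bit score lattice; a raw-p prefilter
#' (1e-4) is applied before Benjamini-Hochberg correction across the whole
#' scan. Calls: loss (REF significant, ALT not), gain (ALT significant,
#' REF not), weaken/strengthen (both significant and |deltaS| >= 0.5, by
#' sign of deltaS), none otherwise; one collapsed call per variant by
#' max |deltaS|.
#'
#' @param hsv_set an `hsv_set`
#' @param ref a `reference_window`
#' @param vt the `variant_table` (supplies each HSV's alt allele)
#' @param pwms list of `pwm`
#' @param scan_halfwidth half-width of the scan region around each SNP
#' @param q_threshold BH q-value significance threshold
#' @param deltaS_threshold |deltaS| needed to call weaken/strengthen
#' @param p_prefilter raw p-value prefilter applied before BH
#' @param bg optional background base frequencies (default: reference
#'   window composition)
#' @return list(calls = one row per variant, per_motif = all pairs,
#'   fraction_with_effect)
#' @export
motif_effects <- function(hsv_set, ref, vt, pwms, scan_halfwidth = 30L,
                          q_threshold = 0.05, deltaS_threshold = 0.5,
                          p_prefilter = 1e-4, bg = NULL) {
  L <- ref$length
  seq_int <- match(strsplit(ref$seq, "")[[1]], BASES)
  if (is.null(bg)) bg <- tabulate(seq_int, 4L) / L
  bg <- pmax(bg, 1e-9); bg <- bg / sum(bg)

  mot <- lapply(pwms, function(pw) {
    is_ <- .pwm_int_scores(pw, bg)
    list(pw = pw, is_ = is_, null = .pwm_null_dist(is_$int, bg))
  })

  mem <- hsv_set$members
  rows <- list()
  for (k in seq_len(nrow(mem))) {
    v_pos <- mem$pos[k]
    alt <- vt$records$alt[mem$idx[k]]
    lo_r <- max(1L, v_pos - scan_halfwidth)
    hi_r <- min(L, v_pos + scan_halfwidth)
    alt_int <- seq_int
    alt_int[v_pos] <- match(alt, BASES)
    for (m in mot) {
      w <- m$pw$w
      lo_s <- max(lo_r, v_pos - w + 1L, 1L)
      hi_s <- min(v_pos, hi_r - w + 1L, L - w + 1L)
      if (lo_s > hi_s) next
      starts <- lo_s:hi_s
      s_ref <- .scan_scores(seq_int, m$is_$int, starts)
      s_alt <- .scan_scores(alt_int, m$is_$int, starts)
      br <- which.max(s_ref); ba <- which.max(s_alt)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v_pos, motif = m$pw$id,
        ref_score = s_ref[br] * m$is_$step,
        alt_score = s_alt[ba] * m$is_$step,
        deltaS = (s_alt[ba] - s_ref[br]) * m$is_$step,
        ref_p = .pwm_pvalue(m$null, s_ref[br]),
        alt_p = .pwm_pvalue(m$null, s_alt[ba]))
    }
  }
  if (!length(rows))
    return(list(calls = data.frame(), per_motif = data.frame(),
                fraction_with_effect = 0))
  df <- do.call(rbind, rows)

  # BH across the whole scan; prefiltered hits never reach significance
  pool <- c(df$ref_p, df$alt_p)
  keep <- pool < p_prefilter
  qv <- rep(NA_real_, length(pool))
  if (any(keep)) qv[keep] <- p.adjust(pool[keep], method = "BH")
  nh <- nrow(df)
  df$ref_q <- qv[seq_len(nh)]
  df$alt_q <- qv[nh + seq_len(nh)]
  ref_sig <- !is.na(df$ref_q) & df$ref_q <= q_threshold
  alt_sig <- !is.na(df$alt_q) & df$alt_q <= q_threshold
  df$class <- "none"
  df$class[ref_sig & !alt_sig] <- "loss"
  df$class[alt_sig & !ref_sig] <- "gain"
  both <- ref_sig & alt_sig & abs(df$deltaS) >= deltaS_threshold
  df$class[both & df$deltaS < 0] <- "weaken"
  df$class[both & df$deltaS > 0] <- "strengthen"

  calls <- do.call(rbind, lapply(split(df, df$variant), function(d) {
    eff <- d[d$class != "none", , drop = FALSE]
    if (nrow(eff)) eff[which.max(abs(eff$deltaS)), , drop = FALSE]
    else d[which.max(abs(d$deltaS)), , drop = FALSE]
  }))
  rownames(calls) <- NULL
  list(calls = calls, per_motif = df,
       fraction_with_effect = mean(calls$class != "none"))
}

# ---- LD redundancy ------------------------------------------------------

#' LD redundancy among HSVs
#'
#' r^2 is the squared Pearson correlation of dosage columns; an HSV is
#' redundant if it has at least one HSV partner with r^2 above the
#' threshold. With a list input the fraction is aggregated across genes as
#' total qualifying HSVs / total HSVs.
#'
#' @param hsv_sets an `hsv_set` or list of them
#' @param vts matching `variant_table` or list
#' @param r2_threshold strong-LD threshold (default 0.8)
#' @return list(per_gene = list of r2 matrices + qualifying flags,
#'   fraction, n)
#' @export
ld_redundancy <- function(hsv_sets, vts, r2_threshold = 0.8) {
  if (inherits(hsv_sets, "hsv_set")) {
    hsv_sets <- list(hsv_sets); vts <- list(vts)
  }
  per_gene <- vector("list", length(hsv_sets))
  qual_tot <- 0L; n_tot <- 0L
  for (g in seq_along(hsv_sets)) {
    idx <- hsv_sets[[g]]$members$idx
    n <- length(idx)
    if (n < 2L) {
      per_gene[[g]] <- list(r2 = matrix(1, n, n), qualifying = logical(n))
      n_tot <- n_tot + n
      next
    }
    D <- vts[[g]]$dosages[, idx, drop = FALSE]
    sds <- apply(D, 2, sd)
    if (any(sds == 0))
      warning("zero-variance dosage column; r^2 treated as 0")
    r2 <- matrix(0, n, n)
    ok <- sds > 0
    if (sum(ok) >= 2L)
      r2[ok, ok] <- cor(D[, ok, drop = FALSE])^2
    diag(r2) <- 1
    off <- r2; diag(off) <- 0
    qual <- apply(off, 1, max) > r2_threshold
    per_gene[[g]] <- list(r2 = r2, qualifying = qual)
    qual_tot <- qual_tot + sum(qual)
    n_tot <- n_tot + n
  }
  list(per_gene = per_gene,
       fraction = if (n_tot) qual_tot / n_tot else 0, n = n_tot)
}
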