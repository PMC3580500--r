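# Study-specific statistics: promoter asymmetry scores, expression-coupled
# modification peak-shift correlation, and CTCF-overlap enrichment by
# expression bin.

#' Per-gene promoter asymmetry scores
#'
#' For each gene, the number of dyad-shifted reads mapping to the 500 bp
#' upstream of the TSS divided by the total mapping within 500 bp on either
#' side. Upstream is positions `[-500, 0)` and downstream `[0, +500)`: the
#' TSS base itself counts as downstream. Genes with zero total reads in the
#' window are excluded and reported.
#'
#' @param matrix a `profile_matrix` whose positions cover `[-500, 499]`.
#' @param halfwidth_bp window half-width (default 500).
#' @return list with `scores` (named numeric, `gene_id -> score in [0,1]`)
#'   and `dropped` (gene ids with zero reads).
#' @export
asymmetry_score <- function(matrix, halfwidth_bp = 500L) {
  stopifnot(inherits(matrix, "profile_matrix"))
  pos <- matrix$rel_positions
  if (min(pos) > -halfwidth_bp || max(pos) < halfwidth_bp - 1L) {
    stop("matrix must cover [", -halfwidth_bp, ", ", halfwidth_bp - 1L, "]")
  }
  up_idx <- pos >= -halfwidth_bp & pos < 0L
  all_idx <- pos >= -halfwidth_bp & pos < halfwidth_bp
  up <- rowSums(matrix$values[, up_idx, drop = FALSE])
  tot <- rowSums(matrix$values[, all_idx, drop = FALSE])
  has <- tot > 0
  list(scores = setNames(up[has] / tot[has], matrix$gene_ids[has]),
       dropped = matrix$gene_ids[!has])
}

# exact two-sided rank-sum p by enumeration of all group assignments,
# with midranks under ties; used when the enumeration is small enough
exact_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  w_all <- colSums(matrix(r[combos], nrow = nx))
  eps <- sqrt(.Machine$double.eps)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
}

#' Compare asymmetry-score distributions between gene groups
#'
#' Two-sample Wilcoxon rank-sum test (two-sided, tie-corrected) by default;
#' `paired = TRUE` runs the Wilcoxon signed-rank test on expression-matched
#' pairs instead (both variants are in circulation for this comparison).
#' For small unpaired groups (enumeration up to `max_enum` assignments) the
#' p-value is computed exactly by enumerating all group labellings, which
#' handles ties exactly rather than by normal approximation.
#'
#' @param cpg_scores,noncpg_scores numeric score vectors (paired mode
#'   requires equal lengths, matched by position).
#' @param paired use the signed-rank test on pairs (default FALSE).
#' @param max_enum maximum number of enumerated assignments for the exact
#'   unpaired path (default 2e5; covers group sizes up to 8 vs 8).
#' @return list with `statistic`, `p_value`, `method`, `n_cpg`, `n_noncpg`.
#' @export
compare_asymmetry <- function(cpg_scores, noncpg_scores, paired = FALSE,
                              max_enum = 2e5) {
  if (length(cpg_scores) < 2L || length(noncpg_scores) < 2L) {
    stop("both groups need at least 2 scores")
  }
  if (paired) {
    if (length(cpg_scores) != length(noncpg_scores)) {
      stop("paired test requires equal-length, matched score vectors")
    }
    wt <- suppressWarnings(
      stats::wilcox.test(cpg_scores, noncpg_scores, paired = TRUE,
                         alternative = "two.sided"))
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                method = "wilcoxon_signed_rank",
                n_cpg = length(cpg_scores), n_noncpg = length(noncpg_scores)))
  }
  nx <- length(cpg_scores); ny <- length(noncpg_scores)
  w <- sum(rank(c(cpg_scores, noncpg_scores))[seq_len(nx)]) -
    nx * (nx + 1) / 2   # Mann-Whitney U for the CpG group
  if (choose(nx + ny, nx) <= max_enum) {
    p <- exact_ranksum_p(cpg_scores, noncpg_scores)
    method <- "wilcoxon_rank_sum_exact"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(cpg_scores, noncpg_scores, paired = FALSE,
                         alternative = "two.sided", exact = FALSE,
                         correct = TRUE))
    p <- wt$p.value
    method <- "wilcoxon_rank_sum_normal"
  }
  list(statistic = w, p_value = p, method = method,
       n_cpg = nx, n_noncpg = ny)
}

#' Per-gene modification peak positions
#'
#' The first (leftmost) position with the highest signal within
#' `[0, search_bp]` of the TSS, per gene. Rows that are all zero in the
#' search window are excluded and reported. Optionally a centred running-mean
#' smoother is applied to each row first, since a single-bp argmax on a
#' sparse row is noisy.
#'
#' @param matrix a `profile_matrix` covering `[0, search_bp]`.
#' @param search_bp inclusive search bound downstream of the TSS
#'   (default 2000).
#' @param smooth_bp if > 1, width of a centred running-mean applied per row
#'   before the argmax (default 1 = raw signal). Near the window edges the
#'   mean is taken over the positions that remain, so edge values stay on
#'   the same scale as interior ones.
#' @return list with `peaks` (named integer, `gene_id -> position`) and
#'   `dropped` (gene ids with all-zero rows).
#' @export
peak_positions <- function(matrix, search_bp = 2000L, smooth_bp = 1L) {
  stopifnot(inherits(matrix, "profile_matrix"))
  pos <- matrix$rel_positions
  if (min(pos) > 0L || max(pos) < search_bp) {
    stop("matrix must cover [0, ", search_bp, "]")
  }
  idx <- which(pos >= 0L & pos <= search_bp)
  vals <- matrix$values[, idx, drop = FALSE]
  if (smooth_bp > 1L) {
    n <- length(idx)
    h <- (as.integer(smooth_bp) - 1L) %/% 2L
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    width <- hi - lo + 1L
    vals <- t(apply(vals, 1L, function(r) {
      cs <- c(0, cumsum(r))
      (cs[hi + 1L] - cs[lo]) / width   # partial-window mean at the edges
    }))
  }
  tot <- rowSums(matrix$values[, idx, drop = FALSE])
  has <- tot > 0
  pk <- apply(vals[has, , drop = FALSE], 1L, which.max)  # leftmost argmax
  list(peaks = setNames(pos[idx][pk], matrix$gene_ids[has]),
       dropped = matrix$gene_ids[!has])
}

#' Correlation between peak position and expression rank
#'
#' Spearman rank correlation (tie-corrected ranks, two-sided p) between
#' per-gene peak positions and expression ranks, over genes present in both
#' mappings.
#'
#' @param peaks named numeric vector `gene_id -> peak position`.
#' @param expr_ranks named numeric vector `gene_id -> expression rank`.
#' @return list with `rho`, `p_value`, `n`; `rho` is `NA` (with a warning)
#'   when either vector is constant.
#' @export
peak_shift_correlation <- function(peaks, expr_ranks) {
  ids <- intersect(names(peaks), names(expr_ranks))
  if (length(ids) < 3L) stop("need at least 3 genes with both values")
  x <- as.numeric(peaks[ids]); y <- as.numeric(expr_ranks[ids])
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(ids)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(ids))
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' CTCF-overlap enrichment across expression bins
#'
#' Splits the CpG and non-CpG gene groups each into `n_bins` equally sized
#' expression bins (by within-group rank, sizes differing by at most 1 with
#' the remainder in the lowest bin) and reports the fraction of promoters
#' overlapping a binding site per bin, with 95 percent Wilson score
#' confidence intervals, plus an overall CpG-vs-non-CpG 2x2 chi-squared test
#' (no continuity correction) on the pooled overlap counts.
#'
#' @param classes named character vector `gene_id -> "CPG"/"NONCPG"`.
#' @param overlaps named logical vector `gene_id -> overlap` (e.g. from
#'   [overlaps_any()]).
#' @param expr_ranks named numeric vector `gene_id -> expression rank`.
#' @param n_bins number of expression bins (default 10).
#' @return list with `per_bin` (data.table `bin, class, n, k, fraction,
#'   ci_lower, ci_upper`), `chi2_statistic`, `chi2_p`, `table` (2x2 counts).
#' @export
ctcf_enrichment <- function(classes, overlaps, expr_ranks, n_bins = 10L) {
  ids <- Reduce(intersect, list(names(classes), names(overlaps),
                                names(expr_ranks)))
  if (length(ids) == 0L) stop("no genes shared across inputs")
  rows <- list()
  for (cl in c("CPG", "NONCPG")) {
    gid <- ids[classes[ids] == cl]
    gid <- gid[order(expr_ranks[gid], gid)]
    n <- length(gid)
    if (n == 0L) next
    base <- n %/% n_bins; rem <- n %% n_bins
    sizes <- rep(base, n_bins)
    sizes[1L] <- sizes[1L] + rem
    bin <- rep(seq_len(n_bins), times = sizes)
    for (b in seq_len(n_bins)) {
      g <- gid[bin == b]
      if (length(g) == 0L) {
        rows[[length(rows) + 1L]] <- data.table(
          bin = b, class = cl, n = 0L, k = 0L, fraction = NA_real_,
          ci_lower = NA_real_, ci_upper = NA_real_)
        next
      }
      k <- sum(overlaps[g])
      ci <- wilson_ci(k, length(g))
      rows[[length(rows) + 1L]] <- data.table(
        bin = b, class = cl, n = length(g), k = k,
        fraction = k / length(g), ci_lower = ci[1], ci_upper = ci[2])
    }
  }
  cpg_ids <- ids[classes[ids] == "CPG"]
  non_ids <- ids[classes[ids] == "NONCPG"]
  tab <- rbind(CPG = c(overlap = sum(overlaps[cpg_ids]),
                       no_overlap = sum(!overlaps[cpg_ids])),
               NONCPG = c(overlap = sum(overlaps[non_ids]),
                          no_overlap = sum(!overlaps[non_ids])))
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(per_bin = data.table::rbindlist(rows),
       chi2_statistic = unname(ch$statistic), chi2_p = ch$p.value,
       table = tab)
}
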