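# TSS-anchored, strand-oriented profile matrices and derived metagene
# profiles. Position +k always means k bp downstream of the TSS in the
# direction of transcription; minus-strand genes are reflected.

#' Build a TSS-anchored profile matrix
#'
#' Cell (g, k) holds `scale * dyad count` at the genomic base k bp downstream
#' of gene g's TSS in its direction of transcription (negative k = upstream).
#' Positions falling off the chromosome are zero-filled and masked; genes on
#' chromosomes absent from the track get an all-masked zero row (with a
#' warning).
#'
#' @param track a `dyad_track` from [build_track()].
#' @param genes gene table.
#' @param upstream_bp,downstream_bp window extent around the TSS
#'   (defaults 500 and 3000).
#' @param scaled multiply counts by the track's rescaling factor
#'   (default TRUE).
#' @return object of class `profile_matrix`: list with `gene_ids`,
#'   `rel_positions` (-upstream..+downstream), `values` (genes x positions),
#'   `mask` (TRUE where the position was off-chromosome), `scale`.
#' @export
profile_matrix <- function(track, genes, upstream_bp = 500L,
                           downstream_bp = 3000L, scaled = TRUE) {
  stopifnot(inherits(track, "dyad_track"))
  genes <- validate_genes(genes)
  rel <- seq.int(-upstream_bp, downstream_bp)
  n <- nrow(genes)
  vals <- matrix(0, nrow = n, ncol = length(rel))
  mask <- matrix(FALSE, nrow = n, ncol = length(rel))
  missing_chr <- setdiff(unique(genes$chrom), names(track$counts))
  if (length(missing_chr) > 0L) {
    warning("track has no chromosome(s): ", paste(missing_chr, collapse = ", "),
            "; affected genes get zero rows")
  }
  for (g in seq_len(n)) {
    ch <- genes$chrom[g]
    if (!ch %in% names(track$counts)) { mask[g, ] <- TRUE; next }
    cnt <- track$counts[[ch]]
    pos <- if (genes$strand[g] == "+") genes$tss[g] + rel else genes$tss[g] - rel
    ok <- pos >= 0L & pos < length(cnt)
    mask[g, !ok] <- TRUE
    vals[g, ok] <- cnt[pos[ok] + 1L]
  }
  if (scaled) vals <- vals * track$scale
  out <- list(gene_ids = genes$gene_id, rel_positions = rel, values = vals,
              mask = mask, scale = if (scaled) track$scale else 1)
  class(out) <- "profile_matrix"
  out
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("Profile matrix: ", length(x$gene_ids), " genes x ",
      length(x$rel_positions), " positions [",
      min(x$rel_positions), ", ", max(x$rel_positions), "]\n", sep = "")
  invisible(x)
}

#' Restrict a profile matrix to a position window
#'
#' @param matrix a `profile_matrix`.
#' @param from,to inclusive bounds on relative position.
#' @return a `profile_matrix` over the restricted positions.
#' @export
subset_positions <- function(matrix, from, to) {
  stopifnot(inherits(matrix, "profile_matrix"))
  keep <- matrix$rel_positions >= from & matrix$rel_positions <= to
  if (!any(keep)) stop("no positions in [", from, ", ", to, "]")
  out <- matrix
  out$rel_positions <- matrix$rel_positions[keep]
  out$values <- matrix$values[, keep, drop = FALSE]
  out$mask <- matrix$mask[, keep, drop = FALSE]
  out
}

#' Average (metagene) profile of a profile matrix
#'
#' Per-position mean over genes; masked (off-chromosome) cells are excluded
#' from the mean, not imputed.
#'
#' @param matrix a `profile_matrix`.
#' @return object of class `average_profile`: data.table with columns `pos`,
#'   `mean`, and placeholder `smooth`, `lo`, `hi` (filled by
#'   [loess_smooth()]).
#' @export
average_profile <- function(matrix) {
  stopifnot(inherits(matrix, "profile_matrix"))
  if (length(matrix$gene_ids) == 0L) stop("empty profile matrix")
  n_ok <- colSums(!matrix$mask)
  m <- ifelse(n_ok > 0L, colSums(matrix$values * !matrix$mask) / n_ok, NA_real_)
  out <- data.table(pos = matrix$rel_positions, mean = m,
                    smooth = NA_real_, lo = NA_real_, hi = NA_real_)
  class(out) <- c("average_profile", class(out))
  out[]
}

#' Loess-smooth an average profile with a confidence band
#'
#' Locally weighted polynomial regression (tricube weights, degree 2) where
#' each local fit uses the `span_bp` nearest positions; the band is
#' `smooth +/- band_se * SE` of the fit (default two standard errors,
#' approximating a 95 percent confidence band). The fit is evaluated exactly
#' at every position (direct surface), so it equals the pointwise weighted
#' least-squares solution.
#'
#' @param profile an `average_profile` with finite means.
#' @param span_bp absolute smoothing bandwidth in positions (default 180).
#' @param degree local polynomial degree (default 2).
#' @param band_se half-width of the band in standard errors (default 2).
#' @return the profile with `smooth`, `lo`, `hi` filled.
#' @export
loess_smooth <- function(profile, span_bp = 180L, degree = 2L, band_se = 2) {
  stopifnot(inherits(profile, "average_profile"))
  if (span_bp < 3L * (degree + 1L)) {
    stop("span_bp must be at least ", 3L * (degree + 1L))
  }
  ok <- is.finite(profile$mean)
  if (!all(ok)) {
    if (!any(ok)) stop("profile mean is not finite anywhere")
  }
  x <- profile$pos[ok]; y <- profile$mean[ok]
  fit <- loess(y ~ x, span = span_bp / length(x), degree = degree,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  pr <- predict(fit, newdata = data.frame(x = x), se = TRUE)
  out <- data.table::copy(as.data.table(profile))
  out$smooth[ok] <- pr$fit
  se <- pr$se.fit
  se[!is.finite(se)] <- 0
  out$lo[ok] <- pr$fit - band_se * se
  out$hi[ok] <- pr$fit + band_se * se
  class(out) <- c("average_profile", class(out))
  out[]
}

# sliding-window sums across the columns of a matrix; the returned matrix
# drops the half-window margin on each side (callers extract with margins)
window_sums <- function(mat, window_bp) {
  hw <- (window_bp - 1L) %/% 2L
  cs <- cbind(0, t(apply(mat, 1L, cumsum)))
  centers <- seq.int(hw + 1L, ncol(mat) - hw)
  cs[, centers + hw + 1L, drop = FALSE] - cs[, centers - hw, drop = FALSE]
}

#' Nucleosome-background-subtracted modification profile
#'
#' For each gene and each position around its TSS, computes the difference
#' between the scaled read counts of the modification track and the
#' nucleosome-occupancy track summed in a centred sliding window, then
#' reports the across-gene mean and a `+/- band_se * SE` band of these
#' per-gene differences at each position (SE of the mean, assuming
#' approximate normality).
#'
#' @param mod_track,nuc_track `dyad_track`s rescaled to the same target.
#' @param genes gene table.
#' @param upstream_bp,downstream_bp output window (defaults 500, 3000).
#' @param window_bp sliding-window width (default 75, step 1 bp).
#' @param band_se band half-width in standard errors (default 2).
#' @return an `average_profile` (`mean`/`lo`/`hi` filled; `smooth` = mean).
#' @export
background_subtract <- function(mod_track, nuc_track, genes,
                                upstream_bp = 500L, downstream_bp = 3000L,
                                window_bp = 75L, band_se = 2) {
  stopifnot(inherits(mod_track, "dyad_track"), inherits(nuc_track, "dyad_track"))
  if (mod_track$target_total != nuc_track$target_total) {
    stop("tracks rescaled to different targets (",
         mod_track$target_total, " vs ", nuc_track$target_total, ")")
  }
  hw <- (window_bp - 1L) %/% 2L
  pm_mod <- profile_matrix(mod_track, genes, upstream_bp + hw, downstream_bp + hw)
  pm_nuc <- profile_matrix(nuc_track, genes, upstream_bp + hw, downstream_bp + hw)
  diff <- window_sums(pm_mod$values, window_bp) -
    window_sums(pm_nuc$values, window_bp)
  n <- nrow(diff)
  m <- colMeans(diff)
  if (n >= 2L) {
    se <- apply(diff, 2L, stats::sd) / sqrt(n)
  } else {
    warning("single gene: standard error undefined, band reported as NA")
    se <- rep(NA_real_, ncol(diff))
  }
  out <- data.table(pos = seq.int(-upstream_bp, downstream_bp), mean = m,
                    smooth = m, lo = m - band_se * se, hi = m + band_se * se)
  class(out) <- c("average_profile", class(out))
  out[]
}

#' G+C content metagene profile
#'
#' Per-position fraction of G+C in a centred sliding window around the TSS,
#' strand-oriented and averaged over genes. `N` bases are excluded from both
#' numerator and denominator; positions whose window holds only `N` (or runs
#' off the chromosome for every gene) are `NA`.
#'
#' @param genes gene table.
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param flank_bp half-width of the profiled region (default 3000).
#' @param window_bp GC window width (default 75).
#' @return an `average_profile` (mean = GC fraction; `smooth` = mean).
#' @export
gc_profile <- function(genes, genome, flank_bp = 3000L, window_bp = 75L) {
  genes <- validate_genes(genes)
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  hw <- (window_bp - 1L) %/% 2L
  rel <- seq.int(-flank_bp, flank_bp)
  acc_gc <- matrix(0, nrow = nrow(genes), ncol = length(rel))
  acc_n <- matrix(0, nrow = nrow(genes), ncol = length(rel))
  for (g in seq_len(nrow(genes))) {
    ch <- genes$chrom[g]
    if (!ch %in% names(genome)) next
    seqv <- strsplit(toupper(genome[[ch]]), "", fixed = TRUE)[[1]]
    span <- flank_bp + hw
    pos <- if (genes$strand[g] == "+") genes$tss[g] + seq.int(-span, span)
           else genes$tss[g] - seq.int(-span, span)
    ok <- pos >= 0L & pos < length(seqv)
    base <- rep(NA_character_, length(pos))
    base[ok] <- seqv[pos[ok] + 1L]
    is_gc <- as.numeric(base %in% c("G", "C"))
    is_valid <- as.numeric(base %in% c("A", "C", "G", "T"))
    csg <- c(0, cumsum(is_gc)); csv <- c(0, cumsum(is_valid))
    centers <- seq.int(hw + 1L, length(pos) - hw)
    acc_gc[g, ] <- csg[centers + hw + 1L] - csg[centers - hw]
    acc_n[g, ] <- csv[centers + hw + 1L] - csv[centers - hw]
  }
  frac <- ifelse(acc_n > 0, acc_gc / acc_n, NA_real_)
  m <- colMeans(frac, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  out <- data.table(pos = rel, mean = m, smooth = m,
                    lo = NA_real_, hi = NA_real_)
  class(out) <- c("average_profile", class(out))
  out[]
}

#' Interval-density metagene profile
#'
#' Per position, the fraction of genes whose oriented position is covered by
#' at least one interval (e.g. exons). Off-chromosome positions are excluded
#' from the denominator.
#'
#' @param genes gene table.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param flank_bp half-width of the profiled region (default 3000).
#' @param chrom_sizes optional named vector bounding the chromosomes; when
#'   absent, coverage extends to the furthest interval end.
#' @return an `average_profile` (mean = covered fraction).
#' @export
interval_density_profile <- function(genes, intervals, flank_bp = 3000L,
                                     chrom_sizes = NULL) {
  genes <- validate_genes(genes)
  intervals <- as.data.table(intervals)
  rel <- seq.int(-flank_bp, flank_bp)
  covered <- matrix(FALSE, nrow = nrow(genes), ncol = length(rel))
  valid <- matrix(TRUE, nrow = nrow(genes), ncol = length(rel))
  cov_by_chr <- list()
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    cov_by_chr[[ch]] <- IRanges::coverage(ir) > 0L
  }
  for (g in seq_len(nrow(genes))) {
    ch <- genes$chrom[g]
    pos <- if (genes$strand[g] == "+") genes$tss[g] + rel else genes$tss[g] - rel
    if (!is.null(chrom_sizes) && ch %in% names(chrom_sizes)) {
      valid[g, ] <- pos >= 0L & pos < chrom_sizes[[ch]]
    } else {
      valid[g, ] <- pos >= 0L
    }
    if (!ch %in% names(cov_by_chr)) next
    cv <- cov_by_chr[[ch]]
    ok <- valid[g, ] & pos + 1L <= length(cv)
    covered[g, ok] <- as.logical(cv[pos[ok] + 1L])
  }
  n_ok <- colSums(valid)
  m <- ifelse(n_ok > 0L, colSums(covered & valid) / n_ok, NA_real_)
  out <- data.table(pos = rel, mean = m, smooth = m,
                    lo = NA_real_, hi = NA_real_)
  class(out) <- c("average_profile", class(out))
  out[]
}

#' Reorder a profile matrix for heatmap export
#'
#' Rows are sorted by the supplied ranking (ascending); ties are broken by
#' `gene_id` so the order is stable. Values are untouched.
#'
#' @param matrix a `profile_matrix`.
#' @param order_by named numeric vector `gene_id -> rank` covering every gene
#'   in the matrix.
#' @return the row-reordered `profile_matrix`.
#' @export
heatmap_matrix <- function(matrix, order_by) {
  stopifnot(inherits(matrix, "profile_matrix"))
  miss <- setdiff(matrix$gene_ids, names(order_by))
  if (length(miss) > 0L) {
    stop("ranking missing gene(s): ", paste(head(miss, 5L), collapse = ", "))
  }
  r <- order_by[matrix$gene_ids]
  ord <- order(r, matrix$gene_ids)
  out <- matrix
  out$gene_ids <- matrix$gene_ids[ord]
  out$values <- matrix$values[ord, , drop = FALSE]
  out$mask <- matrix$mask[ord, , drop = FALSE]
  out
}

#' Write a profile matrix as gzipped TSV
#'
#' First column `gene_id`, header row of relative positions.
#'
#' @param matrix a `profile_matrix`.
#' @param path output path (".gz" appended if absent).
#' @export
write_profile_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "profile_matrix"))
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  dt <- data.table(gene_id = matrix$gene_ids)
  vals <- as.data.table(matrix$values)
  names(vals) <- as.character(matrix$rel_positions)
  fwrite(cbind(dt, vals), path, sep = "\t", compress = "gzip")
  invisible(path)
}

#' Write an average profile as TSV
#'
#' Columns `pos mean smooth lo hi`.
#'
#' @param profile an `average_profile`.
#' @param path output path.
#' @export
write_average_profile <- function(profile, path) {
  stopifnot(inherits(profile, "average_profile"))
  fwrite(as.data.table(profile), path, sep = "\t")
  invisible(path)
}
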