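#' @importFrom data.table data.table fread fwrite as.data.table
NULL

# All genomic coordinates in this package are 0-based, half-open. The TSS of a
# minus-strand gene is the right-most base of its annotated extent, so for a
# minus-strand gene tss > end and the occupied interval is [end + 1, tss + 1).

#' Validate a gene table
#'
#' Checks that a gene table has the required columns and coherent coordinates.
#' Genes are rows with columns `gene_id`, `chrom`, `strand` (+/-), `tss`,
#' `end` (both 0-based; for minus-strand genes `tss > end`), and optionally
#' `n_tss` (number of annotated alternative start sites).
#'
#' @param genes data.frame of gene models.
#' @return The validated table as a `data.table` (invisibly coerced).
#' @export
validate_genes <- function(genes) {
  genes <- as.data.table(genes)
  need <- c("gene_id", "chrom", "strand", "tss", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0L) {
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!genes$strand %in% c("+", "-")]
    stop("invalid strand for gene(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  len <- abs(genes$end - genes$tss)
  bad <- !is.finite(genes$tss) | !is.finite(genes$end) | len < 1L |
    (genes$strand == "+" & genes$end <= genes$tss) |
    (genes$strand == "-" & genes$end >= genes$tss)
  if (any(bad)) {
    stop("malformed coordinates for gene(s): ",
         paste(head(genes$gene_id[bad], 5L), collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id(s): ",
         paste(head(unique(genes$gene_id[duplicated(genes$gene_id)]), 5L),
               collapse = ", "))
  }
  genes
}

#' Genomic extent of genes as half-open intervals
#'
#' @param genes validated gene table.
#' @return data.table with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open interval covering the annotated gene body).
#' @export
gene_extent <- function(genes) {
  genes <- as.data.table(genes)
  start <- ifelse(genes$strand == "+", genes$tss, genes$end + 1L)
  end <- ifelse(genes$strand == "+", genes$end, genes$tss + 1L)
  data.table(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end))
}

#' Filter genes by length and promoter isolation
#'
#' Removes genes shorter than `min_length_bp` and genes whose TSS lies within
#' `isolation_bp` of any other gene's annotated extent, so that upstream
#' promoter windows do not overlap neighbouring genes. Input order is
#' preserved. A gene whose TSS falls inside another gene's extent has
#' distance 0 and is removed.
#'
#' @param genes gene table (see [validate_genes()]).
#' @param min_length_bp minimum gene length in bp (default 3000).
#' @param isolation_bp minimum distance from the TSS to any other gene's
#'   extent (default 500); distances strictly less than this remove the gene.
#' @param single_tss_only if TRUE, additionally keep only genes with
#'   `n_tss == 1` (requires an `n_tss` column).
#' @return the filtered gene table, original row order preserved.
#' @export
filter_genes <- function(genes, min_length_bp = 3000L, isolation_bp = 500L,
                         single_tss_only = FALSE) {
  genes <- validate_genes(genes)
  if (nrow(genes) == 0L) return(genes)
  keep <- abs(genes$end - genes$tss) >= min_length_bp
  if (single_tss_only) {
    if (!"n_tss" %in% names(genes)) stop("single_tss_only requires an n_tss column")
    keep <- keep & genes$n_tss == 1L
  }
  ext <- gene_extent(genes)
  isolated <- rep(TRUE, nrow(genes))
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    if (length(idx) < 2L) next
    # TSS point padded by (isolation_bp - 1) on both sides; any overlap with
    # another gene's extent means the gap is < isolation_bp
    tssr <- IRanges::IRanges(start = genes$tss[idx] + 1L - (isolation_bp - 1L),
                             end = genes$tss[idx] + 1L + (isolation_bp - 1L))
    extr <- IRanges::IRanges(start = ext$start[idx] + 1L, end = ext$end[idx])
    hits <- IRanges::findOverlaps(tssr, extr)
    near <- S4Vectors::queryHits(hits)[S4Vectors::queryHits(hits) !=
                                         S4Vectors::subjectHits(hits)]
    isolated[idx[unique(near)]] <- FALSE
  }
  genes[keep & isolated, ]
}

#' Classify genes by CpG-island overlap at the TSS
#'
#' A gene is labelled `CPG` when its TSS coordinate lies within
#' `[start, end)` of an island on the same chromosome, `NONCPG` otherwise.
#' Genes on chromosomes absent from the island set are `NONCPG` (a note is
#' emitted).
#'
#' @param genes gene table.
#' @param islands data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @return named character vector, `gene_id -> "CPG"/"NONCPG"`.
#' @export
classify_island_overlap <- function(genes, islands) {
  genes <- validate_genes(genes)
  islands <- as.data.table(islands)
  out <- setNames(rep("NONCPG", nrow(genes)), genes$gene_id)
  missing_chr <- setdiff(unique(genes$chrom), unique(islands$chrom))
  if (length(missing_chr) > 0L) {
    message("no islands on chromosome(s): ", paste(missing_chr, collapse = ", "),
            "; genes there classified NONCPG")
  }
  for (ch in intersect(unique(genes$chrom), unique(islands$chrom))) {
    gi <- which(genes$chrom == ch)
    isl <- islands[islands$chrom == ch, ]
    tssr <- IRanges::IRanges(start = genes$tss[gi] + 1L, width = 1L)
    islr <- IRanges::IRanges(start = isl$start + 1L, end = isl$end)
    hit <- IRanges::overlapsAny(tssr, islr)
    out[gi[hit]] <- "CPG"
  }
  out
}

#' CpG observed/expected ratio
#'
#' Computes `n_CpG * L / (n_C * n_G)` for a DNA string, where `n_CpG` counts
#' CG dinucleotides, `L` is the sequence length and `n_C`, `n_G` the base
#' counts. Returns 0 when either base count is 0. `N` bases count as neither
#' C nor G and never form a CpG.
#'
#' @param seq a single DNA string (A/C/G/T/N).
#' @return non-negative numeric ratio.
#' @export
cpg_oe_ratio <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L < 2L) stop("sequence must have length >= 2")
  s <- Biostrings::DNAString(seq)
  n_c <- Biostrings::countPattern("C", s)
  n_g <- Biostrings::countPattern("G", s)
  if (n_c == 0L || n_g == 0L) return(0)
  n_cg <- Biostrings::countPattern("CG", s)
  n_cg * L / (n_c * n_g)
}

#' Classify a promoter as HCP / ICP / LCP by a windowed CpG scan
#'
#' Scans a 1,500-bp strand-oriented promoter sequence (TSS-1200 .. TSS+300;
#' minus-strand genes supply the reverse complement) with a sliding window.
#' `HCP` if any window has CpG o/e ratio > 0.75 and GC content > 55 percent;
#' `LCP` if all windows have o/e <= 0.48; `ICP` otherwise. Windows with more
#' than 10 percent `N` are skipped (with a note).
#'
#' @param promoter_seq a single 1,500-bp DNA string, strand-oriented.
#' @param window_bp sliding-window width in bp (default 500).
#' @param step_bp window step in bp (default 1).
#' @param hcp_oe,hcp_gc,lcp_oe class thresholds (o/e > `hcp_oe` and
#'   GC% > `hcp_gc` for HCP; all o/e <= `lcp_oe` for LCP).
#' @param expected_length expected promoter length (default 1500); a sequence
#'   of any other length is an error.
#' @return one of `"HCP"`, `"ICP"`, `"LCP"`.
#' @export
classify_weber <- function(promoter_seq, window_bp = 500L, step_bp = 1L,
                           hcp_oe = 0.75, hcp_gc = 55, lcp_oe = 0.48,
                           expected_length = 1500L) {
  stopifnot(is.character(promoter_seq), length(promoter_seq) == 1L)
  L <- nchar(promoter_seq)
  if (L != expected_length) {
    stop("promoter sequence must be ", expected_length, " bp, got ", L)
  }
  v <- strsplit(toupper(promoter_seq), "", fixed = TRUE)[[1]]
  is_c <- v == "C"
  is_g <- v == "G"
  is_n <- !(v %in% c("A", "C", "G", "T"))
  is_cg <- c(is_c[-L] & is_g[-1L], FALSE)
  # cumulative sums -> O(1) window statistics
  cc <- c(0L, cumsum(is_c)); cg <- c(0L, cumsum(is_g))
  cn <- c(0L, cumsum(is_n)); ccg <- c(0L, cumsum(is_cg))
  starts <- seq.int(1L, L - window_bp + 1L, by = step_bp)
  ends <- starts + window_bp - 1L
  n_c <- cc[ends + 1L] - cc[starts]
  n_g <- cg[ends + 1L] - cg[starts]
  n_n <- cn[ends + 1L] - cn[starts]
  # CG dinucleotides fully inside the window: positions start .. end-1
  n_cg <- ccg[ends] - ccg[starts]
  ok <- n_n <= 0.10 * window_bp
  if (!any(ok)) stop("all windows exceed 10% N; cannot classify")
  if (!all(ok)) message(sum(!ok), " window(s) skipped (>10% N)")
  n_c <- n_c[ok]; n_g <- n_g[ok]; n_cg <- n_cg[ok]
  oe <- ifelse(n_c == 0L | n_g == 0L, 0, n_cg * window_bp / (n_c * n_g))
  gc_pct <- 100 * (n_c + n_g) / window_bp
  if (any(oe > hcp_oe & gc_pct > hcp_gc)) return("HCP")
  if (all(oe <= lcp_oe)) return("LCP")
  "ICP"
}

#' Test gene promoters for overlap with a peak set
#'
#' In `tss_point` mode a gene overlaps when its TSS coordinate falls inside
#' a peak interval; in `promoter_window` mode when the window
#' `[tss - window_bp, tss + window_bp)` intersects any peak.
#'
#' @param genes gene table.
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param mode `"tss_point"` or `"promoter_window"`.
#' @param window_bp half-width of the promoter window (used in
#'   `promoter_window` mode).
#' @return named logical vector `gene_id -> TRUE/FALSE`.
#' @export
overlaps_any <- function(genes, peaks, mode = c("tss_point", "promoter_window"),
                         window_bp = 500L) {
  mode <- match.arg(mode)
  genes <- validate_genes(genes)
  peaks <- as.data.table(peaks)
  out <- setNames(rep(FALSE, nrow(genes)), genes$gene_id)
  for (ch in intersect(unique(genes$chrom), unique(peaks$chrom))) {
    gi <- which(genes$chrom == ch)
    pk <- peaks[peaks$chrom == ch, ]
    if (mode == "tss_point") {
      qr <- IRanges::IRanges(start = genes$tss[gi] + 1L, width = 1L)
    } else {
      qr <- IRanges::IRanges(start = genes$tss[gi] - window_bp + 1L,
                             end = genes$tss[gi] + window_bp)
    }
    pr <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    out[gi[IRanges::overlapsAny(qr, pr)]] <- TRUE
  }
  out
}

#' Read a gene table
#'
#' Tab-delimited with header `gene_id chrom strand tss end n_tss`.
#'
#' @param path file path.
#' @return validated gene `data.table`.
#' @export
read_gene_table <- function(path) {
  validate_genes(fread(path, sep = "\t"))
}

#' Read a BED file of intervals
#'
#' Accepts 3+ column BED (0-based half-open). Columns beyond the sixth are
#' ignored; missing name/score/strand columns are filled with defaults.
#'
#' @param path file path.
#' @return data.table with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t")
  if (ncol(x) < 3L) stop("BED file must have at least 3 columns: ", path)
  out <- data.table(chrom = as.character(x[[1]]),
                    start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]))
  out$name <- if (ncol(x) >= 4L) as.character(x[[4]]) else "."
  out$score <- if (ncol(x) >= 5L) x[[5]] else 0
  out$strand <- if (ncol(x) >= 6L) as.character(x[[6]]) else "*"
  if (any(out$start >= out$end)) stop("BED intervals must satisfy start < end: ", path)
  out
}
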