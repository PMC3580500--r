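# Mapped reads -> deduplicated, dyad-shifted, depth-rescaled count tracks.
#
# A read's dyad is estimated by shifting its 5' end `shift_bp` bases in the
# sequencing direction: plus-strand dyad = start + shift; minus-strand dyad =
# (end - 1) - shift (BED stores leftmost coordinates, so the 5' end of a
# minus-strand read is end - 1).

#' Read mapped reads from a BED-like file
#'
#' 6-column BED (name and score ignored); `strand_column` selects the column
#' holding +/- for headerless files that deviate from the standard layout.
#'
#' @param path file path.
#' @param strand_column column index holding the strand (default 6).
#' @return data.table with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_mapped_reads <- function(path, strand_column = 6L) {
  x <- fread(path, header = FALSE, sep = "\t")
  if (ncol(x) < max(3L, strand_column)) {
    stop("read file needs at least ", max(3L, strand_column), " columns: ", path)
  }
  out <- data.table(chrom = as.character(x[[1]]),
                    start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]),
                    strand = as.character(x[[strand_column]]))
  if (!all(out$strand %in% c("+", "-"))) {
    stop("strand column must contain only + or -: ", path)
  }
  if (any(out$start >= out$end)) stop("reads must satisfy start < end: ", path)
  out
}

#' Remove duplicate reads
#'
#' Keeps at most one read per (chrom, start, end, strand) tuple, preserving
#' the order of first occurrence. Including strand in the tuple avoids
#' collapsing genuine sense/antisense coverage.
#'
#' @param reads data.table of reads (see [read_mapped_reads()]).
#' @return deduplicated reads.
#' @export
dedup <- function(reads) {
  reads <- as.data.table(reads)
  if (nrow(reads) == 0L) return(reads)
  reads[!duplicated(reads[, c("chrom", "start", "end", "strand"), with = FALSE]), ]
}

#' Shift read starts to nucleosome dyad positions
#'
#' @param reads data.table of reads.
#' @param shift_bp shift in bp from the 5' end in the sequencing direction
#'   (default 75, about half the nucleosomal fragment length).
#' @return list with `dyads` (data.table `chrom`, `pos`) and `n_discarded`
#'   (reads whose dyad would fall before position 0).
#' @export
shift_to_dyad <- function(reads, shift_bp = 75L) {
  reads <- as.data.table(reads)
  pos <- ifelse(reads$strand == "+",
                reads$start + shift_bp,
                (reads$end - 1L) - shift_bp)
  keep <- pos >= 0L
  list(dyads = data.table(chrom = reads$chrom[keep], pos = as.integer(pos[keep])),
       n_discarded = sum(!keep))
}

#' Build a per-base dyad-count track
#'
#' Deduplicates reads, shifts them to dyad positions, and tallies dyads per
#' base per chromosome. The depth-rescaling factor `scale = target_total /
#' n_reads` is carried alongside the integer counts (never applied to them),
#' so read-count conservation stays exact; consumers multiply at read-out.
#'
#' @param reads data.table of mapped reads.
#' @param chrom_sizes named integer vector of chromosome lengths (bp),
#'   covering every chromosome present in `reads`.
#' @param target_total rescaling target (default 10 million fragments).
#' @param shift_bp dyad shift (default 75).
#' @param deduplicate remove identical reads first (default TRUE).
#' @return object of class `dyad_track`: list with `counts` (named list of
#'   integer vectors, one cell per bp), `n_reads` (retained dyads),
#'   `scale`, `target_total`, `n_discarded`.
#' @export
build_track <- function(reads, chrom_sizes, target_total = 1e7L,
                        shift_bp = 75L, deduplicate = TRUE) {
  reads <- as.data.table(reads)
  bad <- setdiff(unique(reads$chrom), names(chrom_sizes))
  if (length(bad) > 0L) {
    stop("chrom_sizes missing chromosome(s): ", paste(bad, collapse = ", "))
  }
  if (deduplicate) reads <- dedup(reads)
  sh <- shift_to_dyad(reads, shift_bp = shift_bp)
  dyads <- sh$dyads
  n_disc <- sh$n_discarded
  counts <- lapply(names(chrom_sizes), function(ch) {
    size <- as.integer(chrom_sizes[[ch]])
    p <- dyads$pos[dyads$chrom == ch]
    off <- sum(p >= size)
    if (off > 0L) {
      n_disc <<- n_disc + off
      p <- p[p < size]
    }
    tabulate(p + 1L, nbins = size)
  })
  names(counts) <- names(chrom_sizes)
  n_reads <- sum(vapply(counts, sum, numeric(1)))
  if (n_reads == 0L) stop("no reads retained after deduplication and shifting")
  out <- list(counts = counts, n_reads = n_reads,
              scale = target_total / n_reads, target_total = target_total,
              n_discarded = n_disc)
  class(out) <- "dyad_track"
  out
}

#' @export
print.dyad_track <- function(x, ...) {
  cat("Dyad track: ", length(x$counts), " chromosome(s), ",
      format(x$n_reads, big.mark = ","), " dyads, scale = ",
      signif(x$scale, 6), " (target ", format(x$target_total, big.mark = ","),
      ")\n", sep = "")
  invisible(x)
}

#' Write a dyad track as bedGraph
#'
#' Adjacent equal-count runs are merged; zero-count positions are omitted.
#'
#' @param track a `dyad_track`.
#' @param path output path.
#' @param scaled write depth-rescaled values (default) or raw integer counts.
#' @export
write_bedgraph <- function(track, path, scaled = TRUE) {
  stopifnot(inherits(track, "dyad_track"))
  rows <- lapply(names(track$counts), function(ch) {
    v <- track$counts[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    if (!any(keep)) return(NULL)
    val <- if (scaled) r$values[keep] * track$scale else r$values[keep]
    data.table(chrom = ch, start = starts[keep], end = ends[keep], value = val)
  })
  fwrite(data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))]),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
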