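# Shared fixture builders and independent brute-force oracles.

make_gene <- function(id, chrom = "chr1", strand = "+", tss, len = 5000L) {
  if (strand == "+") data.table::data.table(
    gene_id = id, chrom = chrom, strand = strand,
    tss = as.integer(tss), end = as.integer(tss + len), n_tss = 1L)
  else data.table::data.table(
    gene_id = id, chrom = chrom, strand = strand,
    tss = as.integer(tss), end = as.integer(tss - len), n_tss = 1L)
}

make_reads <- function(chrom, start, end, strand) {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), strand = strand)
}

# profile_matrix object built directly from a value matrix
fake_matrix <- function(values, rel_positions,
                        gene_ids = sprintf("g%03d", seq_len(nrow(values)))) {
  out <- list(gene_ids = gene_ids, rel_positions = as.integer(rel_positions),
              values = values,
              mask = matrix(FALSE, nrow(values), ncol(values)),
              scale = 1)
  class(out) <- "profile_matrix"
  out
}

# brute-force dinucleotide tally for the CpG o/e ratio
oracle_cpg_oe <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  n_c <- sum(v == "C"); n_g <- sum(v == "G")
  if (n_c == 0 || n_g == 0) return(0)
  n_cg <- sum(v[-length(v)] == "C" & v[-1] == "G")
  n_cg * length(v) / (n_c * n_g)
}

# brute-force per-read dyad tally
oracle_track_counts <- function(reads, chrom_sizes, shift_bp = 75L) {
  reads <- reads[!duplicated(reads[, c("chrom", "start", "end", "strand")]), ]
  counts <- lapply(chrom_sizes, function(s) integer(s))
  for (i in seq_len(nrow(reads))) {
    d <- if (reads$strand[i] == "+") reads$start[i] + shift_bp
         else (reads$end[i] - 1L) - shift_bp
    ch <- reads$chrom[i]
    if (d >= 0L && d < chrom_sizes[[ch]]) {
      counts[[ch]][d + 1L] <- counts[[ch]][d + 1L] + 1L
    }
  }
  counts
}

# exact two-sided rank-sum p by direct enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  mu <- nx * (nx + length(y) + 1) / 2
  w_obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(length(r), nx)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  eps <- sqrt(.Machine$double.eps)
  mean(abs(ws - mu) >= abs(w_obs - mu) - eps)
}

# local tricube weighted quadratic regression at a single target position
oracle_loess_at <- function(x, y, x0, q) {
  d <- abs(x - x0)
  dq <- sort(d)[q]
  w <- pmax(0, 1 - pmin(d / dq, 1)^3)^3
  fit <- stats::lm(y ~ x + I(x^2), weights = w)
  unname(stats::predict(fit, newdata = data.frame(x = x0)))
}

# mirror a read table and gene table through a chromosome of length L
mirror_reads <- function(reads, L) {
  data.table::data.table(chrom = reads$chrom,
                         start = L - reads$end, end = L - reads$start,
                         strand = ifelse(reads$strand == "+", "-", "+"))
}
mirror_genes <- function(genes, L) {
  data.table::data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                         strand = ifelse(genes$strand == "+", "-", "+"),
                         tss = L - 1L - genes$tss, end = L - 1L - genes$end,
                         n_tss = genes$n_tss)
}
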