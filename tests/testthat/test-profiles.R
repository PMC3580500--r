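single_dyad_track <- function(chrom = "c1", dyad, size = 20000L, n = 1L) {
  counts <- setNames(list(integer(size)), chrom)
  counts[[chrom]][dyad + 1L] <- n
  out <- list(counts = counts, n_reads = n, scale = 1, target_total = n,
              n_discarded = 0L)
  class(out) <- "dyad_track"
  out
}

test_that("profile matrix is TSS-anchored and strand-oriented", {
  g_plus <- make_gene("gp", chrom = "c1", tss = 1000, len = 5000)
  g_minus <- make_gene("gm", chrom = "c1", strand = "-", tss = 1000, len = 900)
  tr <- single_dyad_track(dyad = 1010L)
  pm_p <- profile_matrix(tr, g_plus, upstream_bp = 100, downstream_bp = 100)
  expect_equal(pm_p$values[1, pm_p$rel_positions == 10], 1)
  expect_equal(sum(pm_p$values), 1)
  # minus-strand gene: +10 means 10 bp downstream along transcription
  tr_m <- single_dyad_track(dyad = 990L)
  pm_m <- profile_matrix(tr_m, g_minus, upstream_bp = 100, downstream_bp = 100)
  expect_equal(pm_m$values[1, pm_m$rel_positions == 10], 1)
  # dyad outside the window contributes nowhere
  tr_far <- single_dyad_track(dyad = 6000L)
  pm_far <- profile_matrix(tr_far, g_plus, upstream_bp = 500, downstream_bp = 3000)
  expect_equal(sum(pm_far$values), 0)
  # scale multiplies values
  tr2 <- single_dyad_track(dyad = 1010L); tr2$scale <- 2.5
  pm2 <- profile_matrix(tr2, g_plus, upstream_bp = 100, downstream_bp = 100)
  expect_equal(sum(pm2$values), 2.5)
  # missing chromosome: zero masked row with warning
  g_z <- make_gene("gz", chrom = "cZ", tss = 1000, len = 5000)
  expect_warning(pm_z <- profile_matrix(tr, g_z, 100, 100), "cZ")
  expect_true(all(pm_z$mask))
})

test_that("profile rows conserve the dyads in each gene window", {
  set.seed(81)
  size <- 30000L
  counts <- list(c1 = as.integer(rpois(size, 0.05)))
  tr <- list(counts = counts, n_reads = sum(counts$c1),
             scale = 1.7, target_total = 1, n_discarded = 0L)
  class(tr) <- "dyad_track"
  genes <- rbind(make_gene("a", chrom = "c1", tss = 5000, len = 5000),
                 make_gene("b", chrom = "c1", strand = "-", tss = 25000, len = 5000))
  pm <- profile_matrix(tr, genes, upstream_bp = 500, downstream_bp = 3000)
  for (i in 1:2) {
    pos <- if (genes$strand[i] == "+") genes$tss[i] + pm$rel_positions
           else genes$tss[i] - pm$rel_positions
    expect_equal(sum(pm$values[i, ]), 1.7 * sum(counts$c1[pos + 1L]))
  }
})

test_that("oriented profiles are invariant under genome mirroring", {
  set.seed(91)
  L <- 40000L
  n <- 3000
  st <- sample(500:(L - 700), n, replace = TRUE)
  reads <- make_reads("c1", st, st + 151L, sample(c("+", "-"), n, TRUE))
  genes <- rbind(make_gene("a", chrom = "c1", tss = 6000, len = 5000),
                 make_gene("b", chrom = "c1", strand = "-", tss = 30000, len = 5000))
  tr <- build_track(reads, c(c1 = L))
  pm <- profile_matrix(tr, genes, scaled = FALSE)
  tr_mir <- build_track(mirror_reads(reads, L), c(c1 = L))
  pm_mir <- profile_matrix(tr_mir, mirror_genes(genes, L), scaled = FALSE)
  expect_identical(pm$values, pm_mir$values)   # bit-for-bit on raw counts
})

test_that("average profile equals the brute-force column mean", {
  m <- fake_matrix(rbind(c(1, 3), c(3, 1)), c(0, 1))
  expect_equal(average_profile(m)$mean, c(2, 2))
  single <- fake_matrix(matrix(c(4, 7), 1), c(0, 1))
  expect_equal(average_profile(single)$mean, c(4, 7))
  set.seed(101)
  vals <- matrix(rpois(100 * 50, 3), nrow = 100)
  mp <- fake_matrix(vals, seq_len(50))
  expect_equal(average_profile(mp)$mean, colMeans(vals))
  expect_error(average_profile(fake_matrix(vals[0, , drop = FALSE], 1:50,
                                           gene_ids = character(0))),
               "empty")
})

test_that("loess smoothing reproduces constants, lines, and spike symmetry", {
  n <- 400
  const <- fake_matrix(matrix(5, 1, n), seq_len(n))
  ap <- loess_smooth(average_profile(const))
  expect_true(all(abs(ap$smooth - 5) < 1e-8))
  expect_true(all(ap$hi - ap$lo < 1e-8))
  expect_true(all(ap$lo <= ap$smooth + 1e-12 & ap$smooth <= ap$hi + 1e-12))

  lin <- fake_matrix(matrix(0.5 * seq_len(n) + 3, 1), seq_len(n))
  apl <- loess_smooth(average_profile(lin))
  expect_true(all(abs(apl$smooth - (0.5 * seq_len(n) + 3)) /
                    abs(0.5 * seq_len(n) + 3) < 1e-6))

  spike <- matrix(0, 1, n); spike[1, 200] <- 1
  aps <- loess_smooth(average_profile(fake_matrix(spike, seq_len(n))))
  expect_equal(aps$pos[which.max(aps$smooth)], 200)

  expect_error(loess_smooth(average_profile(const), span_bp = 5), "span_bp")
})

test_that("loess equals a direct weighted-least-squares oracle", {
  set.seed(111)
  n <- 800; span_bp <- 180
  y <- sin(seq_len(n) / 50) + rnorm(n, sd = 0.2)
  ap <- loess_smooth(average_profile(fake_matrix(matrix(y, 1), seq_len(n))),
                     span_bp = span_bp)
  for (i in sample(n, 20)) {
    want <- oracle_loess_at(as.numeric(seq_len(n)), y, i, q = span_bp)
    expect_equal(ap$smooth[i], want, tolerance = 1e-8)
  }
})

test_that("background subtraction is zero for identical tracks and linear", {
  set.seed(121)
  size <- 20000L
  base <- as.integer(rpois(size, 0.2))
  mk_track <- function(cnt, target) {
    out <- list(counts = list(c1 = cnt), n_reads = sum(cnt),
                scale = target / sum(cnt), target_total = target,
                n_discarded = 0L)
    class(out) <- "dyad_track"
    out
  }
  genes <- rbind(make_gene("a", chrom = "c1", tss = 5000, len = 5000),
                 make_gene("b", chrom = "c1", tss = 12000, len = 5000))
  t1 <- mk_track(base, 1e6)
  bs0 <- background_subtract(t1, t1, genes)
  expect_true(all(abs(bs0$mean) < 1e-9))

  # mod = 2 x nuc after scaling: difference equals the mean scaled window sum
  t2 <- mk_track(base * 2L, 2e6)   # same scale, doubled counts
  t2$scale <- t1$scale             # force equal scaling of doubled counts
  t2$target_total <- 1e6
  bs2 <- background_subtract(t2, t1, genes)
  pm <- profile_matrix(t1, genes, upstream_bp = 500 + 37, downstream_bp = 3000 + 37)
  win <- t(apply(pm$values, 1, function(r) {
    cs <- c(0, cumsum(r))
    cs[(75 + 1):length(cs)] - cs[1:(length(cs) - 75)]
  }))
  expect_equal(bs2$mean, colMeans(win))

  # mismatched targets refuse to subtract
  t3 <- mk_track(base, 5e5)
  expect_error(background_subtract(t3, t1, genes), "different targets")
  # single gene: band undefined
  expect_warning(bs1 <- background_subtract(t2, t1, genes[1, ]), "single gene")
  expect_true(all(is.na(bs1$lo)))
})

test_that("GC profile counts windowed base composition", {
  g <- rbind(make_gene("p", chrom = "c1", tss = 5000, len = 4000),
             make_gene("m", chrom = "c1", strand = "-", tss = 9000, len = 3000))
  all_gc <- setNames(list(strrep("GC", 10000)), "c1")
  pr <- gc_profile(g, all_gc, flank_bp = 200)
  expect_true(all(abs(pr$mean - 1) < 1e-12))
  all_at <- setNames(list(strrep("AT", 10000)), "c1")
  expect_true(all(abs(gc_profile(g, all_at, flank_bp = 200)$mean) < 1e-12))
  # ACGT-repeat genome: every 75-bp window holds 37 or 38 G/C bases
  acgt <- setNames(list(strrep("ACGT", 5000)), "c1")
  pr2 <- gc_profile(g, acgt, flank_bp = 200)
  expect_true(all(abs(pr2$mean - 0.5) <= 0.5 - 37 / 75 + 1e-12))
  expect_equal(mean(pr2$mean), 0.5, tolerance = 1e-3)
})

test_that("interval density is the covered-gene fraction per position", {
  g <- rbind(make_gene("a", chrom = "c1", tss = 5000, len = 4000),
             make_gene("b", chrom = "c1", tss = 20000, len = 4000))
  full <- data.table::data.table(chrom = "c1", start = 0L, end = 30000L)
  d <- interval_density_profile(g, full, flank_bp = 100)
  expect_true(all(d$mean == 1))
  d0 <- interval_density_profile(g, full[0, ], flank_bp = 100)
  expect_true(all(d0$mean == 0))
  # only gene a covered at +100
  iva <- data.table::data.table(chrom = "c1", start = 5100L, end = 5101L)
  dh <- interval_density_profile(g, iva, flank_bp = 200)
  expect_equal(dh$mean[dh$pos == 100], 0.5)
  expect_equal(sum(dh$mean), 0.5)
})

test_that("heatmap ordering sorts rows by rank with stable ties", {
  vals <- rbind(c(1, 2), c(3, 4), c(5, 6))
  m <- fake_matrix(vals, c(0, 1), gene_ids = c("b", "a", "c"))
  id <- heatmap_matrix(m, c(a = 2, b = 1, c = 3))
  expect_identical(id$gene_ids, c("b", "a", "c"))
  expect_identical(id$values, vals)
  rev_ord <- heatmap_matrix(m, c(a = 2, b = 3, c = 1))
  expect_identical(rev_ord$gene_ids, c("c", "a", "b"))
  ties <- heatmap_matrix(m, c(a = 1, b = 1, c = 1))
  expect_identical(ties$gene_ids, c("a", "b", "c"))
  expect_error(heatmap_matrix(m, c(a = 1, b = 2)), "missing gene")
})

test_that("profile matrices and average profiles round-trip through disk", {
  m <- fake_matrix(matrix(c(1.5, 0, 2, 7), 2), c(-1, 0),
                   gene_ids = c("g1", "g2"))
  tmp <- tempfile(fileext = ".tsv.gz")
  write_profile_matrix(m, tmp)
  back <- utils::read.delim(gzfile(tmp), check.names = FALSE)
  expect_identical(back$gene_id, c("g1", "g2"))
  expect_equal(unname(as.matrix(back[, -1])), m$values)
  ap <- average_profile(m)
  tmp2 <- tempfile(fileext = ".tsv")
  write_average_profile(ap, tmp2)
  back2 <- data.table::fread(tmp2)
  expect_equal(back2$mean, ap$mean)
})
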