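# Synthetic data with the statistical structure the analysis assumes:
# isolated gene models, CpG-rich vs CpG-poor promoter sequences, heavy-tailed
# expression, and chromatin reads drawn from parameterized nucleosome
# occupancy / modification placement models. Everything is deterministic
# given the config seed; per-gene read simulation uses seeds derived from it
# so partial regeneration is stable.

#' Configuration for the synthetic dataset
#'
#' @param n_genes number of genes (default 200).
#' @param frac_cpg fraction of genes given a CpG-island promoter
#'   (default 0.5).
#' @param gene_length_bp gene length (default 4000; comfortably above the
#'   3 kb retention threshold).
#' @param gene_spacing_bp distance between consecutive gene slots
#'   (default 8000; guarantees every gene passes the isolation filter).
#' @param margin_bp empty margin at each chromosome end (default 5000).
#' @param expression_meanlog,expression_sdlog log-normal expression
#'   parameters (defaults 4 and 1.5: heavy-tailed, microarray-like).
#' @param read_depth expected reads per track (default 30000, i.e. about
#'   150 per gene at the default gene count).
#' @param fragment_len_bp sequenced fragment length (default 151, so that a
#'   75 bp shift from either end recovers the central dyad).
#' @param seed integer master seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 200L, frac_cpg = 0.5,
                         gene_length_bp = 4000L, gene_spacing_bp = 8000L,
                         margin_bp = 5000L,
                         expression_meanlog = 4, expression_sdlog = 1.5,
                         read_depth = 30000L, fragment_len_bp = 151L,
                         seed = 1L) {
  stopifnot(n_genes >= 1L, frac_cpg >= 0, frac_cpg <= 1,
            fragment_len_bp >= 1L, gene_spacing_bp > gene_length_bp)
  cfg <- list(n_genes = as.integer(n_genes), frac_cpg = frac_cpg,
              gene_length_bp = as.integer(gene_length_bp),
              gene_spacing_bp = as.integer(gene_spacing_bp),
              margin_bp = as.integer(margin_bp),
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              read_depth = as.integer(read_depth),
              fragment_len_bp = as.integer(fragment_len_bp),
              seed = as.integer(seed))
  cfg$chrom_length_bp <- cfg$n_genes * cfg$gene_spacing_bp + 2L * cfg$margin_bp
  class(cfg) <- "synth_config"
  cfg
}

# derived 32-bit sub-seed for gene g of stream k
sub_seed <- function(seed, g, k = 0L) {
  as.integer((as.numeric(seed) * 7919 + g * 104729 + k * 1299709) %% 2147483647)
}

# CpG-rich promoter sequence: with probability p_cg emit a CG dinucleotide,
# otherwise a uniform single base; every 500-bp window then has o/e well
# above 0.75 and GC well above 55%
synth_seq_cpg_rich <- function(len, p_cg = 0.3) {
  n_blocks <- len  # upper bound; blocks of 1 or 2 bases
  pick <- runif(n_blocks) < p_cg
  blocks <- ifelse(pick, "CG", sample(c("A", "C", "G", "T"), n_blocks,
                                      replace = TRUE))
  s <- paste(blocks, collapse = "")
  substr(s, 1L, len)
}

# CpG-poor sequence: i.i.d. bases with moderate GC, CG dinucleotides
# suppressed by redrawing G after C. Suppression is strong enough that even
# the most CpG-dense 500-bp window stays far below an o/e of 0.48
synth_seq_cpg_poor <- function(len, p_keep_cg = 0.05) {
  probs <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  v <- sample(names(probs), len, replace = TRUE, prob = probs)
  for (i in which(v == "G")) {
    if (i > 1L && v[i - 1L] == "C" && runif(1) > p_keep_cg) {
      v[i] <- sample(c("A", "T"), 1L)
    }
  }
  paste(v, collapse = "")
}

#' Generate synthetic gene models, islands, promoters and expression
#'
#' Genes are laid out on one chromosome in regular, well-separated slots with
#' alternating strand, so [filter_genes()] retains all of them. Designated
#' CpG genes get a CpG island (500-1500 bp, centred on the TSS) and a
#' CpG-rich promoter sequence (classified HCP by the windowed scan); the rest
#' get CpG-poor promoters (classified LCP). Expression is i.i.d. log-normal,
#' independent of promoter class, so expression-matching is feasible. CTCF
#' sites are placed at promoters with a probability that increases with
#' expression rank and is higher for CpG promoters, plus intergenic sites.
#'
#' @param config a `synth_config`.
#' @return list with `genes` (gene table), `islands`, `ctcf` (interval
#'   tables), `promoters` (named character vector of 1500-bp strand-oriented
#'   sequences), `expression` (data.table `gene_id, expr`), `classes`
#'   (named vector, the designed CPG/NONCPG labels), `chrom_sizes`.
#' @export
make_genes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rng <- local_rng(config$seed)
  on.exit(rng$restore())
  n <- config$n_genes
  L <- config$gene_length_bp
  if (config$margin_bp < 2000L) stop("margin_bp must be >= 2000 for promoter windows")
  slot <- config$margin_bp + (seq_len(n) - 1L) * config$gene_spacing_bp
  strand <- rep(c("+", "-"), length.out = n)
  tss <- ifelse(strand == "+", slot, slot + L - 1L)
  end <- ifelse(strand == "+", slot + L, slot - 1L)
  genes <- data.table(gene_id = sprintf("G%04d", seq_len(n)), chrom = "chrS",
                      strand = strand, tss = as.integer(tss),
                      end = as.integer(end), n_tss = 1L)
  is_cpg <- seq_len(n) <= round(config$frac_cpg * n)
  is_cpg <- sample(is_cpg)   # decouple class from genomic position
  classes <- setNames(ifelse(is_cpg, "CPG", "NONCPG"), genes$gene_id)
  widths <- as.integer(round(runif(sum(is_cpg), 500, 1500)))
  islands <- data.table(chrom = "chrS",
                        start = as.integer(genes$tss[is_cpg] - widths %/% 2L),
                        end = as.integer(genes$tss[is_cpg] - widths %/% 2L + widths))
  promoters <- character(n)
  for (g in seq_len(n)) {
    promoters[g] <- if (is_cpg[g]) synth_seq_cpg_rich(1500L)
                    else synth_seq_cpg_poor(1500L)
  }
  names(promoters) <- genes$gene_id
  expr <- rlnorm(n, meanlog = config$expression_meanlog,
                 sdlog = config$expression_sdlog)
  expression <- data.table(gene_id = genes$gene_id, expr = expr)
  # CTCF: promoter sites more likely at CpG promoters and at high expression
  r <- rank(expr) / n
  p_site <- ifelse(is_cpg, 0.25 + 0.5 * r, 0.05 + 0.25 * r)
  has_site <- runif(n) < p_site
  ctcf_prom <- data.table(chrom = "chrS",
                          start = as.integer(genes$tss[has_site] - 50L),
                          end = as.integer(genes$tss[has_site] + 50L))
  n_inter <- max(1L, n %/% 4L)
  inter_pos <- as.integer(round(runif(n_inter, 1000, config$chrom_length_bp - 1000)))
  ctcf <- rbind(ctcf_prom,
                data.table(chrom = "chrS", start = inter_pos - 50L,
                           end = inter_pos + 50L))
  list(genes = genes, islands = islands, ctcf = ctcf, promoters = promoters,
       expression = expression, classes = classes,
       chrom_sizes = c(chrS = config$chrom_length_bp))
}

#' Nucleosome-occupancy placement model
#'
#' Uniform background, a phased array of Gaussian nucleosome peaks
#' downstream of the TSS (centres `first_center + spacing * k`), an upstream
#' array mirrored beyond the promoter, and a nucleosome-depleted region
#' (NDR): a multiplicative depletion over `ndr_window` that is constitutive
#' for CpG-promoter genes and present only in highly expressed non-CpG genes
#' (expression-gated).
#'
#' @param background uniform per-bp rate (default 0.2).
#' @param amplitude area of each nucleosome peak (default 60).
#' @param first_center centre of the +1 nucleosome (default +50).
#' @param spacing nucleosome repeat length (default 185).
#' @param sd peak standard deviation (default 30).
#' @param n_nucs number of downstream nucleosomes (default 16).
#' @param ndr_mult depletion multiplier in the NDR (default 0.15).
#' @param ndr_window NDR extent, half-open `[from, to)` (default c(-200, 0)).
#' @param upstream_centers centres of upstream nucleosomes (default
#'   c(-300, -485)).
#' @return list of class `chromatin_model`, type "occupancy".
#' @export
occupancy_model <- function(background = 0.2, amplitude = 60,
                            first_center = 50, spacing = 185, sd = 30,
                            n_nucs = 16L, ndr_mult = 0.15,
                            ndr_window = c(-200L, 0L),
                            upstream_centers = c(-300, -485)) {
  m <- list(type = "occupancy", background = background, amplitude = amplitude,
            first_center = first_center, spacing = spacing, sd = sd,
            n_nucs = n_nucs, ndr_mult = ndr_mult, ndr_window = ndr_window,
            upstream_centers = upstream_centers)
  class(m) <- "chromatin_model"
  m
}

#' Expression-coupled gene-body modification model
#'
#' A Gaussian modification peak whose centre and amplitude depend on the
#' gene's expression tier, over a uniform background: peaks shift further
#' into the gene body and grow with expression.
#'
#' @param center_by_tier named numeric, peak centre (bp downstream of TSS)
#'   per tier (default low/medium/high = 500/800/1100).
#' @param amp_by_tier named numeric, relative peak mass per tier
#'   (default 1/2/3).
#' @param sd peak standard deviation (default 150).
#' @param background uniform per-bp rate (default 0.02).
#' @return list of class `chromatin_model`, type "modification".
#' @export
modification_model <- function(center_by_tier = c(low = 500, medium = 800,
                                                  high = 1100),
                               amp_by_tier = c(low = 1, medium = 2, high = 3),
                               sd = 150, background = 0.02) {
  m <- list(type = "modification", center_by_tier = center_by_tier,
            amp_by_tier = amp_by_tier, sd = sd, background = background)
  class(m) <- "chromatin_model"
  m
}

#' Asymmetric promoter-mark model
#'
#' Two Gaussian peaks flanking the TSS: a fraction `w_up` of the mark's mass
#' sits upstream (centre `-center_offset`) and `1 - w_up` downstream
#' (centre `+center_offset`), both well inside the +/-500 bp asymmetry
#' window.
#'
#' @param w_up upstream mass fraction in `[0, 1]` (default 0.7).
#' @param center_offset distance of each peak centre from the TSS
#'   (default 250).
#' @param sd peak standard deviation (default 60).
#' @param background uniform per-bp rate (default 0).
#' @return list of class `chromatin_model`, type "promoter_mark".
#' @export
promoter_mark_model <- function(w_up = 0.7, center_offset = 250, sd = 60,
                                background = 0) {
  stopifnot(w_up >= 0, w_up <= 1)
  m <- list(type = "promoter_mark", w_up = w_up,
            center_offset = center_offset, sd = sd, background = background)
  class(m) <- "chromatin_model"
  m
}

#' Per-position dyad rate for one gene under a chromatin model
#'
#' @param model a `chromatin_model`.
#' @param rel integer vector of positions relative to the TSS,
#'   sense-oriented.
#' @param class `"CPG"` or `"NONCPG"` (gates the NDR of the occupancy
#'   model).
#' @param tier expression tier label (selects modification centre/amplitude;
#'   gates the non-CpG NDR: present only for `"high"`).
#' @return non-negative numeric rate per position (arbitrary units).
#' @export
model_rate <- function(model, rel, class = "CPG", tier = "high") {
  stopifnot(inherits(model, "chromatin_model"))
  if (model$type == "occupancy") {
    centers <- c(model$first_center + model$spacing * (seq_len(model$n_nucs) - 1L),
                 model$upstream_centers)
    rate <- rep(model$background, length(rel))
    for (c0 in centers) {
      rate <- rate + model$amplitude * stats::dnorm(rel, mean = c0, sd = model$sd)
    }
    has_ndr <- class == "CPG" || (class == "NONCPG" && tier == "high")
    if (has_ndr) {
      in_ndr <- rel >= model$ndr_window[1] & rel < model$ndr_window[2]
      rate[in_ndr] <- rate[in_ndr] * model$ndr_mult
    }
    return(rate)
  }
  if (model$type == "modification") {
    if (!tier %in% names(model$center_by_tier)) {
      stop("unknown tier '", tier, "' for modification model")
    }
    return(model$background +
             model$amp_by_tier[[tier]] * 100 *
             stats::dnorm(rel, mean = model$center_by_tier[[tier]],
                          sd = model$sd))
  }
  if (model$type == "promoter_mark") {
    return(model$background +
             100 * (model$w_up *
                      stats::dnorm(rel, -model$center_offset, model$sd) +
                    (1 - model$w_up) *
                      stats::dnorm(rel, model$center_offset, model$sd)))
  }
  stop("unknown model type: ", model$type)
}

#' Simulate mapped reads for a gene set under a chromatin model
#'
#' For each gene, dyad positions are drawn from the model's per-position
#' rate over `window` (sense-oriented, mapped back to genomic coordinates);
#' read totals per gene are Poisson with mean proportional to the gene's
#' rate mass, summing to `config$read_depth` in expectation. Each dyad is
#' emitted as a read of `config$fragment_len_bp` on a random strand
#' (Bernoulli 0.5, independent of the gene's strand, as for ChIP fragments),
#' positioned so that [shift_to_dyad()] with `shift_bp` recovers the dyad
#' exactly. Per-gene randomness uses seeds derived from the config seed.
#'
#' @param genes gene table.
#' @param model a `chromatin_model`.
#' @param config a `synth_config`.
#' @param classes named vector `gene_id -> CPG/NONCPG` (default all CPG).
#' @param tiers named vector `gene_id -> tier` (default all "high").
#' @param window sense-oriented simulation window around the TSS
#'   (default c(-600, 3100)).
#' @param shift_bp dyad shift the downstream pipeline will apply
#'   (default 75).
#' @param stream integer stream id, so distinct tracks simulated from the
#'   same config are independent (default 0).
#' @return data.table of reads: `chrom, start, end, name, score, strand`.
#' @export
simulate_reads <- function(genes, model, config, classes = NULL, tiers = NULL,
                           window = c(-600L, 3100L), shift_bp = 75L,
                           stream = 0L) {
  stopifnot(inherits(config, "synth_config"))
  genes <- validate_genes(genes)
  rel <- seq.int(window[1], window[2])
  n <- nrow(genes)
  if (is.null(classes)) classes <- setNames(rep("CPG", n), genes$gene_id)
  if (is.null(tiers)) tiers <- setNames(rep("high", n), genes$gene_id)
  rates <- lapply(seq_len(n), function(g) {
    model_rate(model, rel, class = classes[[genes$gene_id[g]]],
               tier = tiers[[genes$gene_id[g]]])
  })
  mass <- vapply(rates, sum, numeric(1))
  mean_reads <- config$read_depth * mass / sum(mass)
  frag <- config$fragment_len_bp
  out <- vector("list", n)
  for (g in seq_len(n)) {
    rng <- local_rng(sub_seed(config$seed, g, stream))
    n_g <- rpois(1L, mean_reads[g])
    if (n_g == 0L) { rng$restore(); next }
    k <- sample.int(length(rel), n_g, replace = TRUE, prob = rates[[g]])
    dy <- if (genes$strand[g] == "+") genes$tss[g] + rel[k]
          else genes$tss[g] - rel[k]
    read_strand <- ifelse(runif(n_g) < 0.5, "+", "-")
    start <- ifelse(read_strand == "+", dy - shift_bp, dy + shift_bp + 1L - frag)
    end <- start + frag
    rng$restore()
    keep <- start >= 0L
    out[[g]] <- data.table(chrom = genes$chrom[g],
                           start = as.integer(start[keep]),
                           end = as.integer(end[keep]),
                           name = ".", score = 0L,
                           strand = read_strand[keep])
  }
  data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
}

#' Write a complete miniature synthetic dataset to disk
#'
#' Emits exactly the file formats the pipeline consumes: gene table TSV,
#' CpG-island BED, CTCF BED, promoter FASTA, expression TSV, chromosome
#' sizes, and one 6-column BED of reads per track (nucleosome occupancy, an
#' expression-coupled gene-body mark, an asymmetric promoter mark, and a
#' promoter-proximal mark with a fixed peak).
#'
#' @param dir output directory (created if needed).
#' @param config a `synth_config` (default `synth_config()`).
#' @return invisible named list of the file paths written.
#' @export
make_fixtures <- function(dir, config = synth_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- make_genes(config)
  tiers <- tier_split(d$expression)
  paths <- list(
    genes = file.path(dir, "genes.tsv"),
    islands = file.path(dir, "cpg_islands.bed"),
    ctcf = file.path(dir, "ctcf_peaks.bed"),
    promoters = file.path(dir, "promoters.fa"),
    expression = file.path(dir, "expression.tsv"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    occupancy = file.path(dir, "reads_occupancy.bed"),
    body_mark = file.path(dir, "reads_body_mark.bed"),
    promoter_mark = file.path(dir, "reads_promoter_mark.bed"),
    fixed_mark = file.path(dir, "reads_fixed_mark.bed"),
    config = file.path(dir, "config.yaml"))
  fwrite(d$genes, paths$genes, sep = "\t")
  fwrite(d$islands[, c("chrom", "start", "end")], paths$islands,
         sep = "\t", col.names = FALSE)
  fwrite(d$ctcf[, c("chrom", "start", "end")], paths$ctcf,
         sep = "\t", col.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(d$promoters),
                              paths$promoters)
  fwrite(d$expression, paths$expression, sep = "\t")
  writeLines(paste("chrS", config$chrom_length_bp, sep = "\t"),
             paths$chrom_sizes)
  tracks <- list(
    occupancy = list(model = occupancy_model(), stream = 1L),
    body_mark = list(model = modification_model(), stream = 2L),
    promoter_mark = list(model = promoter_mark_model(), stream = 3L),
    fixed_mark = list(model = modification_model(
      center_by_tier = c(low = 300, medium = 300, high = 300),
      amp_by_tier = c(low = 1, medium = 1, high = 1)), stream = 4L))
  for (nm in names(tracks)) {
    reads <- simulate_reads(d$genes, tracks[[nm]]$model, config,
                            classes = d$classes, tiers = tiers,
                            stream = tracks[[nm]]$stream)
    fwrite(reads, paths[[nm]], sep = "\t", col.names = FALSE)
  }
  cfg <- unclass(config)
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
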