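# End-to-end orchestration: classification, matching, tracks, profiles,
# statistics, manifest. Intermediate artifacts are plain files so stages
# compose externally.

#' Build a pipeline configuration
#'
#' Collects input paths and every tunable parameter of the analysis, each at
#' its standard default. The configuration is serialized verbatim into the
#' output directory by [run_pipeline()].
#'
#' @param genes,islands,ctcf,promoters,expression,chrom_sizes input paths
#'   (gene TSV, BED, BED, FASTA, TSV, two-column sizes).
#' @param tracks named character vector of read BED paths, one per chromatin
#'   mark; must include an element named `occupancy` (nucleosome occupancy)
#'   for background subtraction.
#' @param out_dir output directory.
#' @param shift_bp dyad shift (default 75).
#' @param target_total track rescaling target (default 1e7).
#' @param min_length_bp,isolation_bp gene filters (defaults 3000, 500).
#' @param upstream_bp,downstream_bp profile window (defaults 500, 3000).
#' @param span_bp loess span (default 180).
#' @param window_bp background-subtraction window (default 75).
#' @param per_tier matched pairs requested per tier (default 500).
#' @param tolerance_ln matching tolerance in ln units (default 0.1).
#' @param search_bp peak search bound (default 2000).
#' @param peak_smooth_bp running-mean width for per-gene peak calling
#'   (default 151).
#' @param n_bins expression bins for overlap enrichment (default 10).
#' @param seed integer seed for the matching sampler.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes, islands, ctcf = NULL, promoters = NULL,
                            expression, chrom_sizes, tracks, out_dir,
                            shift_bp = 75L, target_total = 1e7,
                            min_length_bp = 3000L, isolation_bp = 500L,
                            upstream_bp = 500L, downstream_bp = 3000L,
                            span_bp = 180L, window_bp = 75L,
                            per_tier = 500L, tolerance_ln = 0.1,
                            search_bp = 2000L, peak_smooth_bp = 151L,
                            n_bins = 10L, seed = 1L) {
  req <- list(genes = genes, islands = islands, expression = expression,
              chrom_sizes = chrom_sizes)
  for (nm in names(req)) {
    if (is.null(req[[nm]])) stop("config missing required input: ", nm)
  }
  if (length(tracks) == 0L || is.null(names(tracks))) {
    stop("tracks must be a named vector of read BED paths")
  }
  cfg <- c(req, list(ctcf = ctcf, promoters = promoters,
                     tracks = as.list(tracks), out_dir = out_dir,
                     shift_bp = shift_bp, target_total = target_total,
                     min_length_bp = min_length_bp, isolation_bp = isolation_bp,
                     upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                     span_bp = span_bp, window_bp = window_bp,
                     per_tier = per_tier, tolerance_ln = tolerance_ln,
                     search_bp = search_bp, peak_smooth_bp = peak_smooth_bp,
                     n_bins = n_bins, seed = seed))
  class(cfg) <- "pipeline_config"
  cfg
}

read_chrom_sizes <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t")
  setNames(as.integer(x[[2]]), as.character(x[[1]]))
}

#' Run the full comparative chromatin-profiling pipeline
#'
#' Stages: load and filter genes; classify promoters by CpG-island overlap
#' (and by the windowed CpG scan when promoter sequences are supplied);
#' build expression tiers and expression-matched CpG / non-CpG sets; build
#' dyad tracks; for each mark write average, loess-smoothed, and
#' background-subtracted profiles for the six class-by-tier groups plus
#' heatmap matrices over all classified genes; compute asymmetry, peak-shift
#' and CTCF-enrichment reports; and write a manifest with input checksums
#' and the configuration. All randomness flows from `config$seed`, so a
#' rerun reproduces every numeric output byte for byte.
#'
#' @param config a `pipeline_config`.
#' @return invisible list of the principal results (matched sets, stats
#'   reports, output paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  genes <- stage("load_genes", read_gene_table(config$genes))
  islands <- stage("load_islands", read_bed(config$islands))
  expression <- stage("load_expression", read_expression(config$expression))
  chrom_sizes <- stage("load_chrom_sizes", read_chrom_sizes(config$chrom_sizes))

  genes <- stage("filter_genes",
                 filter_genes(genes, min_length_bp = config$min_length_bp,
                              isolation_bp = config$isolation_bp))
  genes <- genes[genes$gene_id %in% expression$gene_id, ]
  if (nrow(genes) == 0L) stop("stage 'filter_genes' failed: no genes with expression left")
  classes <- stage("classify_islands", classify_island_overlap(genes, islands))
  class_tab <- data.table(gene_id = genes$gene_id,
                          island_class = classes[genes$gene_id])
  if (!is.null(config$promoters)) {
    proms <- stage("load_promoters", {
      p <- Biostrings::readDNAStringSet(config$promoters)
      setNames(as.character(p), names(p))
    })
    class_tab$weber_class <- vapply(class_tab$gene_id, function(g) {
      if (g %in% names(proms)) classify_weber(proms[[g]]) else "UNKNOWN"
    }, character(1))
  } else {
    class_tab$weber_class <- "UNKNOWN"
  }
  fwrite(class_tab, file.path(out, "promoter_classes.tsv"), sep = "\t")

  expression <- expression[expression$gene_id %in% genes$gene_id, ]
  ranked <- rank_expression(expression)
  tiers <- tier_split(expression)
  expr_by_class <- split(as.data.frame(expression),
                         classes[expression$gene_id])
  if (is.null(expr_by_class$CPG) || is.null(expr_by_class$NONCPG)) {
    stop("stage 'match' failed: need both CPG and NONCPG genes")
  }
  matched <- stage("match",
                   sample_matched(expr_by_class$NONCPG, expr_by_class$CPG,
                                  per_tier = config$per_tier,
                                  tolerance_ln = config$tolerance_ln,
                                  seed = config$seed))
  write_matched(matched, file.path(out, "matched_gene_sets.tsv"))

  tracks <- stage("tracks", lapply(config$tracks, function(p) {
    build_track(read_mapped_reads(p), chrom_sizes,
                target_total = config$target_total,
                shift_bp = config$shift_bp)
  }))

  groups <- list()
  for (cl in c("CPG", "NONCPG")) {
    for (ti in c("low", "medium", "high")) {
      ids <- if (cl == "CPG") matched$pairs$cpg_id[matched$pairs$tier == ti]
             else matched$pairs$noncpg_id[matched$pairs$tier == ti]
      groups[[paste(cl, ti, sep = "_")]] <- ids
    }
  }

  ranks_vec <- setNames(ranked$rank, ranked$gene_id)
  prof_dir <- file.path(out, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  matrices <- list()
  for (mk in names(tracks)) {
    pm_all <- stage(paste0("profile_", mk),
                    profile_matrix(tracks[[mk]], genes,
                                   upstream_bp = config$upstream_bp,
                                   downstream_bp = config$downstream_bp))
    matrices[[mk]] <- pm_all
    hm <- heatmap_matrix(pm_all, ranks_vec)
    write_profile_matrix(hm, file.path(prof_dir, paste0("heatmap_", mk, ".tsv")))
    for (gp in names(groups)) {
      ids <- groups[[gp]]
      if (length(ids) == 0L) next
      sub <- genes[match(ids, genes$gene_id), ]
      pm <- profile_matrix(tracks[[mk]], sub,
                           upstream_bp = config$upstream_bp,
                           downstream_bp = config$downstream_bp)
      ap <- loess_smooth(average_profile(pm), span_bp = config$span_bp)
      write_average_profile(ap, file.path(
        prof_dir, paste0("avg_", mk, "_", gp, ".tsv")))
      if (mk != "occupancy" && "occupancy" %in% names(tracks)) {
        bs <- background_subtract(tracks[[mk]], tracks$occupancy, sub,
                                  upstream_bp = config$upstream_bp,
                                  downstream_bp = config$downstream_bp,
                                  window_bp = config$window_bp)
        write_average_profile(bs, file.path(
          prof_dir, paste0("bgsub_", mk, "_", gp, ".tsv")))
      }
    }
  }

  stats_dir <- file.path(out, "stats")
  dir.create(stats_dir, showWarnings = FALSE)
  reports <- list()
  marks <- setdiff(names(tracks), "occupancy")

  # promoter asymmetry at highly expressed matched genes, per mark
  asym_report <- list()
  for (mk in marks) {
    hi_cpg <- groups$CPG_high; hi_non <- groups$NONCPG_high
    if (length(hi_cpg) < 2L || length(hi_non) < 2L) next
    sc <- asymmetry_score(matrices[[mk]])$scores
    cpg_s <- sc[names(sc) %in% hi_cpg]
    non_s <- sc[names(sc) %in% hi_non]
    if (length(cpg_s) < 2L || length(non_s) < 2L) next
    cmp <- compare_asymmetry(cpg_s, non_s)
    fwrite(data.table(gene_id = c(names(cpg_s), names(non_s)),
                      class = rep(c("CPG", "NONCPG"),
                                  c(length(cpg_s), length(non_s))),
                      score = c(cpg_s, non_s)),
           file.path(stats_dir, paste0("asymmetry_", mk, ".tsv")), sep = "\t")
    asym_report[[mk]] <- c(cmp, list(median_cpg = stats::median(cpg_s),
                                     median_noncpg = stats::median(non_s)))
  }
  reports$asymmetry <- asym_report

  # expression-coupled peak shift, per mark and class, over matched genes
  peak_report <- list()
  for (mk in marks) {
    pk <- peak_positions(matrices[[mk]], search_bp = config$search_bp,
                         smooth_bp = config$peak_smooth_bp)$peaks
    fwrite(data.table(gene_id = names(pk), peak_pos = as.integer(pk)),
           file.path(stats_dir, paste0("peaks_", mk, ".tsv")), sep = "\t")
    for (cl in c("CPG", "NONCPG")) {
      ids <- unlist(groups[paste(cl, c("low", "medium", "high"), sep = "_")],
                    use.names = FALSE)
      sub <- pk[names(pk) %in% ids]
      if (length(sub) < 3L) next
      peak_report[[paste(mk, cl, sep = "_")]] <-
        peak_shift_correlation(sub, ranks_vec)
    }
  }
  reports$peak_shift <- peak_report

  # CTCF overlap enrichment by expression bin
  if (!is.null(config$ctcf)) {
    ctcf <- stage("load_ctcf", read_bed(config$ctcf))
    ov <- overlaps_any(genes, ctcf, mode = "tss_point")
    enr <- ctcf_enrichment(classes, ov, ranks_vec, n_bins = config$n_bins)
    fwrite(enr$per_bin, file.path(stats_dir, "ctcf_enrichment_bins.tsv"),
           sep = "\t")
    reports$ctcf <- list(chi2_statistic = enr$chi2_statistic,
                         chi2_p = enr$chi2_p,
                         table = as.list(as.data.frame(enr$table)))
  }

  jsonlite::write_json(reports, file.path(stats_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  inputs <- c(genes = config$genes, islands = config$islands,
              expression = config$expression, chrom_sizes = config$chrom_sizes,
              ctcf = config$ctcf, promoters = config$promoters,
              unlist(config$tracks))
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    inputs = as.list(tools::md5sum(unlist(inputs))),
    config = unclass(config),
    groups = lapply(groups, length),
    n_genes = nrow(genes))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  invisible(list(genes = genes, classes = classes, matched = matched,
                 tiers = tiers, reports = reports, out_dir = out))
}
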