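# Expression ranking, tiering, and expression-matched gene-set construction.

#' Collapse probe-level expression to gene level
#'
#' Probes mapping to multiple genes are discarded; each remaining gene gets
#' the value of its most sensitive probe, interpreted as the maximum
#' (replicate-averaged) probe value.
#'
#' @param probes data.frame with columns `probe_id`, `expr`
#'   (replicate-averaged linear-scale value).
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; probes
#'   occurring with more than one gene are dropped.
#' @return data.table with columns `gene_id`, `expr`.
#' @export
collapse_probes <- function(probes, probe_map) {
  probes <- as.data.table(probes)
  probe_map <- as.data.table(probe_map)
  multi <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
  keep <- probe_map[!probe_map$probe_id %in% multi, ]
  m <- merge(keep, probes, by = "probe_id")
  out <- m[, list(expr = max(expr)), by = "gene_id"]
  data.table::setorder(out, gene_id)
  out[]
}

#' Rank genes by expression
#'
#' Ranks are 1 = lowest expression; ties are broken by `gene_id` in
#' lexicographic order so ranking is deterministic.
#'
#' @param records data.frame with columns `gene_id`, `expr` (positive,
#'   linear scale).
#' @return data.table with columns `gene_id`, `expr`, `rank`.
#' @export
rank_expression <- function(records) {
  records <- as.data.table(records)
  if (!all(c("gene_id", "expr") %in% names(records))) {
    stop("expression records need columns gene_id and expr")
  }
  if (any(!is.finite(records$expr) | records$expr <= 0)) {
    stop("all expr values must be positive and finite (linear scale)")
  }
  ord <- order(records$expr, records$gene_id)
  out <- records[ord, c("gene_id", "expr"), with = FALSE]
  out$rank <- seq_len(nrow(out))
  out[]
}

#' Split ranked genes into expression tiers
#'
#' Splits genes into `n_tiers` contiguous rank groups of (near-)equal size;
#' when sizes cannot be equal, the remainder goes to the lowest tier. With
#' the default three tiers the labels are `low`, `medium`, `high`.
#'
#' @param records data.frame with `gene_id`, `expr` (ranked internally via
#'   [rank_expression()]).
#' @param n_tiers number of tiers (default 3).
#' @return named character vector `gene_id -> tier label` (in rank order).
#' @export
tier_split <- function(records, n_tiers = 3L) {
  ranked <- rank_expression(records)
  n <- nrow(ranked)
  if (n < n_tiers) stop("fewer genes (", n, ") than tiers (", n_tiers, ")")
  base <- n %/% n_tiers
  rem <- n %% n_tiers
  sizes <- rep(base, n_tiers)
  sizes[1L] <- sizes[1L] + rem   # remainder to the lowest tier
  labels <- if (n_tiers == 3L) c("low", "medium", "high")
            else paste0("tier", seq_len(n_tiers))
  setNames(rep(labels, times = sizes), ranked$gene_id)
}

#' Build expression-matched CpG / non-CpG gene sets
#'
#' Within each expression tier, `per_tier` non-CpG promoter genes are sampled
#' uniformly without replacement; each is matched greedily, in sampled order,
#' to the unused CpG gene minimizing the absolute difference in natural-log
#' expression, accepted only when that difference is at most `tolerance_ln`.
#' Non-CpG genes that cannot be matched are replaced by fresh samples until
#' `per_tier` pairs exist or the tier is exhausted (genes with extreme
#' expression for which no similarly expressed partner exists are thereby
#' dropped). Tiers are defined on the pooled ranking of both groups.
#'
#' @param noncpg,cpg data.frames with `gene_id`, `expr` for the two promoter
#'   classes (disjoint gene sets).
#' @param per_tier pairs requested per tier (default 500).
#' @param tolerance_ln maximum |difference of ln expression| (default 0.1).
#' @param seed integer seed for the sampling RNG.
#' @param n_tiers number of expression tiers (default 3).
#' @return object of class `matched_gene_sets`: list with `pairs` (data.table
#'   `tier, noncpg_id, cpg_id, delta_ln`), `seed`, `tolerance`.
#' @export
sample_matched <- function(noncpg, cpg, per_tier = 500L, tolerance_ln = 0.1,
                           seed, n_tiers = 3L) {
  stopifnot(!missing(seed))
  noncpg <- as.data.table(noncpg)
  cpg <- as.data.table(cpg)
  if (length(intersect(noncpg$gene_id, cpg$gene_id)) > 0L) {
    stop("gene sets must be disjoint")
  }
  pooled <- rbind(noncpg[, c("gene_id", "expr"), with = FALSE],
                  cpg[, c("gene_id", "expr"), with = FALSE])
  tiers <- tier_split(pooled, n_tiers = n_tiers)
  labels <- unique(unname(tiers))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  out <- vector("list", length(labels))
  for (ti in seq_along(labels)) {
    lab <- labels[ti]
    nc <- noncpg[tiers[noncpg$gene_id] == lab, ]
    cp <- cpg[tiers[cpg$gene_id] == lab, ]
    data.table::setorder(nc, gene_id)  # stable candidate order before sampling
    cand_ln <- sort(log(cp$expr))
    cand_id <- cp$gene_id[order(log(cp$expr), cp$gene_id)]
    used_c <- rep(FALSE, length(cand_ln))
    # sampled order = a seeded permutation of the non-CpG tier; walk it,
    # which realises "sample, match, replace failures with fresh samples"
    perm <- sample.int(nrow(nc))
    pairs_nc <- character(0); pairs_cp <- character(0); pairs_d <- numeric(0)
    for (i in perm) {
      if (length(pairs_nc) >= per_tier) break
      x <- log(nc$expr[i])
      j <- nearest_unused(cand_ln, used_c, x)
      if (is.na(j)) next
      d <- abs(cand_ln[j] - x)
      if (d <= tolerance_ln) {
        used_c[j] <- TRUE
        pairs_nc <- c(pairs_nc, nc$gene_id[i])
        pairs_cp <- c(pairs_cp, cand_id[j])
        pairs_d <- c(pairs_d, d)
      }
    }
    if (length(pairs_nc) < per_tier) {
      warning("tier '", lab, "': only ", length(pairs_nc), " of ", per_tier,
              " pairs could be matched at tolerance ", tolerance_ln)
    }
    out[[ti]] <- data.table(tier = lab, noncpg_id = pairs_nc,
                            cpg_id = pairs_cp, delta_ln = pairs_d)
  }
  res <- list(pairs = data.table::rbindlist(out), seed = seed,
              tolerance = tolerance_ln)
  class(res) <- "matched_gene_sets"
  res
}

# index of the unused element of sorted vector `v` nearest to `x`, NA if none
nearest_unused <- function(v, used, x) {
  j <- findInterval(x, v)
  lo <- j; hi <- j + 1L
  while (lo >= 1L && used[lo]) lo <- lo - 1L
  while (hi <= length(v) && used[hi]) hi <- hi + 1L
  has_lo <- lo >= 1L; has_hi <- hi <= length(v)
  if (!has_lo && !has_hi) return(NA_integer_)
  if (!has_hi) return(lo)
  if (!has_lo) return(hi)
  if (abs(v[lo] - x) <= abs(v[hi] - x)) lo else hi
}

# seeded RNG scope: sets the seed, returns a restorer for the previous state
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
}

#' @export
print.matched_gene_sets <- function(x, ...) {
  cat("Expression-matched gene sets (seed ", x$seed, ", tolerance ",
      x$tolerance, " ln units)\n", sep = "")
  tab <- table(x$pairs$tier)
  for (lab in names(tab)) cat("  ", lab, ": ", tab[[lab]], " pairs\n", sep = "")
  invisible(x)
}

#' Write matched gene sets as TSV
#'
#' Columns `tier noncpg_id cpg_id delta_ln`.
#'
#' @param x a `matched_gene_sets` object.
#' @param path output file path.
#' @export
write_matched <- function(x, path) {
  stopifnot(inherits(x, "matched_gene_sets"))
  fwrite(x$pairs, path, sep = "\t")
  invisible(path)
}

#' Read an expression table
#'
#' Tab-delimited with header `gene_id expr` (linear scale).
#'
#' @param path file path.
#' @return data.table with `gene_id`, `expr`.
#' @export
read_expression <- function(path) {
  x <- fread(path, sep = "\t")
  if (!all(c("gene_id", "expr") %in% names(x))) {
    stop("expression table needs columns gene_id and expr: ", path)
  }
  x
}
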