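# Genomic-context annotation: TSS-window / gene-body / exon classification,
# nearest-gene assignment, and per-element aggregation of per-base
# conservation scores (phyloP / phastCons style tracks).

# [tss - window, tss + window] inclusive -> 0-based half-open window
tss_windows <- function(genes, window) {
  if (!length(genes))
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  genomic_intervals(
    seq_id = vapply(genes, function(g) g$interval$seq_id, ""),
    start  = pmax(0, vapply(genes, function(g) g$tss, 0) - window),
    end    = vapply(genes, function(g) g$tss, 0) + window + 1,
    name   = vapply(genes, function(g) g$gene_id, "")
  )
}

gene_bodies <- function(genes) {
  if (!length(genes))
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  do.call(rbind, lapply(genes, function(g) as.data.frame(g$interval))) |>
    validate_intervals()
}

gene_exons <- function(genes) {
  ex <- lapply(genes, function(g) as.data.frame(g$exons))
  ex <- ex[vapply(ex, nrow, 1L) > 0]
  if (!length(ex))
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  validate_intervals(do.call(rbind, ex))
}

overlaps_any <- function(res, targets) {
  hit <- logical(nrow(res))
  if (nrow(res) && nrow(targets)) hit[unique(iv_overlap_pairs(res, targets)$a)] <- TRUE
  hit
}

#' Three-way genomic-location classification
#'
#' Each RE is `tss_proximal` if it overlaps (>= 1 bp) the TSS +/- `window`
#' region of any gene; otherwise `genic` if it overlaps any gene body;
#' otherwise `intergenic`. Precedence is tss_proximal > genic > intergenic.
#' The window is symmetric around the TSS by default; pass
#' `upstream`/`downstream` to make it asymmetric.
#'
#' @param res [genomic_intervals] of REs.
#' @param genes gene models from [read_gff_genes].
#' @param window half-width in bases of the TSS window (default 2000, i.e.
#'   TSS +/- 2 kb).
#' @return character vector, one of `tss_proximal` / `genic` / `intergenic`
#'   per RE.
#' @export
classify_location <- function(res, genes, window = 2000) {
  tssw <- tss_windows(genes, window)
  bodies <- gene_bodies(genes)
  out <- rep("intergenic", nrow(res))
  out[overlaps_any(res, bodies)] <- "genic"
  out[overlaps_any(res, tssw)] <- "tss_proximal"
  out
}

#' Four-way genomic-feature classification
#'
#' `promoter` (overlaps a TSS +/- `window` region) > `exonic` (overlaps an
#' exon) > `intronic` (overlaps a gene body) > `intergenic`. The promoter is
#' deliberately the same TSS window as [classify_location], so
#' `tss_proximal` and `promoter` agree under an equal window.
#'
#' @inheritParams classify_location
#' @return character vector, one of `promoter` / `exonic` / `intronic` /
#'   `intergenic` per RE.
#' @export
classify_feature <- function(res, genes, window = 2000) {
  out <- rep("intergenic", nrow(res))
  out[overlaps_any(res, gene_bodies(genes))] <- "intronic"
  out[overlaps_any(res, gene_exons(genes))] <- "exonic"
  out[overlaps_any(res, tss_windows(genes, window))] <- "promoter"
  out
}

#' Nearest-gene assignment
#'
#' Distance is the interval-to-interval base gap (0 when overlapping),
#' minimised over genes on the same sequence; ties broken by the
#' lexicographically smaller gene id. REs on gene-free sequences get
#' `NA` gene and distance.
#'
#' @inheritParams classify_location
#' @return data.frame `re_name`, `gene_id`, `distance`, one row per RE in
#'   input order.
#' @export
nearest_gene <- function(res, genes) {
  out <- data.frame(re_name = res$name, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  if (!nrow(res) || !length(genes)) return(out)
  gb <- gene_bodies(genes)
  gr_re <- iv_as_granges(res)
  gr_g <- iv_as_granges(gb)
  for (i in seq_len(nrow(res))) {
    same <- which(gb$seq_id == res$seq_id[i])
    if (!length(same)) next
    d <- GenomicRanges::distance(gr_re[i], gr_g[same], ignore.strand = TRUE)
    dmin <- min(d)
    cand <- gb$name[same[d == dmin]]
    out$gene_id[i] <- sort(cand)[1]
    out$distance[i] <- dmin
  }
  out
}

#' Aggregate per-base conservation scores per RE and per category
#'
#' The per-RE mean is taken over the bases that carry a score: unscored bases
#' are excluded from both numerator and denominator, and an RE with no scored
#' base gets `NA` (flagged, never silently 0). Per-category summaries are the
#' mean and population standard deviation (n denominator -- the summaries are
#' descriptive of the full element set, not sample estimates) of the per-RE
#' means.
#'
#' @param res [genomic_intervals] of REs.
#' @param track a `score_track` from [read_score_track].
#' @param categories optional factor/character of per-RE categories; when
#'   given, per-category aggregates are computed.
#' @return list with `per_re` (data.frame `re_name`, `mean_score`,
#'   `n_bases_scored`) and `per_category` (data.frame `category`, `n`,
#'   `mean`, `sd`), the latter `NULL` when `categories` is missing.
#' @export
aggregate_scores <- function(res, track, categories = NULL) {
  means <- rep(NA_real_, nrow(res))
  nb <- numeric(nrow(res))
  h <- iv_overlap_pairs(res, track)
  if (nrow(h)) {
    w <- pmin(res$end[h$a], track$end[h$b]) - pmax(res$start[h$a], track$start[h$b])
    ssum <- tapply(w * track$score[h$b], h$a, sum)
    wsum <- tapply(w, h$a, sum)
    idx <- as.integer(names(wsum))
    nb[idx] <- as.numeric(wsum)
    means[idx] <- as.numeric(ssum) / as.numeric(wsum)
  }
  per_re <- data.frame(re_name = res$name, mean_score = means,
                       n_bases_scored = nb, stringsAsFactors = FALSE)
  per_cat <- NULL
  if (!is.null(categories)) {
    categories <- factor(as.character(categories), levels = re_categories())
    pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
    per_cat <- do.call(rbind, lapply(levels(categories), function(cc) {
      x <- means[!is.na(means) & categories == cc]
      data.frame(category = cc, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x)) pop_sd(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_re = per_re, per_category = per_cat)
}
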