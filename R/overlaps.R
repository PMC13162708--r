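# TE coverage, TE class composition, motif presence/TE overlap, and QTL
# intersection per constraint tier. All overlaps are >= 1 bp; TE intervals
# are merged (union) before base counting so nested RepeatMasker calls are
# never double-counted.

cat_levels_present <- function(categories) {
  lv <- re_categories()
  c(lv[lv %in% unique(as.character(categories))], "all")
}

re_subset <- function(res, categories, cc) {
  if (cc == "all") res else res[as.character(categories) == cc, , drop = FALSE]
}

#' TE coverage of REs, per constraint tier
#'
#' Coverage is a union measure: TEs are merged per sequence first, then the
#' covered fraction is (covered RE bases) / (total RE bases) within each
#' category and overall.
#'
#' @param res [genomic_intervals] of REs.
#' @param tes [genomic_intervals] of transposable elements.
#' @param categories per-RE category vector (parallel to `res` rows); `NULL`
#'   reports a single overall row.
#' @return data.frame `category`, `n_res`, `total_re_bases`,
#'   `te_covered_bases`, `coverage_fraction` (a final row `all` aggregates
#'   every RE).
#' @export
te_coverage <- function(res, tes, categories = NULL) {
  if (!nrow(res)) stop("empty RE set", call. = FALSE)
  if (is.null(categories)) categories <- rep("all", nrow(res))
  covered <- iv_covered_bases(res, tes)
  lens <- iv_width(res)
  do.call(rbind, lapply(cat_levels_present(categories), function(cc) {
    sel <- if (cc == "all") rep(TRUE, nrow(res)) else as.character(categories) == cc
    data.frame(category = cc, n_res = sum(sel),
               total_re_bases = sum(lens[sel]),
               te_covered_bases = sum(covered[sel]),
               coverage_fraction = sum(covered[sel]) / sum(lens[sel]),
               stringsAsFactors = FALSE)
  }))
}

# Disjoint attribution of overlapping TEs of different classes: the longer
# element claims shared bases; ties go to the lexicographically smaller
# class. Returns disjoint class-labelled pieces.
te_disjoint_pieces <- function(tes) {
  if (!nrow(tes)) return(tes)
  if (is.null(tes$te_class)) stop("TEs must carry a te_class column", call. = FALSE)
  ord <- order(-iv_width(tes), tes$te_class, tes$seq_id, tes$start)
  claimed <- GenomicRanges::GRanges()
  pieces <- list()
  for (i in ord) {
    g <- iv_as_granges(tes[i, , drop = FALSE])
    GenomicRanges::strand(g) <- "*"
    # suppress the disjoint-seqlevels advisory: pieces legitimately live on
    # sequences the claimed set has not touched yet
    new <- suppressWarnings(GenomicRanges::setdiff(g, claimed, ignore.strand = TRUE))
    if (!length(new)) next
    claimed <- suppressWarnings(GenomicRanges::union(claimed, new, ignore.strand = TRUE))
    p <- granges_as_iv(new)
    p$te_class <- tes$te_class[i]
    pieces[[length(pieces) + 1]] <- as.data.frame(p)
  }
  validate_intervals(do.call(rbind, pieces))
}

#' TE class composition of RE coverage, per constraint tier
#'
#' Overlapping TEs of different classes are attributed disjointly (longer
#' element wins shared bases, ties by lexicographic class order), so the
#' per-class covered bases sum exactly to the merged TE coverage of
#' [te_coverage]. Unrecognised class labels are kept verbatim.
#'
#' @inheritParams te_coverage
#' @return data.frame `category`, `te_class`, `covered_bases`,
#'   `fraction_of_re_bases`.
#' @export
te_class_composition <- function(res, tes, categories = NULL) {
  if (!nrow(res)) stop("empty RE set", call. = FALSE)
  if (is.null(categories)) categories <- rep("all", nrow(res))
  pieces <- te_disjoint_pieces(tes)
  classes <- sort(unique(pieces$te_class))
  do.call(rbind, lapply(cat_levels_present(categories), function(cc) {
    sub <- re_subset(res, categories, cc)
    total <- sum(iv_width(sub))
    do.call(rbind, lapply(classes, function(cl) {
      cov <- sum(iv_covered_bases(sub, pieces[pieces$te_class == cl, , drop = FALSE]))
      data.frame(category = cc, te_class = cl, covered_bases = cov,
                 fraction_of_re_bases = if (total > 0) cov / total else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Motif presence and motif/TE overlap, per constraint tier
#'
#' An RE "has a motif" iff at least one hit overlaps it by >= 1 bp. A hit
#' "overlaps TE" iff >= 1 bp intersects a merged TE interval. A hit touching
#' several REs counts once per RE for presence, but once globally in the hit
#' tallies. Because the published figure does not state its denominator, two
#' labelled proportions are reported: `prop_te_of_in_re_hits` (denominator =
#' hits overlapping the category's REs) and `prop_te_of_all_hits`
#' (denominator = every motif hit supplied). Zero denominators yield `NA`.
#'
#' @param res,tes,categories as in [te_coverage].
#' @param motifs [genomic_intervals] of motif hits.
#' @return data.frame with one row per category plus `all`.
#' @export
motif_reports <- function(res, motifs, tes, categories = NULL) {
  if (!nrow(res)) stop("empty RE set", call. = FALSE)
  if (is.null(categories)) categories <- rep("all", nrow(res))
  te_merged <- merge_intervals(tes)
  hit_te <- overlaps_any(motifs, te_merged)
  n_hits_total <- nrow(motifs)
  do.call(rbind, lapply(cat_levels_present(categories), function(cc) {
    sub <- re_subset(res, categories, cc)
    re_has <- overlaps_any(sub, motifs)
    in_re <- overlaps_any(motifs, sub)
    n_in <- sum(in_re)
    n_in_te <- sum(in_re & hit_te)
    data.frame(category = cc,
               n_res = nrow(sub),
               n_res_with_motif = sum(re_has),
               prop_res_with_motif = if (nrow(sub)) sum(re_has) / nrow(sub) else NA_real_,
               n_hits_in_res = n_in,
               n_hits_in_res_te = n_in_te,
               prop_te_of_in_re_hits = if (n_in) n_in_te / n_in else NA_real_,
               prop_te_of_all_hits = if (n_hits_total) n_in_te / n_hits_total else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' RE x QTL overlap pairs with a length filter
#'
#' QTLs strictly longer than `max_qtl_len` are removed before intersection
#' (a literal "larger than" reading: a QTL of exactly `max_qtl_len` is kept).
#' Each overlapping (RE, QTL) pair is listed once.
#'
#' @param res [genomic_intervals] of REs.
#' @param qtls [genomic_intervals] of QTL intervals.
#' @param max_qtl_len maximum retained QTL length in bases (default 1 Mb).
#' @return data.frame `re_name`, `qtl_name`.
#' @export
qtl_overlap <- function(res, qtls, max_qtl_len = 1e6) {
  keep <- qtls[iv_width(qtls) <= max_qtl_len, , drop = FALSE]
  h <- iv_overlap_pairs(res, keep)
  out <- unique(data.frame(re_name = res$name[h$a], qtl_name = keep$name[h$b],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
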