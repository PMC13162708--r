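#' Construct a set of genomic intervals
#'
#' The package-wide coordinate container: a plain `data.frame` with class
#' `"genomic_intervals"` holding 0-based half-open intervals. Every reader in
#' the package converts its source dialect (BED, GFF3, RepeatMasker `.out`,
#' bedGraph/wig, chain) to this one convention at the boundary.
#'
#' @param seq_id character vector of sequence (chromosome/scaffold) names.
#' @param start integer-like vector, 0-based inclusive start offsets.
#' @param end integer-like vector, exclusive end offsets; `end > start`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval (recycled).
#'   `"."` means unstranded and is treated as `"+"` wherever strand matters.
#' @param name optional identifiers; `NA` allowed. Duplicate names are
#'   permitted (a message is emitted, matching upstream RE catalogues that do
#'   not guarantee uniqueness).
#' @param ... further equal-length columns kept as annotation (e.g. TE class).
#'
#' @return a `genomic_intervals` data.frame with columns `seq_id`, `start`,
#'   `end`, `strand`, `name` plus any extra columns.
#' @export
genomic_intervals <- function(seq_id, start, end, strand = ".", name = NA_character_, ...) {
  n <- max(length(seq_id), length(start), length(end))
  df <- data.frame(
    seq_id = rep_len(as.character(seq_id), n),
    start  = rep_len(as.numeric(start), n),
    end    = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    name   = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_intervals(df)
}

validate_intervals <- function(df) {
  if (nrow(df)) {
    if (anyNA(df$start) || anyNA(df$end) ||
        any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
      stop("interval coordinates must be integers", call. = FALSE)
    bad <- which(df$start < 0 | df$start >= df$end)
    if (length(bad))
      stop(sprintf("invalid interval at row %d: need 0 <= start < end (got [%s, %s))",
                   bad[1], format(df$start[bad[1]], scientific = FALSE),
                   format(df$end[bad[1]], scientific = FALSE)), call. = FALSE)
    if (!all(df$strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'", call. = FALSE)
    nm <- df$name[!is.na(df$name)]
    if (anyDuplicated(nm))
      message("genomic_intervals: duplicate interval names present (allowed)")
  }
  class(df) <- unique(c("genomic_intervals", class(df)))
  df
}

#' Interval widths (base counts)
#' @param iv a `genomic_intervals` data.frame.
#' @return integer-valued widths, `end - start`.
#' @export
iv_width <- function(iv) iv$end - iv$start

# 0-based half-open -> GRanges (1-based closed). "." strand becomes "*".
iv_as_granges <- function(iv) {
  if (!nrow(iv)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = iv$seq_id,
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end),
    strand = ifelse(iv$strand == ".", "*", iv$strand)
  )
}

granges_as_iv <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  genomic_intervals(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1,
    end    = GenomicRanges::end(gr),
    strand = ifelse(s == "*", ".", s)
  )
}

# all overlapping pairs (>= 1 bp), strand ignored
iv_overlap_pairs <- function(a, b) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(a = integer(0), b = integer(0)))
  # disjoint sequence-name sets are a legitimate no-overlap case, not a
  # user error: silence the GenomicRanges advisory
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(iv_as_granges(a), iv_as_granges(b),
                                ignore.strand = TRUE))
  data.frame(a = S4Vectors::queryHits(h), b = S4Vectors::subjectHits(h))
}

#' Merge (union) a set of intervals per sequence
#'
#' Overlapping or book-ended intervals on the same sequence are collapsed so
#' that downstream base counting is a union measure. Strand is ignored.
#'
#' @param iv a `genomic_intervals` data.frame.
#' @return a `genomic_intervals` data.frame of disjoint intervals.
#' @export
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv[, c("seq_id", "start", "end", "strand", "name")])
  granges_as_iv(GenomicRanges::reduce(iv_as_granges(iv), ignore.strand = TRUE))
}

# total bases of `iv` covered by the union of `cover`, per row of `iv`
iv_covered_bases <- function(iv, cover) {
  out <- numeric(nrow(iv))
  if (!nrow(iv) || !nrow(cover)) return(out)
  m <- merge_intervals(cover)
  h <- iv_overlap_pairs(iv, m)
  if (!nrow(h)) return(out)
  w <- pmin(iv$end[h$a], m$end[h$b]) - pmax(iv$start[h$a], m$start[h$b])
  agg <- tapply(w, h$a, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
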