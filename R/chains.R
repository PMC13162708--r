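# UCSC chain parsing and interval projection. A chain records one pairwise
# alignment as ungapped blocks separated by source (dt) and target (dq) gaps;
# projecting an interval through the chains of a genome pair yields the
# fraction of its bases present in ungapped blocks -- the pipeline's core
# per-element conservation measurement.

new_chain <- function(score, t_name, t_size, t_strand, t_start, t_end,
                      q_name, q_size, q_strand, q_start, q_end, chain_id, blocks) {
  structure(list(score = score, t_name = t_name, t_size = t_size,
                 t_strand = t_strand, t_start = t_start, t_end = t_end,
                 q_name = q_name, q_size = q_size, q_strand = q_strand,
                 q_start = q_start, q_end = q_end, chain_id = chain_id,
                 blocks = blocks),
            class = "chain_alignment")
}

#' Validate a chain's internal consistency
#'
#' Checks the UCSC chain invariants: source strand is `+`; query strand is
#' `+` or `-`; block sizes are positive; gap advances non-negative; the block
#' walk spans exactly `t_end - t_start` on the source and `q_end - q_start`
#' on the target.
#'
#' @param chain a `chain_alignment`.
#' @return the chain, invisibly; errors (naming the chain id) otherwise.
#' @export
validate_chain <- function(chain) {
  b <- chain$blocks
  fail <- function(msg)
    stop(sprintf("chain %s: %s", format(chain$chain_id), msg), call. = FALSE)
  if (chain$t_strand != "+") fail("source strand must be '+'")
  if (!(chain$q_strand %in% c("+", "-"))) fail("query strand must be '+' or '-'")
  if (!nrow(b)) fail("chain has no blocks")
  if (any(b$size < 1)) fail("block size < 1")
  if (any(b$dt < 0) || any(b$dq < 0)) fail("negative gap advance")
  n <- nrow(b)
  if (b$dt[n] != 0 || b$dq[n] != 0) fail("trailing block must have dt = dq = 0")
  t_span <- sum(b$size + b$dt)
  q_span <- sum(b$size + b$dq)
  if (t_span != chain$t_end - chain$t_start)
    fail(sprintf("block sum %s != source span %s", t_span, chain$t_end - chain$t_start))
  if (q_span != chain$q_end - chain$q_start)
    fail(sprintf("block sum %s != target span %s", q_span, chain$q_end - chain$q_start))
  if (chain$t_start < 0 || chain$t_end > chain$t_size)
    fail("source span outside [0, t_size]")
  if (chain$q_start < 0 || chain$q_end > chain$q_size)
    fail("target span outside [0, q_size]")
  invisible(chain)
}

#' Read a UCSC chain file
#'
#' Each chain is a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id`
#' followed by block lines (`size dt dq`, final line `size`). Every chain is
#' validated eagerly on load ([validate_chain]); an inconsistent chain aborts
#' the read rather than being skipped, since silently dropping alignments
#' would bias aligned fractions downward.
#'
#' @param path chain file, plain or gzip.
#' @return list of `chain_alignment` objects.
#' @export
read_chain_file <- function(path) {
  lines <- read_lines_any(path)
  chains <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    if (!grepl("^chain\\b", ln))
      stop(sprintf("%s:%d: expected chain header, got '%s'", path, i, ln), call. = FALSE)
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 13)
      stop(sprintf("%s:%d: chain header must have 13 fields", path, i), call. = FALSE)
    num <- function(k) parse_int_or_stop(f[k], path, i, "chain header field")
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    j <- i + 1
    while (j <= n && nzchar(trimws(lines[j])) && !grepl("^chain\\b", lines[j])) {
      bf <- strsplit(trimws(lines[j]), "\\s+")[[1]]
      if (!(length(bf) %in% c(1, 3)))
        stop(sprintf("%s:%d: chain block line must have 1 or 3 fields", path, j), call. = FALSE)
      sizes <- c(sizes, parse_int_or_stop(bf[1], path, j, "block size"))
      dts <- c(dts, if (length(bf) == 3) parse_int_or_stop(bf[2], path, j, "dt") else 0)
      dqs <- c(dqs, if (length(bf) == 3) parse_int_or_stop(bf[3], path, j, "dq") else 0)
      j <- j + 1
    }
    ch <- new_chain(score = as.numeric(f[2]),
                    t_name = f[3], t_size = num(4), t_strand = f[5],
                    t_start = num(6), t_end = num(7),
                    q_name = f[8], q_size = num(9), q_strand = f[10],
                    q_start = num(11), q_end = num(12),
                    chain_id = as.integer(num(13)),
                    blocks = data.frame(size = sizes, dt = dts, dq = dqs))
    validate_chain(ch)
    chains[[length(chains) + 1]] <- ch
    i <- j
  }
  chains
}

#' Write chains in UCSC chain format
#' @param chains list of `chain_alignment` objects.
#' @param path output path.
#' @export
write_chain_file <- function(chains, path) {
  out <- character(0)
  for (ch in chains) {
    hdr <- paste("chain", format(ch$score, scientific = FALSE, trim = TRUE),
                 ch$t_name, ch$t_size, ch$t_strand, ch$t_start, ch$t_end,
                 ch$q_name, ch$q_size, ch$q_strand, ch$q_start, ch$q_end,
                 ch$chain_id)
    b <- ch$blocks
    n <- nrow(b)
    body <- if (n > 1)
      c(paste(b$size[-n], b$dt[-n], b$dq[-n]), as.character(b$size[n]))
    else as.character(b$size[n])
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build a queryable index over a genome pair's chains
#'
#' Flattens every chain into absolute-coordinate ungapped blocks and indexes
#' them for overlap retrieval, so that projecting an interval touches only the
#' blocks that intersect it.
#'
#' @param chains list of `chain_alignment` (one source-genome namespace).
#' @return a `chain_index`.
#' @export
build_chain_index <- function(chains) {
  rows <- lapply(chains, function(ch) {
    b <- ch$blocks
    t0 <- ch$t_start + cumsum(c(0, (b$size + b$dt)[-nrow(b)]))
    q0 <- ch$q_start + cumsum(c(0, (b$size + b$dq)[-nrow(b)]))
    data.frame(t_name = ch$t_name, t_start = t0, t_end = t0 + b$size,
               q_name = ch$q_name, q_size = ch$q_size, q_strand = ch$q_strand,
               q_start = q0, score = ch$score, chain_id = ch$chain_id,
               stringsAsFactors = FALSE)
  })
  blocks <- if (length(rows)) do.call(rbind, rows)
  else data.frame(t_name = character(0), t_start = numeric(0), t_end = numeric(0),
                  q_name = character(0), q_size = numeric(0), q_strand = character(0),
                  q_start = numeric(0), score = numeric(0), chain_id = integer(0))
  gr <- if (nrow(blocks))
    GenomicRanges::GRanges(blocks$t_name,
                           IRanges::IRanges(blocks$t_start + 1, blocks$t_end))
  else GenomicRanges::GRanges()
  structure(list(blocks = blocks, granges = gr), class = "chain_index")
}

block_hits <- function(index, seq_id, start, end) {
  if (!nrow(index$blocks)) return(integer(0))
  q <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(start + 1, end))
  S4Vectors::subjectHits(suppressWarnings(
    GenomicRanges::findOverlaps(q, index$granges, ignore.strand = TRUE)))
}

#' Project an interval through a chain index
#'
#' A source base counts as aligned iff it lies inside an ungapped block of at
#' least one chain (`mode = "any"`, the default) or of the best-scoring
#' overlapping chain only (`mode = "best"`). When several chains cover the
#' same base, the base counts once and the mapped segment keeps the
#' highest-score chain's image, so `aligned_fraction` never exceeds 1. Query
#' coordinates on `-`-strand chains are converted to forward-strand target
#' coordinates (`q_size - pos - 1` per base).
#'
#' An interval on a sequence absent from every chain is not an error: it
#' returns `aligned_fraction = 0`.
#'
#' @param iv a one-row [genomic_intervals] (or list with `seq_id`, `start`,
#'   `end`).
#' @param index a `chain_index` from [build_chain_index].
#' @param mode `"any"` or `"best"`.
#' @return a `projection_result`: list with `source`, `segments`
#'   (target-coordinate [genomic_intervals]), `aligned_bases`,
#'   `aligned_fraction`.
#' @export
project_interval <- function(iv, index, mode = c("any", "best")) {
  mode <- match.arg(mode)
  if (is.data.frame(iv)) {
    stopifnot(nrow(iv) == 1)
    iv <- as.list(iv[1, ])
  }
  len <- iv$end - iv$start
  hits <- block_hits(index, iv$seq_id, iv$start, iv$end)
  empty <- genomic_intervals(character(0), numeric(0), numeric(0))
  if (!length(hits)) {
    return(structure(list(source = iv, segments = empty,
                          aligned_bases = 0L, aligned_fraction = 0),
                     class = "projection_result"))
  }
  b <- index$blocks[hits, , drop = FALSE]
  if (mode == "best") {
    best <- b$chain_id[which.max(b$score)]
    b <- b[b$chain_id == best, , drop = FALSE]
  }
  # disjoint source attribution: higher score claims shared bases first
  b <- b[order(-b$score, b$chain_id, b$t_start), , drop = FALSE]
  claimed <- IRanges::IRanges()
  seg_seq <- character(0); seg_start <- numeric(0); seg_end <- numeric(0)
  seg_strand <- character(0)
  for (k in seq_len(nrow(b))) {
    s <- max(iv$start, b$t_start[k]); e <- min(iv$end, b$t_end[k])
    piece <- IRanges::setdiff(IRanges::IRanges(s + 1, e), claimed)
    if (!length(piece)) next
    claimed <- IRanges::union(claimed, piece)
    ps <- IRanges::start(piece) - 1; pe <- IRanges::end(piece)
    qs <- b$q_start[k] + (ps - b$t_start[k])
    qe <- qs + (pe - ps)
    if (b$q_strand[k] == "-") {
      fs <- b$q_size[k] - qe; fe <- b$q_size[k] - qs
    } else {
      fs <- qs; fe <- qe
    }
    seg_seq <- c(seg_seq, rep(b$q_name[k], length(fs)))
    seg_start <- c(seg_start, fs); seg_end <- c(seg_end, fe)
    seg_strand <- c(seg_strand, rep(b$q_strand[k], length(fs)))
  }
  aligned <- as.integer(sum(IRanges::width(claimed)))
  segs <- if (length(seg_seq))
    genomic_intervals(seg_seq, seg_start, seg_end, strand = seg_strand)
  else empty
  structure(list(source = iv, segments = segs,
                 aligned_bases = aligned, aligned_fraction = aligned / len),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection of %s:[%s,%s): %d/%d bases aligned (%.4f)\n",
              x$source$seq_id, format(x$source$start, scientific = FALSE),
              format(x$source$end, scientific = FALSE),
              x$aligned_bases, x$source$end - x$source$start,
              x$aligned_fraction))
  invisible(x)
}

#' Build a conservation matrix (REs x genomes)
#'
#' Entry (i, g) is the aligned-base fraction of RE i under genome g's chain
#' index. Row order follows the input RE order; column order follows the order
#' of `indexes` (recorded in attribute `genome_order`). Integer aligned-base
#' counts and RE lengths are kept as attributes `aligned` and `lengths`, so
#' threshold comparisons can be reproduced exactly from integers.
#'
#' @param res [genomic_intervals] of regulatory elements.
#' @param indexes named list mapping genome name to `chain_index`.
#' @param mode passed to [project_interval].
#' @return numeric matrix with class `conservation_matrix`, values in [0,1].
#' @export
conservation_matrix <- function(res, indexes, mode = c("any", "best")) {
  mode <- match.arg(mode)
  if (!nrow(res)) stop("need at least one RE", call. = FALSE)
  if (!length(indexes)) stop("need at least one genome index", call. = FALSE)
  gnames <- names(indexes)
  if (is.null(gnames) || any(!nzchar(gnames)))
    stop("indexes must be a named list (genome names)", call. = FALSE)
  if (anyDuplicated(gnames)) stop("duplicate genome names", call. = FALSE)
  lens <- iv_width(res)
  aligned <- matrix(0, nrow(res), length(indexes),
                    dimnames = list(NULL, gnames))
  for (g in gnames) {
    idx <- indexes[[g]]
    if (!nrow(idx$blocks)) next
    if (mode == "any") {
      cover <- genomic_intervals(idx$blocks$t_name, idx$blocks$t_start,
                                 idx$blocks$t_end)
      aligned[, g] <- iv_covered_bases(res, cover)
    } else {
      aligned[, g] <- vapply(seq_len(nrow(res)), function(i)
        project_interval(res[i, ], idx, mode = "best")$aligned_bases, 0)
    }
  }
  m <- sweep(aligned, 1, lens, "/")
  rn <- res$name
  if (anyNA(rn)) rn[is.na(rn)] <- paste0("re_", which(is.na(rn)))
  rownames(m) <- make.unique(rn)
  structure(m, aligned = aligned, lengths = lens, genome_order = gnames,
            class = c("conservation_matrix", class(m)))
}

#' Write / read a conservation matrix as TSV
#'
#' RE names as row names, genome names as columns, fractions with 6 decimals.
#' @param mat matrix from [conservation_matrix].
#' @param path TSV path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(re_name = rownames(mat),
                   apply(mat, 2, function(x) sprintf("%.6f", x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  structure(m, genome_order = colnames(m),
            class = c("conservation_matrix", class(m)))
}
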