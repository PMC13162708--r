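# Readers for the plain-text formats the pipeline consumes. All of them emit
# 0-based half-open coordinates (see genomic_intervals) regardless of the
# source convention, and all accept gzip-compressed files.

read_lines_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_int_or_stop <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) || any(v != floor(v)))
    stop(sprintf("%s:%d: non-integer %s '%s'", path, lineno, what,
                 paste(x[is.na(v) | v != floor(v)], collapse = ",")),
         call. = FALSE)
  v
}

#' Read a BED3/BED6 file
#'
#' Columns 2 and 3 are interpreted as 0-based half-open (native BED
#' convention); column 4 becomes the interval name, column 6 the strand when
#' present. Extra columns beyond 6 are ignored so BED12 exports are tolerated.
#' Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path BED file, plain or gzip.
#' @return a [genomic_intervals] data.frame.
#' @export
read_bed <- function(path) {
  lines <- read_lines_any(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 1L)
  if (any(ncol < 3))
    stop(sprintf("%s:%d: BED line has fewer than 3 columns", path,
                 idx[which(ncol < 3)[1]]), call. = FALSE)
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- parse_int_or_stop(get(2), path, idx[1], "start")
  end <- parse_int_or_stop(get(3), path, idx[1], "end")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop(sprintf("%s:%d: invalid BED interval (start >= end or negative)",
                 path, idx[bad[1]]), call. = FALSE)
  strand <- get(6)
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "."
  nm <- get(4)
  genomic_intervals(get(1), start, end, strand = strand, name = nm)
}

#' Write intervals as BED
#'
#' Emits BED6 when any name/strand information is present, BED3 otherwise.
#' Extra columns named in `extra_cols` are appended after column 6.
#'
#' @param iv a [genomic_intervals] data.frame.
#' @param path output path.
#' @param extra_cols character vector of additional columns of `iv` to write.
#' @export
write_bed <- function(iv, path, extra_cols = character(0)) {
  if (!nrow(iv)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- ifelse(is.na(iv$name), ".", iv$name)
  cols <- list(iv$seq_id, format(iv$start, scientific = FALSE, trim = TRUE),
               format(iv$end, scientific = FALSE, trim = TRUE),
               nm, rep("0", nrow(iv)), iv$strand)
  for (ec in extra_cols) cols <- c(cols, list(as.character(iv[[ec]])))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

parse_gff_attrs <- function(s) {
  # key=value (GFF3) or key "value" (GTF-ish) pairs
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    p <- trimws(p)
    if (!nzchar(p)) next
    if (grepl("=", p, fixed = TRUE)) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1]]
      out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else {
      kv <- strsplit(p, " ", fixed = TRUE)[[1]]
      out[[kv[1]]] <- gsub('^"|"$', "", paste(kv[-1], collapse = " "))
    }
  }
  out
}

#' Read gene models from a GFF3 file
#'
#' Retains `gene` features whose `biotype` (or `gene_biotype`/`gene_type`)
#' attribute matches `biotype_filter`, together with their `exon` children
#' (matched through the `Parent` attribute). GFF 1-based inclusive coordinates
#' are converted to 0-based half-open; the transcription start site is the
#' first transcribed base (`start` on "+", `end - 1` on "-").
#'
#' @param path GFF3 file, plain or gzip.
#' @param biotype_filter keep only genes with this biotype
#'   (default `"protein_coding"`); `NULL` keeps all.
#' @return list of gene models; each element has `gene_id`, `interval`
#'   (one-row [genomic_intervals]), `tss`, `biotype`, `exons`.
#' @export
read_gff_genes <- function(path, biotype_filter = "protein_coding") {
  lines <- read_lines_any(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  genes <- list()
  exons_by_parent <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop(sprintf("%s:%d: GFF line has fewer than 9 columns", path, i), call. = FALSE)
    type <- f[3]
    if (!(type %in% c("gene", "exon"))) next
    start1 <- parse_int_or_stop(f[4], path, i, "start")
    end1 <- parse_int_or_stop(f[5], path, i, "end")
    strand <- f[7]
    attrs <- parse_gff_attrs(f[9])
    if (type == "gene") {
      if (!(strand %in% c("+", "-")))
        stop(sprintf("%s:%d: gene with unknown strand '%s'", path, i, strand), call. = FALSE)
      id <- attrs$ID
      if (is.null(id))
        stop(sprintf("%s:%d: gene feature lacks ID attribute", path, i), call. = FALSE)
      biotype <- attrs$biotype %||% attrs$gene_biotype %||% attrs$gene_type %||% NA_character_
      genes[[id]] <- list(
        gene_id = id,
        interval = genomic_intervals(f[1], start1 - 1, end1, strand = strand, name = id),
        tss = if (strand == "+") start1 - 1 else end1 - 1,
        biotype = biotype,
        exons = genomic_intervals(character(0), numeric(0), numeric(0))
      )
    } else {
      parent <- attrs$Parent %||% attrs$parent
      if (is.null(parent)) next
      ex <- genomic_intervals(f[1], start1 - 1, end1, strand = strand)
      exons_by_parent[[parent]] <- rbind2_iv(exons_by_parent[[parent]], ex)
    }
  }
  for (id in names(exons_by_parent)) {
    if (!is.null(genes[[id]])) {
      ex <- exons_by_parent[[id]]
      genes[[id]]$exons <- validate_intervals(ex[order(ex$start), , drop = FALSE])
    }
  }
  if (!is.null(biotype_filter))
    genes <- Filter(function(g) identical(g$biotype, biotype_filter), genes)
  unname(genes)
}

rbind2_iv <- function(a, b) {
  if (is.null(a)) return(b)
  validate_intervals(rbind(as.data.frame(a), as.data.frame(b)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a RepeatMasker `.out` annotation
#'
#' Parses the standard whitespace-separated layout (two header lines plus a
#' blank line). Query coordinates are converted from 1-based inclusive to
#' 0-based half-open; the `class/family` column is split on the first `/` into
#' a repeat class (LINE, SINE, LTR, DNA, Satellite, Simple_repeat, ...) and a
#' family, empty when absent.
#'
#' @param path RepeatMasker `.out` file, plain or gzip.
#' @return a [genomic_intervals] data.frame with `te_class`, `te_family` and
#'   `repeat_name` columns.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- read_lines_any(path)
  # drop the banner: lines starting with "SW"/"score" headers and blank lines
  body <- lines[!grepl("^\\s*(SW|score|$)", lines)]
  if (!length(body))
    return(genomic_intervals(character(0), numeric(0), numeric(0),
                             te_class = character(0), te_family = character(0),
                             repeat_name = character(0)))
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- vapply(fields, length, 1L)
  if (any(ncol < 11)) {
    lineno <- which(lines %in% body[ncol < 11])[1]
    stop(sprintf("%s:%d: truncated RepeatMasker record", path, lineno), call. = FALSE)
  }
  get <- function(i) vapply(fields, `[`, "", i)
  begin1 <- parse_int_or_stop(get(6), path, 1, "query begin")
  end1 <- parse_int_or_stop(get(7), path, 1, "query end")
  cf <- get(11)
  slash <- regexpr("/", cf, fixed = TRUE)
  te_class <- ifelse(slash > 0, substr(cf, 1, slash - 1), cf)
  te_family <- ifelse(slash > 0, substring(cf, slash + 1), "")
  strand <- ifelse(get(9) == "C", "-", "+")
  genomic_intervals(get(5), begin1 - 1, end1, strand = strand,
                    name = get(10), te_class = te_class,
                    te_family = te_family, repeat_name = get(10))
}

#' Read a per-base score track (bedGraph or fixed-step wig)
#'
#' @param path bedGraph (4 whitespace-separated columns, 0-based half-open) or
#'   fixed-step wiggle file, plain or gzip. Overlapping records are rejected:
#'   a base must have at most one score.
#' @return a `score_track`: a [genomic_intervals] data.frame with a `score`
#'   column, sorted and non-overlapping within each sequence.
#' @export
read_score_track <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track\\b)", lines)]
  seqs <- character(0); starts <- numeric(0); ends <- numeric(0); scores <- numeric(0)
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^fixedStep", ln)) {
      kv <- parse_wig_header(ln)
      j <- i + 1
      vals <- numeric(0)
      while (j <= length(lines) && !grepl("^(fixedStep|variableStep)", lines[j]) &&
             grepl("^\\s*-?[0-9.eE+-]+\\s*$", lines[j])) {
        vals <- c(vals, as.numeric(lines[j])); j <- j + 1
      }
      if (length(vals)) {
        pos0 <- kv$start - 1 + kv$step * (seq_along(vals) - 1)
        seqs <- c(seqs, rep(kv$chrom, length(vals)))
        starts <- c(starts, pos0)
        ends <- c(ends, pos0 + kv$span)
        scores <- c(scores, vals)
      }
      i <- j
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 4)
        stop(sprintf("%s:%d: bedGraph line needs 4 columns", path, i), call. = FALSE)
      seqs <- c(seqs, f[1])
      starts <- c(starts, as.numeric(f[2]))
      ends <- c(ends, as.numeric(f[3]))
      scores <- c(scores, as.numeric(f[4]))
      i <- i + 1
    }
  }
  tr <- genomic_intervals(seqs, starts, ends, score = scores)
  tr <- tr[order(tr$seq_id, tr$start), , drop = FALSE]
  ov <- with(tr, seq_id[-1] == seq_id[-nrow(tr)] & start[-1] < end[-nrow(tr)])
  if (nrow(tr) > 1 && any(ov))
    stop("score track has overlapping records (ambiguous per-base value)", call. = FALSE)
  rownames(tr) <- NULL
  class(tr) <- unique(c("score_track", class(tr)))
  tr
}

parse_wig_header <- function(ln) {
  kvs <- strsplit(trimws(ln), "\\s+")[[1]][-1]
  out <- list(step = 1, span = NULL, start = NA, chrom = NA)
  for (kv in kvs) {
    p <- strsplit(kv, "=", fixed = TRUE)[[1]]
    out[[p[1]]] <- p[2]
  }
  list(chrom = out$chrom,
       start = as.numeric(out$start),
       step = as.numeric(out$step),
       span = as.numeric(out$span %||% out$step))
}

#' Read a divergence-time table
#'
#' A TSV with header `taxon<TAB>divergence_mya<TAB>clade` mapping each target
#' genome to its divergence time from the reference (million years ago) and a
#' clade label (e.g. `clade` / `outgroup` / `conspecific`).
#'
#' @param path TSV file, plain or gzip.
#' @return data.frame with columns `taxon`, `divergence_mya`, `clade`.
#' @export
read_divergence_table <- function(path) {
  lines <- read_lines_any(path)
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("taxon", "divergence_mya", "clade")
  if (!all(need %in% names(df)))
    stop("divergence table must have columns taxon, divergence_mya, clade", call. = FALSE)
  if (anyDuplicated(df$taxon)) stop("duplicate taxon names in divergence table", call. = FALSE)
  if (anyNA(df$divergence_mya) || any(!is.finite(df$divergence_mya)) ||
      any(df$divergence_mya < 0))
    stop("divergence_mya must be finite and >= 0", call. = FALSE)
  df[need]
}
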