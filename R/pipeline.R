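# End-to-end orchestration: read inputs, project, classify, annotate,
# overlap, regress, ordinate; write TSV outputs plus a machine-readable run
# manifest. Every stage logs record counts in/out, since the pipeline's
# headline outputs are record counts and count logging makes each filter
# auditable. Any stage failure aborts with the stage name.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

log_stage <- function(...) message(sprintf(...))

#' Run the full constraint pipeline on files
#'
#' Reads REs (BED; an optional 5th column is interpreted as truth tier
#' labels from the simulator), one chain file per target genome from
#' `chains_dir` (`<taxon>.chain`, plain or gzip), and optional gene / TE /
#' motif / QTL / score / divergence tracks; computes the conservation
#' matrix, N1/N2 classification and summary, context annotation, overlap
#' statistics, divergence regressions and PCA; writes everything under
#' `out_dir` and returns the report as a list. The genome grouping defaults
#' to the `clade` column of the divergence table (`clade` vs `outgroup`
#' members; `conspecific` panels instead trigger the intraspecific summary).
#'
#' @param re_path BED of REs.
#' @param chains_dir directory of `<taxon>.chain` files.
#' @param out_dir output directory.
#' @param divergence_path TSV (`taxon`, `divergence_mya`, `clade`).
#' @param genes_path,te_path,motifs_path,qtl_path,scores_path optional
#'   tracks (GFF3 / BED with class column 4 / BED / BED / bedGraph).
#' @param grouping optional [genome_grouping]; derived from the divergence
#'   table when `NULL`.
#' @param hi,lo,window,max_qtl_len,k thresholds (see the module functions).
#' @param mode chain coverage rule, `"any"` or `"best"`.
#' @return invisible list with all computed tables.
#' @export
run_pipeline <- function(re_path, chains_dir, out_dir,
                         divergence_path = NULL, genes_path = NULL,
                         te_path = NULL, motifs_path = NULL, qtl_path = NULL,
                         scores_path = NULL, grouping = NULL,
                         hi = 0.9, lo = 0.1, window = 2000,
                         max_qtl_len = 1e6, k = NULL, mode = "any") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()

  res <- stage("read_res", read_bed(re_path))
  truth <- stage("read_res", tryCatch(read_truth_labels(re_path),
                                      error = function(e) NULL))
  if (!is.null(truth) && (anyNA(truth) || !all(truth %in% re_categories())))
    truth <- NULL
  log_stage("read_res: %d REs", nrow(res))

  if (!dir.exists(chains_dir))
    stop("[projection] chain directory not found: ", chains_dir, call. = FALSE)
  chain_files <- list.files(chains_dir, pattern = "\\.chain(\\.gz)?$",
                            full.names = TRUE)
  if (!length(chain_files))
    stop("[projection] no .chain files in ", chains_dir, call. = FALSE)
  indexes <- stage("projection", {
    idx <- lapply(chain_files, function(f) build_chain_index(read_chain_file(f)))
    names(idx) <- sub("\\.chain(\\.gz)?$", "", basename(chain_files))
    idx
  })
  mat <- stage("projection", conservation_matrix(res, indexes, mode = mode))
  write_matrix_tsv(mat, file.path(out_dir, "matrix.tsv"))
  log_stage("projection: %d REs x %d genomes", nrow(mat), ncol(mat))

  div <- if (!is.null(divergence_path))
    stage("divergence", read_divergence_table(divergence_path)) else NULL

  interspecific <- is.null(div) || any(div$clade != "conspecific")
  classes <- NULL
  if (interspecific) {
    if (is.null(grouping)) {
      if (is.null(div))
        stop("[classify] need a grouping or a divergence table", call. = FALSE)
      grouping <- genome_grouping(div$taxon[div$clade == "clade"],
                                  div$taxon[div$clade != "clade"])
    }
    classes <- stage("classify", classify_matrix(mat, grouping, hi = hi, lo = lo))
    utils::write.table(classes, file.path(out_dir, "classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$summary <- summarize_classification(classes)
    utils::write.table(report$summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("classify: %s",
              paste(report$summary$category, report$summary$count,
                    collapse = ", "))
    if (!is.null(truth)) {
      report$recovery <- evaluate_recovery(
        truth, stats::setNames(as.character(classes$category), classes$re_name))
      log_stage("classify: truth-recovery accuracy %.4f", report$recovery$accuracy)
    }
  } else {
    kk <- if (is.null(k)) max(1, ncol(mat) - 4) else k
    report$intraspecific <- stage("intraspecific",
                                  intraspecific_summary(mat, hi = hi, k = kk))
    log_stage("intraspecific: %d/%d REs high in all genomes",
              report$intraspecific$count_all, nrow(mat))
  }
  cats <- if (!is.null(classes)) as.character(classes$category) else NULL

  if (!is.null(genes_path)) {
    genes <- stage("annotate", read_gff_genes(genes_path))
    annot <- data.frame(re_name = res$name,
                        three_way = classify_location(res, genes, window),
                        four_way = classify_feature(res, genes, window),
                        stringsAsFactors = FALSE)
    ng <- nearest_gene(res, genes)
    annot$nearest_gene <- ng$gene_id
    annot$distance <- ng$distance
    if (!is.null(scores_path)) {
      track <- stage("annotate", read_score_track(scores_path))
      sc <- aggregate_scores(res, track, categories = cats)
      annot$mean_score <- sc$per_re$mean_score
      report$score_by_category <- sc$per_category
    }
    utils::write.table(annot, file.path(out_dir, "annot.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$annot <- annot
    log_stage("annotate: %d REs against %d genes", nrow(res), length(genes))
  }

  if (!is.null(te_path)) {
    tes <- stage("overlaps", {
      te <- read_bed(te_path)
      te$te_class <- te$name  # simulator convention: column 4 = class
      te
    })
    report$te_coverage <- te_coverage(res, tes, cats)
    report$te_classes <- te_class_composition(res, tes, cats)
    utils::write.table(report$te_coverage, file.path(out_dir, "coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$te_classes, file.path(out_dir, "te_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(motifs_path)) {
      motifs <- stage("overlaps", read_bed(motifs_path))
      report$motifs <- motif_reports(res, motifs, tes, cats)
      utils::write.table(report$motifs, file.path(out_dir, "motif_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(qtl_path)) {
    qtls <- stage("overlaps", read_bed(qtl_path))
    report$qtl_pairs <- qtl_overlap(res, qtls, max_qtl_len)
    utils::write.table(report$qtl_pairs, file.path(out_dir, "qtl_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("overlaps: %d RE-QTL pairs", nrow(report$qtl_pairs))
  }

  if (!is.null(div)) {
    ord <- match(colnames(mat), div$taxon)
    if (!anyNA(ord)) {
      x <- div$divergence_mya[ord]
      if (length(unique(x)) > 2) {
        report$trend_high <- stage("trends",
          fit_regression(x, count_by_genome(mat, "high", hi = hi)))
        report$trend_low <- stage("trends",
          fit_regression(x, count_by_genome(mat, "low", lo = lo)))
        tr <- data.frame(mode = c("high", "low"),
                         slope = c(report$trend_high$slope, report$trend_low$slope),
                         r_squared = c(report$trend_high$r_squared,
                                       report$trend_low$r_squared),
                         p_value = c(report$trend_high$p_value,
                                     report$trend_low$p_value))
        utils::write.table(tr, file.path(out_dir, "trends.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if (ncol(mat) >= 2 && nrow(mat) >= 2) {
    pca <- stage("pca", run_pca(mat, n_components = 2))
    utils::write.table(
      data.frame(re_name = rownames(pca$scores), pca$scores),
      file.path(out_dir, "pca.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    report$pca <- pca
  }

  inputs <- c(re_path, divergence_path, genes_path, te_path, motifs_path,
              qtl_path, scores_path, chain_files)
  manifest <- list(
    tool = "relic", version = as.character(utils::packageVersion("relic")),
    parameters = list(hi = hi, lo = lo, window = window,
                      max_qtl_len = max_qtl_len, mode = mode),
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report$manifest <- manifest
  invisible(report)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (!grepl("^--", args[i]))
      stop("unexpected argument: ", args[i], call. = FALSE)
    key <- sub("^--", "", args[i])
    if (i == length(args) || grepl("^--", args[i + 1]))
      stop("missing value for --", key, call. = FALSE)
    out[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Command-line entry point
#'
#' Subcommands: `simulate`, `project`, `classify`, `summarize`, `annotate`,
#' `overlaps`, `trends`, `pca`, `run`. See `inst/cli/relic` for the
#' executable wrapper. Returns (and, from the wrapper, exits with) 0 on
#' success.
#'
#' @param args character vector, `commandArgs(trailingOnly = TRUE)` style.
#' @return exit status, invisibly.
#' @export
relic_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: relic <simulate|project|classify|summarize|annotate|overlaps|trends|pca|run> [--opt value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  o <- parse_cli_args(args[-1])
  status <- 0L
  switch(cmd,
    simulate = {
      cfg <- simulation_config(seed = num_or(o$seed, 1),
                               noise = num_or(o$noise, 0))
      write_dataset(simulate_dataset(cfg), o$out)
    },
    project = {
      res <- read_bed(o$re)
      files <- list.files(o$chains, pattern = "\\.chain(\\.gz)?$", full.names = TRUE)
      idx <- lapply(files, function(f) build_chain_index(read_chain_file(f)))
      names(idx) <- sub("\\.chain(\\.gz)?$", "", basename(files))
      if (!is.null(o$genomes)) {
        order <- readLines(o$genomes)
        idx <- idx[order]
      }
      write_matrix_tsv(conservation_matrix(res, idx, mode = o$mode %||% "any"), o$out)
    },
    classify = {
      mat <- read_matrix_tsv(o$matrix)
      g <- jsonlite::read_json(o$groups, simplifyVector = TRUE)
      cls <- classify_matrix(mat, genome_grouping(g$clade_members, g$outgroup_members),
                             hi = num_or(o$hi, 0.9), lo = num_or(o$lo, 0.1))
      utils::write.table(cls, o$out, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    summarize = {
      cls <- utils::read.table(o$classes, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      print(summarize_classification(cls$category))
    },
    annotate = {
      res <- read_bed(o$re)
      genes <- read_gff_genes(o$genes)
      annot <- data.frame(re_name = res$name,
                          three_way = classify_location(res, genes, num_or(o$window, 2000)),
                          four_way = classify_feature(res, genes, num_or(o$window, 2000)))
      ng <- nearest_gene(res, genes)
      annot$nearest_gene <- ng$gene_id; annot$distance <- ng$distance
      if (!is.null(o$scores))
        annot$mean_score <-
          aggregate_scores(res, read_score_track(o$scores))$per_re$mean_score
      utils::write.table(annot, o$out, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    overlaps = {
      res <- read_bed(o$re)
      cats <- NULL
      if (!is.null(o$classes)) {
        cls <- utils::read.table(o$classes, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        cats <- cls$category[match(res$name, cls$re_name)]
      }
      dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
      if (!is.null(o$te)) {
        tes <- read_bed(o$te); tes$te_class <- tes$name
        utils::write.table(te_coverage(res, tes, cats),
                           file.path(o$out, "coverage.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(o$motifs))
          utils::write.table(motif_reports(res, read_bed(o$motifs), tes, cats),
                             file.path(o$out, "motif_report.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(o$qtl))
        utils::write.table(qtl_overlap(res, read_bed(o$qtl),
                                       num_or(o$max_qtl_len, 1e6)),
                           file.path(o$out, "qtl_pairs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    },
    trends = {
      mat <- read_matrix_tsv(o$matrix)
      div <- read_divergence_table(o$divergence)
      x <- div$divergence_mya[match(colnames(mat), div$taxon)]
      hi_fit <- fit_regression(x, count_by_genome(mat, "high"))
      lo_fit <- fit_regression(x, count_by_genome(mat, "low"))
      utils::write.table(
        data.frame(mode = c("high", "low"),
                   slope = c(hi_fit$slope, lo_fit$slope),
                   intercept = c(hi_fit$intercept, lo_fit$intercept),
                   r_squared = c(hi_fit$r_squared, lo_fit$r_squared),
                   p_value = c(hi_fit$p_value, lo_fit$p_value)),
        o$out, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    pca = {
      mat <- read_matrix_tsv(o$matrix)
      p <- run_pca(mat, n_components = num_or(o$components, 2))
      utils::write.table(data.frame(re_name = rownames(p$scores), p$scores),
                         o$out, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    run = {
      run_pipeline(re_path = o$re, chains_dir = o$chains, out_dir = o$out,
                   divergence_path = o$divergence, genes_path = o$genes,
                   te_path = o$te, motifs_path = o$motifs, qtl_path = o$qtl,
                   scores_path = o$scores,
                   hi = num_or(o$hi, 0.9), lo = num_or(o$lo, 0.1),
                   window = num_or(o$window, 2000),
                   max_qtl_len = num_or(o$max_qtl_len, 1e6))
    },
    {
      message("unknown subcommand: ", cmd)
      status <- 1L
    }
  )
  invisible(status)
}
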