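# Coordinate-level genome-evolution simulator. No nucleotide sequences are
# generated: the contract of the pipeline is coordinates plus chains, so the
# simulator emits exactly those. For each taxon the reference genome is tiled
# into retained segments and gaps (geometric run lengths, so chains have
# realistic block structure rather than i.i.d. per-base survival); each
# neutral base is retained with probability exp(-lambda * divergence_mya),
# while RE loci override the neutral process according to their truth tier.

#' Default taxon panels for simulation
#'
#' `"interspecific"`: 4 clade taxa at small divergence times plus 8 outgroup
#' taxa spanning roughly the peccary-to-human range of a mammalian panel.
#' `"intraspecific"`: `n` conspecific genomes at sub-MYA divergences.
#'
#' @param mode panel kind.
#' @param n number of conspecific genomes (intraspecific mode only).
#' @return data.frame `taxon`, `divergence_mya`, `clade`.
#' @export
default_taxa <- function(mode = c("interspecific", "intraspecific"), n = 34) {
  mode <- match.arg(mode)
  if (mode == "interspecific") {
    data.frame(
      taxon = c(paste0("suid_", LETTERS[1:4]), paste0("outgroup_", LETTERS[1:8])),
      divergence_mya = c(2, 4, 8, 12, 30, 40, 50, 60, 70, 80, 88, 96),
      clade = c(rep("clade", 4), rep("outgroup", 8)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      taxon = sprintf("pig_%02d", seq_len(n)),
      divergence_mya = round(seq(0.02, 1, length.out = n), 4),
      clade = "conspecific",
      stringsAsFactors = FALSE
    )
  }
}

#' Simulation configuration
#'
#' Defaults describe the stated desk-scale world: a 2 Mb two-sequence
#' reference, 12 taxa (4 clade + 8 outgroup), 500 REs split
#' 150/150/100/100 across the four truth tiers, per-base per-MYA deletion
#' rate `lambda = 0.01` (neutral retention ~98% at 2 MYA down to ~38% at 96
#' MYA, matching the roughly 40% pig-to-human genome alignability at the far
#' end of a mammalian panel), 5 kb mean segment geometry (chain gaps in real
#' pairwise alignments are dominated by kilobase-scale indels, so elements
#' shorter than a segment are retained or lost nearly whole -- the bimodal
#' fraction distribution the tier thresholds assume), genome-wide TE density
#' 0.30 with a
#' 1.55x enrichment inside reference-species-specific REs (mirroring the
#' observed contrast between overall and lineage-specific TE coverage), and
#' no truth-label noise.
#'
#' @param seed integer; fixes every output.
#' @param genome_length total reference length in bases.
#' @param n_sequences number of reference sequences.
#' @param taxa data.frame `taxon`, `divergence_mya`, `clade`
#'   (`clade`/`outgroup`/`conspecific`).
#' @param n_res named integer vector of RE counts per truth tier (names from
#'   [re_categories()]).
#' @param re_length length range (min, max) of REs in bases.
#' @param deletion_rate lambda, per-base per-MYA deletion probability
#'   parameter.
#' @param mean_segment mean retained-segment + gap cycle length in bases.
#' @param te_density genome-wide TE base fraction.
#' @param te_enrichment_specific TE density multiplier inside
#'   reference-species-specific REs.
#' @param te_length TE length range.
#' @param n_genes,n_motifs,n_qtls track sizes.
#' @param qtl_length QTL length range.
#' @param noise probability of flipping each truth-forced base (models
#'   alignment imperfection; 0 = noise-free).
#' @param force_truth when `FALSE`, REs evolve neutrally (no tier forcing);
#'   used to study pure exponential decay.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              genome_length = 2e6,
                              n_sequences = 2,
                              taxa = default_taxa("interspecific"),
                              n_res = c(cross_species_constrained = 150,
                                        clade_specific = 150,
                                        reference_species_specific = 100,
                                        unclassified = 100),
                              re_length = c(200, 1000),
                              deletion_rate = 0.01,
                              mean_segment = 5000,
                              te_density = 0.30,
                              te_enrichment_specific = 1.55,
                              te_length = c(100, 1000),
                              n_genes = 40,
                              n_motifs = 400,
                              n_qtls = 20,
                              qtl_length = c(1e4, 2e5),
                              noise = 0,
                              force_truth = TRUE) {
  cfg <- list(seed = seed, genome_length = genome_length,
              n_sequences = n_sequences, taxa = taxa, n_res = n_res,
              re_length = re_length, deletion_rate = deletion_rate,
              mean_segment = mean_segment, te_density = te_density,
              te_enrichment_specific = te_enrichment_specific,
              te_length = te_length, n_genes = n_genes, n_motifs = n_motifs,
              n_qtls = n_qtls, qtl_length = qtl_length, noise = noise,
              force_truth = force_truth)
  stopifnot(is.numeric(seed), length(seed) == 1,
            noise >= 0, noise <= 1, deletion_rate >= 0,
            all(taxa$divergence_mya >= 0),
            all(names(n_res) %in% re_categories()))
  if (anyDuplicated(taxa$taxon)) stop("duplicate taxon names", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# geometric-run retention mask of length L with per-base retention prob p
sim_mask <- function(L, p, mean_segment) {
  if (p >= 0.999) return(rep(TRUE, L))
  if (p <= 0.001) return(rep(FALSE, L))
  r <- max(1, p * mean_segment)
  g <- max(1, (1 - p) * mean_segment)
  lens <- numeric(0); vals <- logical(0)
  first_ret <- stats::runif(1) < p
  while (sum(lens) < L) {
    npair <- ceiling((L - sum(lens)) / (r + g)) + 10
    ret <- 1 + stats::rgeom(npair, 1 / r)
    gap <- 1 + stats::rgeom(npair, 1 / g)
    if (first_ret && !length(lens)) {
      lens <- as.vector(rbind(ret, gap))
      vals <- rep(c(TRUE, FALSE), npair)
    } else {
      # continue (or start) with a gap run so values stay in register
      lens <- c(lens, as.vector(rbind(gap, ret)))
      vals <- c(vals, rep(c(FALSE, TRUE), npair))
    }
  }
  inverse.rle(structure(list(lengths = lens, values = vals),
                        class = "rle"))[seq_len(L)]
}

# non-overlapping placement via slotting; errors when infeasible
place_in_slots <- function(n, lens_range, seq_names, seq_len, slot_pad = 200) {
  slot_size <- lens_range[2] + slot_pad
  per_seq <- floor(seq_len / slot_size)
  total <- per_seq * length(seq_names)
  if (n > total)
    stop(sprintf("infeasible placement: %d elements but only %d slots", n, total),
         call. = FALSE)
  slots <- sample.int(total, n)
  seq_i <- (slots - 1) %/% per_seq + 1
  slot_i <- (slots - 1) %% per_seq
  lens <- sample(seq(lens_range[1], lens_range[2]), n, replace = TRUE)
  offset <- floor(stats::runif(n) * (slot_size - lens))
  data.frame(seq_id = seq_names[seq_i],
             start = slot_i * slot_size + offset,
             len = lens, stringsAsFactors = FALSE)
}

#' Simulate a full synthetic dataset
#'
#' Generates truth-labelled REs, one chain set per taxon (alignment loss
#' grows with divergence time), gene models, TE/motif/QTL tracks, a
#' phyloP-like score track over the REs, and the divergence table. Truth
#' labels are realised on the chains: a `cross_species_constrained` RE is
#' forced retained in every taxon, a `reference_species_specific` RE forced
#' deleted in every non-conspecific taxon, a `clade_specific` RE retained in
#' clade/conspecific taxa and deleted in outgroups, and an `unclassified` RE
#' retained over its first half and deleted over its second half everywhere
#' (aligned fraction ~0.5, failing every strict rule). `noise` flips forced
#' bases independently. The RNG is seeded from `config$seed` with fixed
#' per-taxon offsets, so outputs are reproducible and independent of
#' iteration order; the caller's RNG state is restored on exit.
#'
#' @param config a [simulation_config].
#' @return a `synthetic_dataset` list: `res` (with `truth` column), `chains`
#'   (named list taxon -> list of `chain_alignment`), `genes`, `tes`,
#'   `motifs`, `qtls`, `score_track`, `divergence`, `config`, `manifest`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  L <- floor(config$genome_length / config$n_sequences)
  seqs <- paste0("chr", seq_len(config$n_sequences))

  ## layout: REs, genes, tracks ------------------------------------------
  set.seed(config$seed)
  n_total <- sum(config$n_res)
  pl <- place_in_slots(n_total, config$re_length, seqs, L)
  truth <- sample(rep(names(config$n_res), config$n_res))
  res <- genomic_intervals(pl$seq_id, pl$start, pl$start + pl$len,
                           name = sprintf("re_%04d", seq_len(n_total)),
                           truth = truth)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL

  genes <- sim_genes(config, seqs, L)
  tes <- sim_tes(config, res, seqs, L)
  motifs <- sim_motifs(config, res, seqs, L)
  qtls <- sim_qtls(config, seqs, L)
  track <- sim_score_track(res)

  ## per-taxon retention masks and chains --------------------------------
  chains <- list()
  for (k in seq_len(nrow(config$taxa))) {
    taxon <- config$taxa$taxon[k]
    t_mya <- config$taxa$divergence_mya[k]
    clade <- config$taxa$clade[k]
    set.seed(config$seed + 1009 * k)
    p <- exp(-config$deletion_rate * t_mya)
    taxon_chains <- list()
    retained_total <- 0
    for (si in seq_along(seqs)) {
      mask <- sim_mask(L, p, config$mean_segment)
      if (config$force_truth) {
        on_seq <- which(res$seq_id == seqs[si])
        for (i in on_seq) {
          rng <- (res$start[i] + 1):res$end[i]
          forced <- switch(res$truth[i],
            cross_species_constrained = rep(TRUE, length(rng)),
            clade_specific = rep(clade %in% c("clade", "conspecific"), length(rng)),
            reference_species_specific = rep(clade == "conspecific", length(rng)),
            unclassified = seq_along(rng) <= length(rng) / 2)
          if (config$noise > 0)
            forced <- xor(forced, stats::runif(length(rng)) < config$noise)
          mask[rng] <- forced
        }
      }
      ch <- mask_to_chain(mask, seqs[si], L, paste0(taxon, "_", seqs[si]),
                          chain_id = si)
      if (!is.null(ch)) taxon_chains[[length(taxon_chains) + 1]] <- ch
    }
    for (ch in taxon_chains) validate_chain(ch)
    chains[[taxon]] <- taxon_chains
  }

  manifest <- list(seed = config$seed, genome_length = config$genome_length,
                   n_sequences = config$n_sequences,
                   n_res = as.list(config$n_res),
                   n_taxa = nrow(config$taxa), noise = config$noise,
                   force_truth = config$force_truth)
  structure(list(res = res, chains = chains, genes = genes, tes = tes,
                 motifs = motifs, qtls = qtls, score_track = track,
                 divergence = config$taxa, config = config,
                 manifest = manifest),
            class = "synthetic_dataset")
}

mask_to_chain <- function(mask, seq_name, seq_len, q_name, chain_id) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  ret <- which(r$values)
  if (!length(ret)) return(NULL)
  sizes <- r$lengths[ret]
  # dt = gap to the next retained run (0 after the last)
  n <- length(ret)
  dt <- if (n > 1) starts[ret[-1]] - ends[ret[-n]] else numeric(0)
  dt <- c(dt, 0)
  total <- sum(sizes)
  new_chain(score = 1000,
            t_name = seq_name, t_size = seq_len, t_strand = "+",
            t_start = starts[ret[1]], t_end = ends[ret[n]],
            q_name = q_name, q_size = total, q_strand = "+",
            q_start = 0, q_end = total, chain_id = chain_id,
            blocks = data.frame(size = sizes, dt = dt, dq = 0))
}

sim_genes <- function(config, seqs, L) {
  if (!config$n_genes) return(list())
  set.seed(config$seed + 5)
  pl <- place_in_slots(config$n_genes, c(2000, 9000), seqs, L, slot_pad = 1000)
  lapply(seq_len(config$n_genes), function(i) {
    strand <- sample(c("+", "-"), 1)
    start <- pl$start[i]; end <- start + pl$len[i]
    # a small minority of non-coding genes exercises the biotype filter
    biotype <- if (stats::runif(1) < 0.1) "lncRNA" else "protein_coding"
    n_ex <- sample(2:4, 1)
    cuts <- sort(sample(seq(start + 100, end - 100, by = 50), 2 * n_ex))
    exons <- genomic_intervals(rep(pl$seq_id[i], n_ex),
                               cuts[seq(1, 2 * n_ex, 2)],
                               cuts[seq(2, 2 * n_ex, 2)], strand = strand)
    id <- sprintf("gene_%03d", i)
    list(gene_id = id,
         interval = genomic_intervals(pl$seq_id[i], start, end,
                                      strand = strand, name = id),
         tss = if (strand == "+") start else end - 1,
         biotype = biotype, exons = exons)
  })
}

sim_tes <- function(config, res, seqs, L) {
  set.seed(config$seed + 7)
  classes <- c("LINE", "SINE", "LTR", "DNA", "Satellite", "Simple_repeat")
  wts <- c(0.35, 0.25, 0.2, 0.1, 0.05, 0.05)
  mean_len <- mean(config$te_length)
  n_bg <- round(config$genome_length * config$te_density / mean_len)
  lens <- sample(seq(config$te_length[1], config$te_length[2]), n_bg, replace = TRUE)
  seq_i <- sample(seq_along(seqs), n_bg, replace = TRUE)
  starts <- floor(stats::runif(n_bg) * (L - lens))
  te <- data.frame(seq_id = seqs[seq_i], start = starts, end = starts + lens,
                   te_class = sample(classes, n_bg, replace = TRUE, prob = wts),
                   stringsAsFactors = FALSE)
  # extra TEs inside reference-species-specific REs to realise the enrichment
  extra_frac <- config$te_density * (config$te_enrichment_specific - 1)
  if (extra_frac > 0) {
    spec <- res[res$truth == "reference_species_specific", , drop = FALSE]
    for (i in seq_len(nrow(spec))) {
      need <- extra_frac * (spec$end[i] - spec$start[i])
      while (need > 0) {
        l <- min(sample(100:300, 1), spec$end[i] - spec$start[i])
        s <- spec$start[i] + floor(stats::runif(1) * (spec$end[i] - spec$start[i] - l + 1))
        te <- rbind(te, data.frame(seq_id = spec$seq_id[i], start = s, end = s + l,
                                   te_class = sample(classes, 1, prob = wts),
                                   stringsAsFactors = FALSE))
        need <- need - l
      }
    }
  }
  te <- te[order(te$seq_id, te$start), , drop = FALSE]
  genomic_intervals(te$seq_id, te$start, te$end,
                    name = sprintf("te_%05d", seq_len(nrow(te))),
                    te_class = te$te_class)
}

sim_motifs <- function(config, res, seqs, L) {
  set.seed(config$seed + 11)
  n <- config$n_motifs
  n_in <- round(0.6 * n)
  lens <- sample(8:15, n, replace = TRUE)
  pick <- sample.int(nrow(res), n_in, replace = TRUE)
  s_in <- res$start[pick] +
    floor(stats::runif(n_in) * (iv_width(res)[pick] - lens[seq_len(n_in)]))
  seq_in <- res$seq_id[pick]
  n_bg <- n - n_in
  seq_bg <- seqs[sample(seq_along(seqs), n_bg, replace = TRUE)]
  s_bg <- floor(stats::runif(n_bg) * (L - lens[n_in + seq_len(n_bg)]))
  genomic_intervals(c(seq_in, seq_bg), c(s_in, s_bg),
                    c(s_in, s_bg) + lens,
                    name = sprintf("motif_%04d", seq_len(n)))
}

sim_qtls <- function(config, seqs, L) {
  set.seed(config$seed + 13)
  n <- config$n_qtls
  lens <- floor(stats::runif(n, config$qtl_length[1],
                             min(config$qtl_length[2], L - 1)))
  seq_i <- sample(seq_along(seqs), n, replace = TRUE)
  starts <- floor(stats::runif(n) * (L - lens))
  genomic_intervals(seqs[seq_i], starts, starts + lens,
                    name = sprintf("qtl_%03d", seq_len(n)))
}

# phyloP-like per-RE scores: constrained tiers score high, lineage-specific
# low, with mild noise -- enough structure to exercise score aggregation
sim_score_track <- function(res) {
  base <- c(cross_species_constrained = 1.5, clade_specific = 0.5,
            reference_species_specific = -0.5, unclassified = 0)
  score <- base[res$truth] + stats::rnorm(nrow(res), 0, 0.1)
  tr <- genomic_intervals(res$seq_id, res$start, res$end, score = unname(score))
  class(tr) <- unique(c("score_track", class(tr)))
  tr
}

#' Write a synthetic dataset to disk
#'
#' Emits `chains/<taxon>.chain`, `res.bed` (column 5 carries the truth
#' tier), `genes.gff3`, `te.bed` (column 4 = TE class), `motifs.bed`,
#' `qtl.bed`, `scores.bedgraph`, `divergence.tsv` and `manifest.json`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(file.path(dir, "chains"), recursive = TRUE, showWarnings = FALSE)
  for (taxon in names(ds$chains))
    write_chain_file(ds$chains[[taxon]], file.path(dir, "chains", paste0(taxon, ".chain")))
  writeLines(paste(ds$res$seq_id, ds$res$start, ds$res$end, ds$res$name,
                   ds$res$truth, sep = "\t"),
             file.path(dir, "res.bed"))
  write_gff_genes(ds$genes, file.path(dir, "genes.gff3"))
  writeLines(paste(ds$tes$seq_id, ds$tes$start, ds$tes$end, ds$tes$te_class,
                   sep = "\t"),
             file.path(dir, "te.bed"))
  write_bed(ds$motifs, file.path(dir, "motifs.bed"))
  write_bed(ds$qtls, file.path(dir, "qtl.bed"))
  writeLines(c(paste(ds$score_track$seq_id, ds$score_track$start,
                     ds$score_track$end,
                     sprintf("%.4f", ds$score_track$score), sep = "\t")),
             file.path(dir, "scores.bedgraph"))
  utils::write.table(ds$divergence, file.path(dir, "divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write gene models as GFF3
#' @param genes list of gene models (as returned by [read_gff_genes]).
#' @param path output path.
#' @export
write_gff_genes <- function(genes, path) {
  out <- "##gff-version 3"
  for (g in genes) {
    iv <- g$interval
    out <- c(out, paste(iv$seq_id, "relic_sim", "gene", iv$start + 1, iv$end,
                        ".", iv$strand, ".",
                        sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype),
                        sep = "\t"))
    ex <- g$exons
    for (i in seq_len(nrow(ex)))
      out <- c(out, paste(ex$seq_id[i], "relic_sim", "exon", ex$start[i] + 1,
                          ex$end[i], ".", ex$strand[i], ".",
                          sprintf("Parent=%s", g$gene_id), sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read truth tier labels from a simulated `res.bed`
#' @param path BED written by [write_dataset] (column 5 = truth tier).
#' @return named character vector, RE name -> truth category.
#' @export
read_truth_labels <- function(path) {
  lines <- read_lines_any(path)
  f <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  stats::setNames(vapply(f, `[`, "", 5), vapply(f, `[`, "", 4))
}

#' Confusion matrix and accuracy of truth recovery
#'
#' @param truth,predicted named character vectors with identical key sets
#'   mapping RE name to category.
#' @return list `confusion` (4x4 table, truth rows x predicted columns),
#'   `accuracy` (trace / total).
#' @export
evaluate_recovery <- function(truth, predicted) {
  if (!setequal(names(truth), names(predicted)) ||
      length(truth) != length(predicted))
    stop("truth and predicted must share one key set", call. = FALSE)
  predicted <- predicted[names(truth)]
  lv <- re_categories()
  cm <- table(truth = factor(truth, lv), predicted = factor(predicted, lv))
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}
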