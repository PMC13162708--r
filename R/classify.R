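# Hierarchical constraint classification from the conservation matrix.
# N1 counts genomes where >= 90% of an element's bases align; N2 counts
# genomes where <= 10% align. Tiers: constrained in every genome, constrained
# only within the clade, or absent from every non-reference genome.

#' Constraint category labels
#'
#' The four mutually exclusive tiers, in reporting order. `unclassified`
#' is an explicit bucket: elements matching none of the three strict rules
#' (the majority, in practice) are never dropped.
#' @return character vector of category levels.
#' @export
re_categories <- function() {
  c("cross_species_constrained", "clade_specific",
    "reference_species_specific", "unclassified")
}

check_fractions <- function(f) {
  if (anyNA(f) || any(f < 0) || any(f > 1))
    stop("aligned fractions must lie in [0, 1]", call. = FALSE)
  invisible(f)
}

#' Compute N1 / N2 alignment counts
#'
#' @param fractions named numeric vector (one RE) or matrix (REs x genomes)
#'   of aligned-base fractions in [0, 1].
#' @param hi high-alignment threshold; a genome counts toward N1 when
#'   `fraction >= hi` (boundary inclusive). Default 0.9.
#' @param lo low-alignment threshold; a genome counts toward N2 when
#'   `fraction <= lo` (boundary inclusive). Default 0.1.
#' @return for a vector, `c(n1, n2)`; for a matrix, a data.frame with one row
#'   per RE and columns `re_name`, `n1`, `n2`.
#' @export
compute_n1_n2 <- function(fractions, hi = 0.9, lo = 0.1) {
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  check_fractions(fractions)
  if (is.matrix(fractions)) {
    data.frame(re_name = rownames(fractions) %||% as.character(seq_len(nrow(fractions))),
               n1 = rowSums(fractions >= hi),
               n2 = rowSums(fractions <= lo),
               stringsAsFactors = FALSE)
  } else {
    c(n1 = sum(fractions >= hi), n2 = sum(fractions <= lo))
  }
}

#' Define the clade / outgroup partition of target genomes
#'
#' @param clade_members genome names inside the reference clade (e.g.
#'   non-reference Suidae assemblies).
#' @param outgroup_members genome names outside it. Together the two sets must
#'   partition the conservation-matrix columns and be disjoint.
#' @return a `genome_grouping` list.
#' @export
genome_grouping <- function(clade_members, outgroup_members) {
  clade_members <- as.character(clade_members)
  outgroup_members <- as.character(outgroup_members)
  if (length(intersect(clade_members, outgroup_members)))
    stop("clade and outgroup sets must be disjoint", call. = FALSE)
  structure(list(clade_members = clade_members,
                 outgroup_members = outgroup_members),
            class = "genome_grouping")
}

#' Classify one RE into a constraint tier
#'
#' Rules, applied with the stated precedence:
#' * `cross_species_constrained`: fraction `>= hi` in ALL genomes;
#' * `reference_species_specific`: fraction `<= lo` in ALL genomes;
#' * `clade_specific`: fraction `>= hi` in all clade members AND, under the
#'   default strict reading, `<= lo` in all outgroup members (set
#'   `outgroup_rule = "lenient"` to require only `< hi` in outgroups);
#' * otherwise `unclassified`.
#'
#' @param fractions named numeric vector of aligned fractions covering every
#'   genome in `grouping`.
#' @param grouping a [genome_grouping].
#' @param hi,lo thresholds as in [compute_n1_n2].
#' @param outgroup_rule `"strict"` (`<= lo`) or `"lenient"` (`< hi`).
#' @return one of [re_categories()].
#' @export
classify_re <- function(fractions, grouping, hi = 0.9, lo = 0.1,
                        outgroup_rule = c("strict", "lenient")) {
  m <- matrix(fractions, nrow = 1, dimnames = list("re", names(fractions)))
  as.character(classify_matrix(m, grouping, hi = hi, lo = lo,
                               outgroup_rule = outgroup_rule)$category[1])
}

#' Classify every RE of a conservation matrix
#'
#' Vectorised [classify_re] over matrix rows; also reports N1/N2.
#'
#' @param mat conservation matrix (REs x genomes), values in [0, 1].
#' @inheritParams classify_re
#' @return data.frame `re_name`, `n1`, `n2`, `category` (factor with levels
#'   [re_categories()]), one row per matrix row, in input order.
#' @export
classify_matrix <- function(mat, grouping, hi = 0.9, lo = 0.1,
                            outgroup_rule = c("strict", "lenient")) {
  outgroup_rule <- match.arg(outgroup_rule)
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  check_fractions(mat)
  all_g <- c(grouping$clade_members, grouping$outgroup_members)
  missing <- setdiff(all_g, colnames(mat))
  if (length(missing))
    stop("genomes in grouping absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(colnames(mat), all_g)
  if (length(extra))
    stop("matrix genomes not covered by grouping: ",
         paste(extra, collapse = ", "), call. = FALSE)
  ng <- ncol(mat)
  cross <- rowSums(mat >= hi) == ng
  ref_specific <- rowSums(mat <= lo) == ng
  cl <- mat[, grouping$clade_members, drop = FALSE]
  og <- mat[, grouping$outgroup_members, drop = FALSE]
  clade_hi <- rowSums(cl >= hi) == ncol(cl)
  out_low <- if (outgroup_rule == "strict") rowSums(og <= lo) == ncol(og)
             else rowSums(og < hi) == ncol(og)
  cats <- re_categories()
  category <- rep(cats[4], nrow(mat))
  category[clade_hi & out_low] <- cats[2]
  category[ref_specific] <- cats[3]
  category[cross] <- cats[1]
  data.frame(re_name = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             n1 = rowSums(mat >= hi),
             n2 = rowSums(mat <= lo),
             category = factor(category, levels = cats),
             stringsAsFactors = FALSE)
}

#' Truncated (floored) percentage
#'
#' `count / total * 100` truncated -- not rounded -- to `digits` decimal
#' places, computed in integer arithmetic so boundary cases are exact
#' (e.g. 22123 / 135254 prints as 16.35, never 16.36).
#'
#' @param count,total non-negative integers, `total > 0`.
#' @param digits decimal places kept.
#' @return numeric truncated percentage.
#' @export
truncated_percent <- function(count, total, digits = 2) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  ((count * 100 * 10^digits) %/% total) / 10^digits
}

#' Summarise a classification into counts and percentages
#'
#' Per-category count and percentage of total, the percentage floor-truncated
#' to 2 decimal places (the convention under which the published category
#' percentages reproduce from their counts).
#'
#' @param categories factor/character vector of per-RE categories, or the
#'   data.frame returned by [classify_matrix].
#' @param digits decimal places for the truncated percentage.
#' @return data.frame `category`, `count`, `percent` (numeric, truncated),
#'   `percent_label` (fixed-precision string); counts sum to the total.
#' @export
summarize_classification <- function(categories, digits = 2) {
  if (is.data.frame(categories)) categories <- categories$category
  if (!length(categories)) stop("empty classification", call. = FALSE)
  categories <- factor(as.character(categories), levels = re_categories())
  if (anyNA(categories)) stop("unknown category label", call. = FALSE)
  counts <- table(categories)
  total <- length(categories)
  pct <- truncated_percent(as.numeric(counts), total, digits)
  data.frame(category = names(counts),
             count = as.numeric(counts),
             percent = pct,
             percent_label = sprintf(paste0("%.", digits, "f"), pct),
             stringsAsFactors = FALSE)
}

#' Intraspecific constraint summary
#'
#' Over a panel of conspecific genomes (the reference itself excluded), counts
#' REs aligning at `>= hi` in every genome and in at least `k` genomes, with
#' percentages floor-truncated to 1 decimal place (the precision at which the
#' published intraspecific fractions are printed).
#'
#' @param mat conservation matrix (REs x conspecific genomes).
#' @param hi high-alignment threshold, default 0.9.
#' @param k minimum genome count for the relaxed criterion;
#'   `1 <= k <= ncol(mat)`.
#' @return list with `n_res`, `count_all`, `count_at_least_k`, `pct_all`,
#'   `pct_at_least_k` (truncated to 1 d.p.).
#' @export
intraspecific_summary <- function(mat, hi = 0.9, k) {
  if (!is.matrix(mat) || !nrow(mat)) stop("matrix must be non-empty", call. = FALSE)
  if (k < 1 || k > ncol(mat)) stop("k out of range [1, n_genomes]", call. = FALSE)
  check_fractions(mat)
  n_hi <- rowSums(mat >= hi)
  count_all <- sum(n_hi == ncol(mat))
  count_k <- sum(n_hi >= k)
  list(n_res = nrow(mat),
       count_all = count_all,
       count_at_least_k = count_k,
       pct_all = truncated_percent(count_all, nrow(mat), 1),
       pct_at_least_k = truncated_percent(count_k, nrow(mat), 1))
}
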