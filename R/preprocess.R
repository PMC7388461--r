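# Quality control of genotypes and OTU counts: marker filters on call rate
# and minor allele frequency with mean imputation, a sparse-OTU filter on
# raw counts, rarefaction to constant depth, and the relative-abundance
# transform. The sparse filter runs on raw counts first, then rarefaction.

#' Quality-control a genotype panel
#'
#' Removes markers with call rate below `min_call_rate` or minor allele
#' frequency below `min_maf` (strictly below: boundary markers are kept),
#' then imputes remaining missing dosages to twice the allele frequency.
#' Mean imputation leaves allele frequencies invariant and is the
#' convention of GBLUP pipelines.
#'
#' @param panel A [genotype_panel()].
#' @param min_call_rate Minimum fraction of non-missing calls per marker.
#' @param min_maf Minimum minor allele frequency.
#' @return A [genotype_panel()] with no missing values and all MAFs at or
#'   above the threshold.
#' @export
qc_genotypes <- function(panel, min_call_rate = 0.90, min_maf = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ncol(panel$dosage) == 0L) abort("Panel has no markers.")
  cr <- call_rate(panel)
  p <- allele_freq(panel)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(p) & cr >= min_call_rate & maf >= min_maf
  if (!any(keep)) {
    abort("All markers removed by QC.", class = "hologen_empty_panel")
  }
  inform(sprintf(
    "qc_genotypes: removed %d of %d markers (call rate < %.2f or MAF < %.2f).",
    sum(!keep), length(keep), min_call_rate, min_maf))
  d <- panel$dosage[, keep, drop = FALSE]
  if (anyNA(d)) {
    pk <- 2 * p[keep]
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- pk[idx[, 2]]
  }
  genotype_panel_imputed(d)
}

# Internal constructor bypassing the {0,1,2,NA} check for imputed dosages.
genotype_panel_imputed <- function(dosage) {
  structure(list(dosage = dosage), class = "genotype_panel")
}

#' Filter sparse OTU
#'
#' Removes OTU whose total count across samples is below `min_total_count`
#' (the minimum is inclusive: an OTU summing exactly to the threshold is
#' retained). Applied to the raw count table, before rarefaction.
#'
#' @param table An [otu_table()].
#' @param min_total_count Minimum total observation count for an OTU to be
#'   retained.
#' @return A filtered [otu_table()].
#' @export
filter_sparse_otus <- function(table, min_total_count = 1200) {
  stopifnot(inherits(table, "otu_table"))
  tot <- colSums(table$counts)
  keep <- tot >= min_total_count
  if (!any(keep)) {
    abort("All OTU removed by the sparsity filter.",
          class = "hologen_empty_table")
  }
  inform(sprintf("filter_sparse_otus: removed %d of %d OTU (total < %d).",
                 sum(!keep), length(keep), min_total_count))
  otu_table(table$counts[, keep, drop = FALSE], stage = table$stage)
}

#' Rarefy an OTU table to constant depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' counts (multivariate hypergeometric). Samples with fewer than `depth`
#' total reads are dropped with a warning.
#'
#' @param table An [otu_table()].
#' @param depth Target counts per sample.
#' @param seed Seed for the subsampling.
#' @return A rarefied [otu_table()] whose rows all sum to `depth`.
#' @export
rarefy <- function(table, depth = 10000, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  assert_scalar_count(depth, "depth")
  tot <- rowSums(table$counts)
  keep <- tot >= depth
  if (!any(keep)) {
    abort("All samples fall below the rarefaction depth.",
          class = "hologen_empty_table")
  }
  if (any(!keep)) {
    warn(sprintf("rarefy: dropped %d sample(s) with total < %d reads.",
                 sum(!keep), depth))
  }
  counts <- table$counts[keep, , drop = FALSE]
  q <- ncol(counts)
  out <- with_seed(seed, {
    t(apply(counts, 1, function(row) {
      if (sum(row) == depth) return(row)
      reads <- rep.int(seq_len(q), row)
      tabulate(sample(reads, depth), nbins = q)
    }))
  })
  dimnames(out) <- dimnames(counts)
  otu_table(out, stage = table$stage)
}

#' Relative abundances of an OTU table
#'
#' Divides each sample's counts by its total, so rows sum to 1.
#'
#' @param table An [otu_table()].
#' @return Numeric matrix of relative abundances with the table's
#'   dimnames.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  tot <- rowSums(table$counts)
  if (any(tot == 0)) abort("Samples with zero total count cannot be scaled.")
  table$counts / tot
}
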