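# Relationship kernels: the VanRaden (Method 1) genomic relationship
# matrix G, the microbial relationship matrix M = XX'/q from
# log-standardized OTU relative abundances, and the Hadamard product G*M
# whose PSD-ness is guaranteed by the Schur product theorem.

#' Genomic relationship matrix (VanRaden Method 1)
#'
#' Centers dosages by twice the allele frequency and scales by
#' `2 * sum(p * (1 - p))`: `G = ZZ' / (2 sum p_j (1 - p_j))` with
#' `Z = dosage - 2p`.
#'
#' @param panel A QC'd [genotype_panel()]: no missing values, no
#'   monomorphic markers.
#' @param allele_freq Optional allele frequencies to center/scale with
#'   (e.g. computed from training animals only in cross-validation);
#'   defaults to in-sample frequencies.
#' @return A [relationship_kernel()] of kind `"G"`.
#' @export
build_grm <- function(panel, allele_freq = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  if (anyNA(d)) abort("Panel has missing dosages; run qc_genotypes() first.")
  p <- allele_freq %||% (colMeans(d) / 2)
  if (length(p) != ncol(d)) {
    abort("`allele_freq` must have one entry per marker.")
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    abort("All markers monomorphic: the VanRaden denominator is zero.",
          class = "hologen_degenerate_denominator")
  }
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  relationship_kernel(G, kind = "G",
                      meta = list(q = ncol(d), denominator = denom))
}

#' Log-standardize OTU relative abundances
#'
#' Adds a pseudocount to all elements of the relative-abundance matrix,
#' takes logs, and centers and scales each OTU column. Under the default
#' `mean-of-logs` centering each column of the result sums to zero; the
#' `log-of-mean` variant centers by the log of the column mean abundance
#' instead. Columns with zero standard deviation are dropped and reported.
#'
#' @param S Relative-abundance matrix (animals x OTU), entries in `[0, 1]`.
#' @param pseudocount Constant added to all elements before logging.
#' @param centering `"mean-of-logs"` (true standardization, default) or
#'   `"log-of-mean"`.
#' @param sd_divisor `"n-1"` (default) or `"n"` for the scaling SD.
#' @param stat_rows Optional row ids/indices from which the centering and
#'   scaling statistics are computed (e.g. training animals only); the
#'   transform is applied to all rows. Defaults to all rows.
#' @return A matrix of class `standardized_otu` with attributes
#'   `centering`, `sd_divisor` and `dropped` (ids of zero-variance OTU).
#' @export
log_standardize_otu <- function(S, pseudocount = 0.001,
                                centering = c("mean-of-logs", "log-of-mean"),
                                sd_divisor = c("n-1", "n"),
                                stat_rows = NULL) {
  centering <- match.arg(centering)
  sd_divisor <- match.arg(sd_divisor)
  if (!is.matrix(S)) abort("`S` must be a matrix of relative abundances.")
  if (any(S < 0) || any(S > 1)) abort("`S` entries must lie in [0, 1].")
  L <- log(S + pseudocount)
  Ls <- if (is.null(stat_rows)) L else L[stat_rows, , drop = FALSE]
  Ss <- if (is.null(stat_rows)) S else S[stat_rows, , drop = FALSE]
  ctr <- switch(centering,
                "mean-of-logs" = colMeans(Ls),
                "log-of-mean" = log(colMeans(Ss) + pseudocount))
  ns <- nrow(Ls)
  ssq <- colSums(sweep(Ls, 2, colMeans(Ls))^2)
  s <- sqrt(ssq / (if (sd_divisor == "n-1") ns - 1 else ns))
  keep <- s > 0
  if (!any(keep)) {
    abort("All OTU columns have zero variance.",
          class = "hologen_zero_variance")
  }
  if (any(!keep)) {
    inform(sprintf("log_standardize_otu: dropped %d zero-variance OTU.",
                   sum(!keep)))
  }
  X <- sweep(sweep(L[, keep, drop = FALSE], 2, ctr[keep]), 2, s[keep], "/")
  structure(X, class = c("standardized_otu", class(X)),
            centering = centering, sd_divisor = sd_divisor,
            dropped = colnames(S)[!keep] %||% which(!keep))
}

#' Microbial relationship matrix
#'
#' `M = XX' / q` from the log-standardized OTU matrix: the covariance
#' between animals based on the resemblance of their microbiome
#' composition. Under mean-of-logs centering and the `n-1` divisor,
#' `trace(M) = n - 1`.
#'
#' @param X A `standardized_otu` matrix from [log_standardize_otu()].
#' @return A [relationship_kernel()] of kind `"M"`.
#' @export
build_microbial_kernel <- function(X) {
  if (!is.matrix(X)) abort("`X` must be a matrix.")
  if (ncol(X) < 1) abort("No OTU columns retained.")
  if (any(!is.finite(X))) abort("`X` contains non-finite values.")
  q <- ncol(X)
  M <- tcrossprod(unclass(X)) / q
  relationship_kernel(M, kind = "M",
                      meta = list(q = q,
                                  centering = attr(X, "centering"),
                                  sd_divisor = attr(X, "sd_divisor")))
}

#' Genome-by-microbiome interaction kernel
#'
#' Element-wise (Hadamard) product of the genomic and microbial kernels.
#' The Schur product theorem guarantees the product of PSD matrices is
#' PSD; the result is checked numerically and not rescaled (its variance
#' parameter absorbs scale).
#'
#' @param G,M [relationship_kernel()] objects indexed by the same animals
#'   in the same order (hard failure on mismatch; no silent reindexing).
#' @return A [relationship_kernel()] of kind `"GxM"`.
#' @export
interaction_kernel <- function(G, M) {
  stopifnot(inherits(G, "relationship_kernel"),
            inherits(M, "relationship_kernel"))
  if (!identical(animal_ids(G), animal_ids(M))) {
    abort("G and M must be indexed by the same animals in the same order.")
  }
  relationship_kernel(as.matrix(G) * as.matrix(M), kind = "GxM",
                      meta = list(from = c(G$kind, M$kind)))
}
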