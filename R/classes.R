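# Core data containers. Tabular results are tibbles throughout the package;
# genotype panels, OTU tables and relationship kernels are matrix-backed S3
# objects because their natural shape is a matrix, with tidy() methods
# providing the tabular view.

#' Construct a genotype panel
#'
#' A genotype panel holds additive allele dosages (0/1/2, `NA` for missing)
#' for a set of animals at a set of biallelic markers.
#'
#' @param dosage Numeric matrix, animals in rows and markers in columns,
#'   entries in `{0, 1, 2, NA}`. Row names are animal ids, column names
#'   marker ids (both required).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage) {
  if (!is.matrix(dosage) || !is.numeric(dosage)) {
    abort("`dosage` must be a numeric matrix.")
  }
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    abort("`dosage` must carry animal row names and marker column names.")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    abort("Dosages must be 0, 1, 2 or NA.")
  }
  structure(list(dosage = dosage), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  d <- dim(x$dosage)
  miss <- mean(is.na(x$dosage))
  cat(sprintf("<genotype_panel> %d animals x %d markers (%.2f%% missing)\n",
              d[1], d[2], 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Animal ids of a container
#' @param x A `genotype_panel`, `otu_table` or `relationship_kernel`.
#' @return Character vector of ids, in storage order.
#' @export
animal_ids <- function(x) UseMethod("animal_ids")

#' @export
animal_ids.genotype_panel <- function(x) rownames(x$dosage)

#' Per-marker call rate
#'
#' Fraction of non-missing dosages per marker.
#' @param panel A `genotype_panel`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
call_rate <- function(panel) {
  colMeans(!is.na(panel$dosage))
}

#' Per-marker allele frequency
#'
#' Frequency of the counted allele, computed from non-missing dosages.
#' @param panel A `genotype_panel`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
allele_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}

#' @method tidy genotype_panel
#' @export
tidy.genotype_panel <- function(x, ...) {
  tibble::tibble(
    marker_id = colnames(x$dosage),
    call_rate = unname(call_rate(x)),
    allele_freq = unname(allele_freq(x))
  )
}

#' Construct an OTU count table
#'
#' Non-negative integer counts of operational taxonomic units (OTU) per
#' sample, tagged with the growth stage at which the samples were taken.
#'
#' @param counts Integer matrix, samples in rows and OTU in columns, with
#'   sample row names and OTU column names.
#' @param stage Growth-stage label (e.g. `"Wean"`, `"Mid-test"`,
#'   `"Off-test"`).
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, stage) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix.")
  }
  if (any(counts < 0, na.rm = TRUE) || any(counts != floor(counts))) {
    abort("OTU counts must be non-negative integers.")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry sample row names and OTU column names.")
  }
  if (!is_string(stage)) abort("`stage` must be a single string.")
  structure(list(counts = counts, stage = stage), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<otu_table> stage %s: %d samples x %d OTU, median depth %s\n",
              x$stage, d[1], d[2],
              format(stats::median(rowSums(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' @export
animal_ids.otu_table <- function(x) rownames(x$counts)

#' Growth stage of an OTU table
#' @param x An `otu_table`.
#' @return The stage label.
#' @export
otu_stage <- function(x) x$stage

#' @method tidy otu_table
#' @export
tidy.otu_table <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_id",
                        values_to = "count") |>
    dplyr::mutate(stage = x$stage, .before = 1)
}

#' Construct a relationship kernel
#'
#' A dense symmetric animal-by-animal covariance structure: the genomic
#' relationship matrix `G`, the microbial relationship matrix `M`, or their
#' Hadamard product `GxM` modelling genome-by-microbiome interaction.
#'
#' @param K Symmetric numeric matrix with identical animal-id row and
#'   column names.
#' @param kind One of `"G"`, `"M"`, `"GxM"`.
#' @param meta Optional named list of construction metadata (number of
#'   features, transform options).
#' @return An object of class `relationship_kernel`.
#' @export
relationship_kernel <- function(K, kind = c("G", "M", "GxM"), meta = list()) {
  kind <- match.arg(kind)
  if (!is.matrix(K) || !is.numeric(K) || nrow(K) != ncol(K)) {
    abort("`K` must be a square numeric matrix.")
  }
  ids <- rownames(K)
  if (is.null(ids) || is.null(colnames(K)) ||
      !identical(ids, colnames(K))) {
    abort("`K` must have identical row and column animal ids.")
  }
  if (anyDuplicated(ids)) abort("Animal ids must be duplicate-free.")
  if (max(abs(K - t(K))) > 1e-10) {
    abort("`K` must be symmetric to 1e-10.")
  }
  lmin <- min_eigenvalue(K)
  if (lmin < -1e-8) {
    abort(sprintf("Kernel is not numerically PSD (min eigenvalue %.3g).",
                  lmin))
  }
  structure(list(K = (K + t(K)) / 2, kind = kind, ids = ids, meta = meta),
            class = "relationship_kernel")
}

#' @export
print.relationship_kernel <- function(x, ...) {
  cat(sprintf("<relationship_kernel %s> %d animals, mean diag %.3f\n",
              x$kind, length(x$ids), mean(diag(x$K))))
  invisible(x)
}

#' @export
dim.relationship_kernel <- function(x) dim(x$K)

#' @export
animal_ids.relationship_kernel <- function(x) x$ids

#' @export
as.matrix.relationship_kernel <- function(x, ...) x$K

#' @method tidy relationship_kernel
#' @export
tidy.relationship_kernel <- function(x, ...) {
  tibble::as_tibble(x$K, rownames = "animal_i") |>
    tidyr::pivot_longer(-"animal_i", names_to = "animal_j",
                        values_to = "value") |>
    dplyr::mutate(kind = x$kind, .before = 1)
}
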