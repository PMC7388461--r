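# Readers and writers for the plain-text interchange formats: PLINK
# .raw-style genotype tables, TSV OTU tables with a JSON stage sidecar,
# CSV phenotype/design records, TSV kernels with a JSON metadata sidecar,
# and YAML/JSON simulation configs.

#' Write / read a genotype panel as a PLINK-.raw-style table
#'
#' Whitespace-separated table with the six standard leading columns
#' (`FID IID PAT MAT SEX PHENOTYPE`) followed by one additive dosage
#' column per marker; missing dosages are written as `NA`.
#'
#' @param panel A [genotype_panel()].
#' @param path Output file.
#' @param design Optional design tibble supplying `sire_id` (written as
#'   `PAT`) and `sex`.
#' @return `path`, invisibly (writer); a [genotype_panel()] (reader).
#' @export
write_genotypes_raw <- function(panel, path, design = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ids <- animal_ids(panel)
  pat <- rep("0", length(ids))
  sex <- rep(0L, length(ids))
  if (!is.null(design)) {
    i <- match(ids, design$animal_id)
    pat <- design$sire_id[i]
    sex <- ifelse(design$sex[i] == "M", 1L, 2L)
  }
  df <- data.frame(FID = ids, IID = ids, PAT = pat, MAT = "0", SEX = sex,
                   PHENOTYPE = -9, panel$dosage, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_raw
#' @export
read_genotypes_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  d <- as.matrix(df[, -(1:6), drop = FALSE])
  rownames(d) <- df$IID
  genotype_panel(d)
}

#' Write / read an OTU count table as TSV with a stage sidecar
#'
#' Counts go to `<path>` (rows = samples, first column `sample_id`); the
#' growth-stage label goes to a JSON sidecar `<path>.meta.json`.
#'
#' @param table An [otu_table()].
#' @param path Output TSV file.
#' @return `path`, invisibly (writer); an [otu_table()] (reader).
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  readr::write_tsv(tibble::as_tibble(table$counts, rownames = "sample_id"),
                   path)
  jsonlite::write_json(list(stage = table$stage),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  otu_table(counts, stage = meta$stage)
}

#' Write / read phenotype and design records as CSV
#'
#' @param records Tibble of design factors and trait values.
#' @param path CSV file.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_phenotypes <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a relationship kernel as TSV with a metadata sidecar
#'
#' The matrix goes to `<path>` with animal ids as header and first
#' column; kind and construction metadata go to `<path>.meta.json`.
#'
#' @param kernel A [relationship_kernel()].
#' @param path Output TSV file.
#' @return `path`, invisibly (writer); a [relationship_kernel()]
#'   (reader).
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "relationship_kernel"))
  readr::write_tsv(tibble::as_tibble(kernel$K, rownames = "animal_id"),
                   path)
  jsonlite::write_json(c(list(kind = kernel$kind), kernel$meta),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  relationship_kernel(K, kind = meta$kind,
                      meta = meta[setdiff(names(meta), "kind")])
}

#' Read / write a simulation config as YAML or JSON
#'
#' The file may set any argument of [sim_config()]; unset fields take the
#' defaults. Format follows the file extension (`.yaml`/`.yml` or
#' `.json`).
#'
#' @param path Config file.
#' @return A [sim_config()] (reader); `path` invisibly (writer).
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vf <- vals$var_fractions
  if (!is.null(vf)) {
    if (is.matrix(vf) || is.data.frame(vf)) {
      vf <- lapply(seq_len(nrow(vf)),
                   function(i) unlist(vf[i, , drop = TRUE]))
    } else if (is.list(vf)) {
      flat <- all(lengths(vf) == 1L) && !is.null(names(vf))
      vf <- if (flat) unlist(vf) else lapply(vf, unlist)
    }
    vals$var_fractions <- vf
  }
  if (is.data.frame(vals$fixed_effect_sizes)) {
    vals$fixed_effect_sizes <- as.list(vals$fixed_effect_sizes)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  # named numeric vectors must become mappings, or the names are lost
  vals$var_fractions <- lapply(vals$var_fractions, as.list)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
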