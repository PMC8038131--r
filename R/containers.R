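#' SNP specification table
#'
#' Builds and validates the per-SNP metadata table used throughout the
#' pipeline: identifier, chromosome, base-pair position, minor/major
#' allele symbols and the population minor allele frequency (MAF).
#'
#' @param snp_id character vector of SNP identifiers (e.g. rs numbers).
#' @param chrom chromosome labels (opaque strings).
#' @param position 1-based base-pair positions.
#' @param minor_allele,major_allele single-character allele symbols.
#' @param maf minor allele frequencies, each in (0, 0.5].
#' @param gene optional gene symbol annotation.
#' @return A `data.frame` of class `snp_spec` with one row per SNP.
#' @examples
#' snp_specs(snp_id = c("rs1", "rs2"), chrom = c("1", "2"),
#'           position = c(100L, 200L), minor_allele = c("A", "G"),
#'           major_allele = c("G", "T"), maf = c(0.2, 0.4))
#' @export
snp_specs <- function(snp_id, chrom, position, minor_allele, major_allele,
                      maf, gene = NA_character_) {
  specs <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    position = as.integer(position),
    minor_allele = as.character(minor_allele),
    major_allele = as.character(major_allele),
    maf = as.numeric(maf),
    gene = rep_len(as.character(gene), length(snp_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(specs$snp_id)) {
    stop("duplicated snp_id in SNP specification")
  }
  if (any(specs$maf <= 0 | specs$maf > 0.5)) {
    stop("maf must lie in (0, 0.5]; offending SNP(s): ",
         paste(specs$snp_id[specs$maf <= 0 | specs$maf > 0.5],
               collapse = ", "))
  }
  if (any(specs$minor_allele == specs$major_allele)) {
    stop("minor and major allele must differ")
  }
  class(specs) <- c("snp_spec", "data.frame")
  specs
}

#' Ten-SNP thyroid cancer panel
#'
#' The default SNP panel of the pipeline: ten biallelic variants in
#' cell-growth and inflammation genes reported to be associated with
#' thyroid cancer in a Korean hospital-based cohort, with their
#' published minor/major alleles, minor allele frequencies and per-SNP
#' odds ratios. The odds ratios are carried as an annotation column
#' (`published_or`) so the synthetic disease model can emulate effect
#' sizes of realistic magnitude; note risk can sit on the major allele
#' (rs6759952, minor-allele OR 0.76).
#'
#' @return A `snp_spec` data.frame with 10 rows and a `published_or`
#'   column.
#' @export
thyroid_snp_panel <- function() {
  specs <- snp_specs(
    snp_id = c("rs6759952", "rs1369535", "rs13059137", "rs72616195",
               "rs76981250", "rs78371177", "rs7834206", "rs605859",
               "rs11175834", "rs2276010"),
    chrom = c("2", "2", "3", "4", "8", "8", "8", "11", "12", "22"),
    position = c(218271719L, 142636357L, 115347556L, 16043608L,
                 18761954L, 23224452L, 32406148L, 126407440L,
                 65992636L, 22142501L),
    minor_allele = c("T", "G", "C", "T", "T", "G", "G", "C", "C", "C"),
    major_allele = c("C", "A", "T", "C", "C", "A", "A", "T", "T", "T"),
    maf = c(0.2491, 0.3784, 0.3443, 0.3467, 0.02597, 0.03784, 0.209,
            0.06575, 0.1554, 0.02019),
    gene = c("DIRC3", "LRP1B", "GAP43", "PROM1", "PSD3", "LOXL2",
             "NRG1", "KIRREL3", "LOC100507065", "MAPK1")
  )
  specs$published_or <- c(0.76, 1.27, 1.29, 1.29, 1.77, 1.66, 1.46,
                          1.51, 1.39, 1.94)
  specs
}

#' Genotype matrix container
#'
#' Wraps an integer subjects x SNPs matrix of additive minor-allele
#' counts (0/1/2, NA for missing) together with its SNP specification
#' table. Additive coding always counts the MINOR allele; risk-allele
#' orientation is applied later, at PRS construction, never here.
#'
#' @param mat integer matrix, subjects in rows (rownames = subject ids),
#'   SNPs in columns (colnames = snp ids).
#' @param specs a [snp_specs()] table covering every column of `mat`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(mat, specs) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("S%05d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) stop("genotype matrix must have SNP column names")
  if (!all(colnames(mat) %in% specs$snp_id)) {
    stop("SNP(s) missing from spec table: ",
         paste(setdiff(colnames(mat), specs$snp_id), collapse = ", "))
  }
  ok <- is.na(mat) | (mat >= 0L & mat <= 2L)
  if (!all(ok)) stop("genotype values must be 0, 1, 2 or NA")
  specs <- specs[match(colnames(mat), specs$snp_id), , drop = FALSE]
  rownames(specs) <- NULL
  structure(mat, snps = specs, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' SNP metadata of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return the `snp_spec` table carried by `g`.
#' @export
snp_info <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  attr(g, "snps")
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  specs <- attr(x, "snps")
  out <- unclass(x)[i, j, drop = FALSE]
  genotype_matrix(out, specs)
}

#' Column-role manifest for a cohort table
#'
#' Declares the semantic role of each cohort column: the binary outcome,
#' the adjustment covariates, the lifestyle exposures (with their
#' dichotomization cutoffs) and the food-group intake columns feeding
#' dietary-pattern analysis.
#'
#' @param outcome name of the binary 0/1 outcome column.
#' @param covariates character vector of covariate column names.
#' @param exposures character vector of exposure column names.
#' @param food_groups character vector of food-group column names.
#' @param id name of the subject-id column.
#' @return A list of class `column_manifest`.
#' @export
column_manifest <- function(outcome = "case", covariates = character(),
                            exposures = character(),
                            food_groups = character(), id = "subject_id") {
  structure(list(id = id, outcome = outcome,
                 covariates = as.character(covariates),
                 exposures = as.character(exposures),
                 food_groups = as.character(food_groups)),
            class = "column_manifest")
}

validate_manifest <- function(cohort, manifest) {
  stopifnot(inherits(manifest, "column_manifest"))
  need <- c(manifest$id, manifest$outcome, manifest$covariates,
            manifest$exposures, manifest$food_groups)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("manifest names absent column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  y <- cohort[[manifest$outcome]]
  if (!all(stats::na.omit(unique(y)) %in% c(0, 1))) {
    stop("outcome column '", manifest$outcome,
         "' is not binary 0/1; recode (e.g. 1/2 -> 0/1) before loading")
  }
  invisible(manifest)
}
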