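# File formats: PLINK-style .ped/.map pairs, additive-coded 0/1/2 TSV
# ("raw" dialect: header of SNP ids, one subject per line), cohort TSV
# with a YAML column-role manifest. Readers reject rather than coerce;
# every writer/reader pair round-trips bit-exactly on valid data.

#' Write a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param path output path; for `dialect = "ped_map"` the base path
#'   (extensions `.ped`/`.map` are appended).
#' @param dialect `"additive_tsv"` (0/1/2 counts, NA missing) or
#'   `"ped_map"` (allele pairs, `0 0` missing).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("additive_tsv", "ped_map")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(g, "genotype_matrix"))
  specs <- snp_info(g)
  if (dialect == "additive_tsv") {
    dt <- data.table::data.table(subject_id = rownames(g))
    for (j in colnames(g)) dt[[j]] <- unclass(g)[, j]
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(path))
  }
  # ped/map: each SNP as two allele symbols; genotype counts the minor allele
  map <- data.table::data.table(chrom = specs$chrom, snp_id = specs$snp_id,
                                cm = 0, position = specs$position)
  data.table::fwrite(map, paste0(path, ".map"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  n <- nrow(g)
  allele_cols <- vector("list", 2L * ncol(g))
  for (k in seq_len(ncol(g))) {
    gk <- unclass(g)[, k]
    mi <- specs$minor_allele[k]; ma <- specs$major_allele[k]
    a1 <- ifelse(is.na(gk), "0", ifelse(gk >= 1, mi, ma))
    a2 <- ifelse(is.na(gk), "0", ifelse(gk == 2, mi, ma))
    allele_cols[[2 * k - 1]] <- a1
    allele_cols[[2 * k]] <- a2
  }
  ped <- data.table::data.table(fid = rownames(g), iid = rownames(g),
                                pat = 0, mat = 0, sex = 0, pheno = -9)
  for (i in seq_along(allele_cols)) ped[[paste0("a", i)]] <- allele_cols[[i]]
  data.table::fwrite(ped, paste0(path, ".ped"), sep = " ",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix
#'
#' Parses either dialect back into minor-allele counts. The ped/map pair
#' is recoded against the declared minor allele of `specs`; any allele
#' symbol outside the declared major/minor pair is a parse error naming
#' the SNP and line.
#'
#' @param path file path (base path for `ped_map`).
#' @param specs a [snp_specs()] table declaring alleles and MAF metadata.
#' @param dialect `"additive_tsv"` or `"ped_map"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, specs,
                           dialect = c("additive_tsv", "ped_map")) {
  dialect <- match.arg(dialect)
  if (dialect == "additive_tsv") {
    dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                            colClasses = list(character = "subject_id"))
    ids <- dt$subject_id
    dt[["subject_id"]] <- NULL
    mat <- as.matrix(dt)
    if (!all(is.na(mat) | mat %in% 0:2)) {
      bad <- colnames(mat)[colSums(!(is.na(mat) | mat %in% 0:2)) > 0]
      stop("non-additive genotype codes in SNP(s): ",
           paste(bad, collapse = ", "))
    }
    rownames(mat) <- ids
    return(genotype_matrix(mat, specs))
  }
  map <- data.table::fread(paste0(path, ".map"), sep = "\t", header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "position"),
                           colClasses = list(character = 1:2))
  ped <- data.table::fread(paste0(path, ".ped"), sep = " ", header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop("ped/map mismatch: ", m, " SNPs in map but ",
         (ncol(ped) - 6) / 2, " in ped")
  }
  sp <- specs[match(map$snp_id, specs$snp_id), , drop = FALSE]
  if (anyNA(sp$snp_id)) {
    stop("map names SNP(s) absent from specs: ",
         paste(map$snp_id[is.na(sp$snp_id)], collapse = ", "))
  }
  n <- nrow(ped)
  mat <- matrix(NA_integer_, n, m,
                dimnames = list(ped[[2]], map$snp_id))
  for (k in seq_len(m)) {
    a1 <- ped[[6 + 2 * k - 1]]
    a2 <- ped[[6 + 2 * k]]
    mi <- sp$minor_allele[k]; ma <- sp$major_allele[k]
    known <- c(mi, ma, "0")
    bad <- which(!(a1 %in% known) | !(a2 %in% known))
    if (length(bad) > 0) {
      stop("unexpected allele '",
           setdiff(unique(c(a1[bad], a2[bad])), known)[1],
           "' for SNP ", map$snp_id[k], " at ped line ", bad[1])
    }
    miss <- a1 == "0" | a2 == "0"
    cnt <- (a1 == mi) + (a2 == mi)
    cnt[miss] <- NA_integer_
    mat[, k] <- as.integer(cnt)
  }
  genotype_matrix(mat, specs)
}

#' Write / read a cohort table with its manifest
#'
#' The cohort is a TSV keyed by subject id; the manifest is a YAML
#' sidecar declaring column roles ([column_manifest()]).
#'
#' @param cohort data.frame with a subject-id column.
#' @param manifest a [column_manifest()].
#' @param path TSV path; the manifest is written to `paste0(path, ".yaml")`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, manifest, path) {
  validate_manifest(cohort, manifest)
  data.table::fwrite(cohort, path, sep = "\t", na = "NA", quote = FALSE)
  yaml::write_yaml(unclass(manifest), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @param genotypes optional [genotype_matrix()]; when given, subjects
#'   are aligned to its row order by id and id mismatches are an error.
#' @export
read_cohort <- function(path, manifest = NULL, genotypes = NULL) {
  if (is.null(manifest)) {
    mf <- yaml::read_yaml(paste0(path, ".yaml"))
    manifest <- column_manifest(outcome = mf$outcome,
                                covariates = mf$covariates,
                                exposures = mf$exposures,
                                food_groups = mf$food_groups,
                                id = mf$id)
  }
  cohort <- as.data.frame(data.table::fread(
    path, sep = "\t", na.strings = "NA",
    colClasses = stats::setNames(list(manifest$id), "character")))
  validate_manifest(cohort, manifest)
  if (!is.null(genotypes)) {
    ids <- rownames(genotypes)
    idx <- match(ids, cohort[[manifest$id]])
    if (anyNA(idx)) {
      stop("subject id(s) in genotypes missing from cohort: ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    }
    cohort <- cohort[idx, , drop = FALSE]
    rownames(cohort) <- NULL
  }
  attr(cohort, "manifest") <- manifest
  cohort
}
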