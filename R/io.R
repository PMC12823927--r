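# Plain-text I/O for genotypes, phenotypes and LD matrices.
# Genotype files are samples x SNPs: a header row of SNP ids preceded by a
# "sample_id" column name, then one row per individual.

#' Write a genotype matrix to delimited text
#'
#' @param G A `genotype_matrix`.
#' @param path Output path (a trailing `.gz` writes gzip).
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, sep = "\t") {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(sample_id = G$sample_ids, G$values, check.names = FALSE)
  colnames(df) <- c("sample_id", G$snp_ids)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from delimited text
#'
#' Expects a header row of SNP ids with a leading sample-id column and one
#' row of 0/1/2 dosages per individual.
#'
#' @param path Input path.
#' @param sep Field separator.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_ldrisk("genotype file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(vals %in% c(0, 1, 2))) {
    stop_ldrisk("genotype dosages must all be 0, 1 or 2")
  }
  storage.mode(vals) <- "integer"
  dimnames(vals) <- NULL
  new_genotype_matrix(vals, snp_ids = colnames(df)[-1L], sample_ids = ids)
}

#' Read genotypes from a VCF into additive minor-allele dosages
#'
#' Converts GT fields to counts of the minor allele, where "minor" means the
#' allele (REF or ALT) with the lower frequency among the samples in the
#' file; at a site where ALT is the major allele the coding is flipped so
#' that 2 always counts two minor alleles. Requires the `vcfR` package.
#'
#' @param path Path to an (optionally gzipped) VCF.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_ldrisk("read_genotypes_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(g) {
    g[is.na(g)] <- "0/0"
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(a, function(al) sum(al != "0" & al != "."), numeric(1))
  }
  dos <- t(apply(gt, 1L, alt_count))          # sites x samples, ALT counts
  alt_freq <- rowMeans(dos) / 2
  flip <- alt_freq > 0.5                      # ALT is the major allele
  dos[flip, ] <- 2 - dos[flip, ]
  vals <- t(dos)                              # samples x sites
  storage.mode(vals) <- "integer"
  snp_ids <- vcfR::getID(v)
  if (all(is.na(snp_ids))) {
    snp_ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  }
  dimnames(vals) <- NULL
  new_genotype_matrix(vals, snp_ids = snp_ids, sample_ids = colnames(gt))
}

#' Write a phenotype vector as two-column delimited text
#'
#' @param y A `phenotype_vector` or numeric vector.
#' @param sample_ids Sample identifiers (required when `y` is bare numeric).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(y, path, sample_ids = NULL, sep = "\t") {
  vals <- if (inherits(y, "phenotype_vector")) y$values else as.numeric(y)
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%05d", seq_along(vals))
  utils::write.table(data.frame(sample_id = sample_ids, value = vals),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column phenotype file
#'
#' @param path Input path.
#' @param sep Field separator.
#' @return Named numeric vector of phenotype values.
#' @export
read_phenotype <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_ldrisk("phenotype file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Write an LD matrix with a provenance header line
#'
#' The first line is `#ldrisk_ld p=<p> n_source=<n>`; the body is the p x p
#' numeric matrix, tab-delimited. A `.gz` suffix gzips the file.
#'
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ldrisk_ld p=%d n_source=%d",
                     ncol(ld$values), ld$n_source), con)
  writeLines(paste(ld$snp_ids, collapse = "\t"), con)
  utils::write.table(ld$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix()]
#'
#' @param path Input path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop_ldrisk("LD file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 2L)
  if (!grepl("^#ldrisk_ld ", hdr[1L])) stop_ldrisk("not an ldrisk LD file: ", path)
  n_source <- as.integer(sub(".*n_source=(\\d+).*", "\\1", hdr[1L]))
  snp_ids <- strsplit(hdr[2L], "\t", fixed = TRUE)[[1L]]
  vals <- as.matrix(utils::read.table(con, sep = "\t", header = FALSE))
  dimnames(vals) <- NULL
  new_ld_matrix(vals, snp_ids = snp_ids, n_source = n_source)
}
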