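#' Construct a genotype dosage matrix
#'
#' Bundles a matrix of SNP dosages (minor/reference allele counts 0, 1, 2,
#' with `NA` for missing calls) together with sample identifiers and SNP
#' identifiers. Allele frequencies may be supplied; when omitted they are
#' computed downstream from the non-missing column means (frequency =
#' mean dosage / 2).
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param fid,iid character vectors of family and individual identifiers,
#'   one per row of `dosages`. The pair (fid, iid) must be unique.
#' @param snp_ids optional character vector of SNP identifiers (defaults to
#'   column names of `dosages`, or `snp1..snpM`).
#' @param allele_freq optional numeric vector of per-SNP reference-allele
#'   frequencies in \[0, 1\]; computed from the data when `NULL`.
#' @return an object of class `gsem_geno` with elements `dosages`,
#'   `sample_ids` (data frame with columns `FID`, `IID`), `snp_ids`,
#'   `allele_freq`.
#' @export
genotype_matrix <- function(dosages, fid, iid, snp_ids = NULL,
                            allele_freq = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  if (length(fid) != n || length(iid) != n)
    stop("fid/iid must have one entry per row of 'dosages'")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1, 2 or NA")
  key <- paste(fid, iid, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate sample ids: ", paste(fid[duplicated(key)],
                                         iid[duplicated(key)], collapse = ", "))
  if (is.null(snp_ids)) {
    snp_ids <- colnames(dosages)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  }
  if (length(snp_ids) != ncol(dosages))
    stop("snp_ids length must match number of SNP columns")
  if (!is.null(allele_freq)) {
    if (length(allele_freq) != ncol(dosages))
      stop("allele_freq length must match number of SNP columns")
    if (any(allele_freq < 0 | allele_freq > 1, na.rm = TRUE))
      stop("allele frequencies must lie in [0, 1]")
  }
  structure(list(dosages = dosages,
                 sample_ids = data.frame(FID = as.character(fid),
                                         IID = as.character(iid),
                                         stringsAsFactors = FALSE),
                 snp_ids = as.character(snp_ids),
                 allele_freq = allele_freq),
            class = "gsem_geno")
}

#' Read a PLINK-raw style genotype file
#'
#' Reads delimited text with a header line, columns `FID`, `IID`, then one
#' column per SNP holding additive dosages 0/1/2 with `NA` for missing
#' (the dialect written by `plink --recode A`, ignoring the PAT/MAT/SEX/
#' PHENOTYPE columns if present).
#'
#' @param path file path.
#' @return a [genotype_matrix()] object.
#' @export
read_plink_raw <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  dat <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "-9"))
  if (ncol(dat) < 3 || !all(c("FID", "IID") %in% names(dat)[1:2]))
    stop("malformed genotype file (line 1): expected header starting FID IID")
  drop <- intersect(c("PAT", "MAT", "SEX", "PHENOTYPE"), names(dat))
  snp_cols <- setdiff(names(dat), c("FID", "IID", drop))
  geno <- as.matrix(dat[, snp_cols, drop = FALSE])
  if (!is.numeric(geno)) {
    bad_col <- snp_cols[!vapply(dat[, snp_cols, drop = FALSE], is.numeric,
                                logical(1))][1]
    bad_row <- which(is.na(suppressWarnings(as.numeric(dat[[bad_col]]))) &
                     !is.na(dat[[bad_col]]))[1]
    stop("malformed genotype file (line ", bad_row + 1L, "): non-numeric ",
         "dosage in column ", bad_col)
  }
  genotype_matrix(geno, dat$FID, dat$IID, snp_ids = snp_cols)
}

#' @export
print.gsem_geno <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "SNPs;",
      sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}
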