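# GCTA binary GRM triple: <prefix>.grm.bin / .grm.N.bin / .grm.id.
# Payload is the lower triangle including the diagonal in row-major order
# ((1,1),(2,1),(2,2),(3,1),...), little-endian float32.

lower_tri_order <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n))   # row index
  k <- sequence(seq_len(n))              # column index
  cbind(j, k)
}

#' Write a GRM as a GCTA binary triple
#'
#' Writes `<prefix>.grm.bin` (relationships), `<prefix>.grm.N.bin`
#' (per-pair SNP counts) and `<prefix>.grm.id` (tab-delimited FID/IID).
#' Values are stored as little-endian float32, lower triangle including
#' the diagonal in row-major order.
#'
#' @param grm a `grm` object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  idx <- lower_tri_order(n)
  vals <- grm$values[idx]
  cnts <- as.numeric(grm$pair_counts[idx])
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(vals, con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(cnts, con, size = 4L, endian = "little")
  close(con)
  utils::write.table(grm$sample_ids, paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

read_grm_bin_payload <- function(path, n_expect) {
  n_vals <- n_expect * (n_expect + 1) / 2
  expect_bytes <- 4 * n_vals
  if (!file.exists(path)) stop("GRM file missing: ", path)
  got <- file.size(path)
  if (got != expect_bytes)
    stop("format error in ", path, ": expected ", expect_bytes,
         " bytes for ", n_expect, " samples, found ", got)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, what = "numeric", n = n_vals, size = 4L, endian = "little")
}

#' Read a GCTA binary GRM triple
#'
#' @param prefix path prefix of the `.grm.bin` / `.grm.N.bin` / `.grm.id`
#'   triple; all three files must be present.
#' @return a `grm` object (double precision in memory; the on-disk format
#'   is float32).
#' @export
read_grm_gcta <- function(prefix) {
  id_path <- paste0(prefix, ".grm.id")
  if (!file.exists(id_path)) stop("GRM file missing: ", id_path)
  ids <- utils::read.table(id_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("FID", "IID"),
                           colClasses = "character")
  n <- nrow(ids)
  vals <- read_grm_bin_payload(paste0(prefix, ".grm.bin"), n)
  cnts <- read_grm_bin_payload(paste0(prefix, ".grm.N.bin"), n)
  A <- matrix(0, n, n)
  M <- matrix(0, n, n)
  idx <- lower_tri_order(n)
  A[idx] <- vals
  A[idx[, 2:1, drop = FALSE]] <- vals
  M[idx] <- cnts
  M[idx[, 2:1, drop = FALSE]] <- cnts
  structure(list(values = A, sample_ids = ids, pair_counts = M,
                 n_snps = max(M), n_monomorphic = NA_integer_),
            class = "grm")
}
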