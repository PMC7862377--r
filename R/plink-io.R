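#' Read a PLINK BED/BIM/FAM fileset
#'
#' Decodes the SNP-major 2-bit PLINK 1 binary format. Dosages count copies
#' of the BIM A1 allele: byte code 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA
#' (missing).
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` must exist.
#' @return a [genotype_panel()]. The FAM's IID column supplies sample ids
#'   (FID kept as attribute `fid`).
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("format error: missing file ", f)

  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos_bp",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           col.names = c("fid", "iid", "pid", "mid", "sex",
                                         "pheno"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01))
    stop("format error: ", bed_path,
         " lacks the SNP-major PLINK magic bytes 6c 1b 01")
  bpv <- ceiling(n / 4)  # bytes per variant
  if (length(raw) != 3 + bpv * m)
    stop("format error: ", bed_path, " has ", length(raw), " bytes; expected ",
         3 + bpv * m, " for ", n, " samples x ", m, " SNPs")

  codes <- plink_decode_lut()          # 256 x 4 dosage values
  body <- as.integer(raw[-(1:3)]) + 1L
  # each byte expands to 4 dosages, sample-minor within byte
  vals <- t(codes[body, , drop = FALSE])        # 4 x (bpv*m)
  dim(vals) <- c(4L * bpv, m)
  dos <- vals[seq_len(n), , drop = FALSE]

  panel <- genotype_panel(dos, bim[, c("id", "chrom", "pos_bp", "allele1",
                                       "allele2")], fam$iid)
  attr(panel, "fid") <- fam$fid
  panel
}

# 2-bit genotype codes of the PLINK 1 .bed format, low bits = first sample
plink_decode_lut <- function() {
  lut <- matrix(NA_real_, 256, 4)
  map <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  for (byte in 0:255) {
    v <- byte
    for (k in 1:4) {
      lut[byte + 1L, k] <- map[[as.character(v %% 4)]]
      v <- v %/% 4
    }
  }
  lut
}

#' Write a PLINK BED/BIM/FAM fileset
#'
#' Inverse of [read_plink()]; padding bits in the final byte of each variant
#' record are zero, so write-then-read round-trips are byte-identical.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$sample_ids)
  m <- nrow(panel$snp_meta)
  bpv <- ceiling(n / 4)

  # dosage -> 2-bit code; NA -> 01; pad slots -> 00 (reads back as dosage 2
  # but padded rows are discarded by the reader)
  code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  codes <- matrix(0L, 4L * bpv, m)
  codes[seq_len(n), ] <- code_of(panel$dosages)
  dim(codes) <- c(4L, bpv * m)
  bytes <- codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] + 64L * codes[4, ]

  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)

  bim <- data.frame(panel$snp_meta$chrom, panel$snp_meta$id, 0,
                    panel$snp_meta$pos_bp, panel$snp_meta$allele1,
                    panel$snp_meta$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fid <- attr(panel, "fid")
  if (is.null(fid)) fid <- panel$sample_ids
  fam <- data.frame(fid, panel$sample_ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read / write a GCTA binary GRM triple
#'
#' The GCTA dialect: `<prefix>.grm.bin` holds the lower triangle (including
#' the diagonal, row by row) as little-endian float32, `<prefix>.grm.N.bin`
#' the per-pair SNP counts in the same layout, and `<prefix>.grm.id` a
#' two-column FID/IID text file.
#'
#' @param prefix path prefix.
#' @return `read_grm`: a `grm` object (see [compute_grm()]).
#' @export
read_grm <- function(prefix) {
  bin <- paste0(prefix, ".grm.bin")
  nbin <- paste0(prefix, ".grm.N.bin")
  idf <- paste0(prefix, ".grm.id")
  for (f in c(bin, nbin, idf))
    if (!file.exists(f)) stop("format error: missing file ", f)
  ids <- utils::read.table(idf, header = FALSE,
                           colClasses = "character")
  n <- nrow(ids)
  npairs <- n * (n + 1) / 2
  vals <- readBin(bin, "numeric", n = npairs + 1, size = 4,
                  endian = "little")
  if (length(vals) != npairs)
    stop("format error: ", bin, " holds ", length(vals),
         " float32 values; expected ", npairs, " for ", n, " ids")
  counts <- readBin(nbin, "numeric", n = npairs + 1, size = 4,
                    endian = "little")
  if (length(counts) != npairs)
    stop("format error: ", nbin, " size mismatch vs id count")
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals   # column-major upper == row-major lower
  A <- A + t(A) - diag(diag(A))
  dimnames(A) <- list(ids[[2]], ids[[2]])
  structure(list(matrix = A, sample_ids = ids[[2]],
                 m_snps = as.integer(round(max(counts)))),
            class = "grm")
}

#' @rdname read_grm
#' @param grm a `grm` object.
#' @return `write_grm`: invisibly, the prefix.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  A <- grm$matrix
  n <- nrow(A)
  vals <- A[upper.tri(A, diag = TRUE)]   # row-major lower triangle
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(vals, con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$m_snps), length(vals)), con, size = 4,
           endian = "little")
  close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Phenotype/covariate table I/O
#'
#' Whitespace-delimited tables with FID and IID as the first two columns
#' (the PLINK/GCTA convention).
#'
#' @param path file path.
#' @return `read_pheno_tsv`: data.frame with columns fid, iid, then the
#'   value columns.
#' @export
read_pheno_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(d)[1:2] <- c("fid", "iid")
  d
}

#' @rdname read_pheno_tsv
#' @param values data.frame of per-sample values.
#' @param sample_ids sample ids (used for both FID and IID).
#' @export
write_pheno_tsv <- function(values, sample_ids, path) {
  out <- cbind(FID = sample_ids, IID = sample_ids, values)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
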