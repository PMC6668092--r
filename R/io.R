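# PLINK1 binary genotype triplet and GCTA binary GRM readers/writers.
# .bed layout (SNP-major): magic bytes 0x6C 0x1B, mode byte 0x01, then
# ceil(n/4) bytes per variant, two bits per sample packed little-endian
# within each byte. 2-bit codes: 00 = homozygous A1 (dosage 2),
# 01 = missing, 10 = heterozygous (1), 11 = homozygous A2 (0).
# The A1-dosage orientation is kept as read; standardization makes the
# orientation irrelevant up to sign.

bedCodeToDosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)

#' Read a PLINK1 binary genotype fileset
#'
#' @param prefix path prefix; \code{prefix.bed}, \code{prefix.bim} and
#'   \code{prefix.fam} must all exist.
#' @return a \code{RawGenotypes}; sample IDs are \code{FID_IID} from the
#'   .fam file, variant IDs from the .bim file.
#' @export
readPlink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "))
  fam <- utils::read.table(paths[3L], header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paths[2L], header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  con <- file(paths[1L], "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 3L)
  if (length(hdr) < 3L || hdr[1L] != as.raw(0x6c) || hdr[2L] != as.raw(0x1b))
    stop("not a PLINK1 bed file (bad magic bytes)")
  if (hdr[3L] == as.raw(0x00))
    stop("sample-major PLINK bed files are not supported")
  if (hdr[3L] != as.raw(0x01))
    stop("unknown PLINK bed mode byte")
  bytesPerVariant <- ceiling(n / 4)
  body <- readBin(con, "raw", bytesPerVariant * m)
  if (length(body) != bytesPerVariant * m)
    stop("truncated PLINK bed file")
  bits <- as.integer(body)
  # decode all four 2-bit fields of every byte at once
  codes <- rbind(bits %% 4L, (bits %/% 4L) %% 4L,
                 (bits %/% 16L) %% 4L, bits %/% 64L)
  G <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    colCodes <- codes[, ((j - 1L) * bytesPerVariant + 1L):(j * bytesPerVariant)]
    G[, j] <- bedCodeToDosage[as.character(as.vector(colCodes)[seq_len(n)])]
  }
  RawGenotypes(G, sampleIDs = paste(fam[[1L]], fam[[2L]], sep = "_"),
               variantIDs = as.character(bim[[2L]]))
}

#' Write a PLINK1 binary genotype fileset
#'
#' @param raw a \code{RawGenotypes}.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(raw, prefix) {
  stopifnot(is(raw, "RawGenotypes"))
  G <- raw@dosages
  n <- nrow(G)
  m <- ncol(G)
  ids <- raw@sampleIDs
  fam <- data.frame(FID = ids, IID = ids, father = 0L, mother = 0L,
                    sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = 1L, id = raw@variantIDs, cm = 0L,
                    pos = seq_len(m), A1 = "A", A2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  dosageToCode <- function(g) {
    code <- integer(length(g))
    code[is.na(g)] <- 1L
    code[!is.na(g) & g == 2] <- 0L
    code[!is.na(g) & g == 1] <- 2L
    code[!is.na(g) & g == 0] <- 3L
    code
  }
  bytesPerVariant <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pow <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    code <- c(dosageToCode(G[, j]), rep(0L, bytesPerVariant * 4L - n))
    byteVals <- colSums(matrix(code * pow, nrow = 4L))
    writeBin(as.raw(byteVals), con)
  }
  invisible(prefix)
}

#' Read a GCTA binary GRM
#'
#' \code{prefix.grm.bin} holds the lower triangle (including diagonal) of
#' the GRM row-major as float32; \code{prefix.grm.id} lists FID/IID pairs;
#' \code{prefix.grm.N.bin} (variant counts) is read when present.
#'
#' @param prefix path prefix.
#' @return list with symmetric \code{grm} matrix, character \code{ids}
#'   (FID_IID) and \code{N} (matrix or NULL).
#' @export
readGctaGrm <- function(prefix) {
  binPath <- paste0(prefix, ".grm.bin")
  idPath <- paste0(prefix, ".grm.id")
  if (!file.exists(binPath) || !file.exists(idPath))
    stop("missing GRM file(s): need .grm.bin and .grm.id")
  idTab <- utils::read.table(idPath, header = FALSE,
                             stringsAsFactors = FALSE)
  n <- nrow(idTab)
  nTri <- n * (n + 1) / 2
  expectBytes <- 4 * nTri
  if (file.info(binPath)$size != expectBytes)
    stop(sprintf("corrupt GRM: %s has %d bytes, expected %d",
                 binPath, file.info(binPath)$size, expectBytes))
  con <- file(binPath, "rb")
  vals <- readBin(con, "numeric", nTri, size = 4L)
  close(con)
  G <- matrix(0, n, n)
  G[upper.tri(G, diag = TRUE)] <- vals   # column-wise upper = row-wise lower
  G <- G + t(G) - diag(diag(G))
  N <- NULL
  nPath <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nPath)) {
    con <- file(nPath, "rb")
    nv <- readBin(con, "numeric", nTri, size = 4L)
    close(con)
    N <- matrix(0, n, n)
    N[upper.tri(N, diag = TRUE)] <- nv
    N <- N + t(N) - diag(diag(N))
  }
  list(grm = G, ids = paste(idTab[[1L]], idTab[[2L]], sep = "_"), N = N)
}

#' Write a GCTA binary GRM
#'
#' @param grm symmetric matrix.
#' @param ids character sample identifiers (used for FID and IID).
#' @param prefix output path prefix.
#' @param N optional variant-count matrix for \code{.grm.N.bin}.
#' @return the prefix, invisibly.
#' @export
writeGctaGrm <- function(grm, ids, prefix, N = NULL) {
  n <- nrow(grm)
  stopifnot(ncol(grm) == n, length(ids) == n)
  utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  vals <- grm[upper.tri(grm, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4L)
  close(con)
  if (!is.null(N)) {
    con <- file(paste0(prefix, ".grm.N.bin"), "wb")
    writeBin(as.numeric(N[upper.tri(N, diag = TRUE)]), con, size = 4L)
    close(con)
  }
  invisible(prefix)
}

#' Read phenotype and covariate files aligned to genotype samples
#'
#' GCTA-style whitespace-delimited files with columns FID IID value(s)
#' and "NA" for missing. Samples are inner-joined on (FID, IID) against
#' the genotype sample order; rows with any missing phenotype or
#' covariate are dropped listwise. An intercept column is prepended to X.
#'
#' @param phenoPath path to the phenotype file (FID IID phenotype).
#' @param covarPath optional path to a covariate file (FID IID covars...).
#' @param sampleIDs genotype sample identifiers ("FID_IID") defining the
#'   output order.
#' @return list with \code{y}, \code{X} (intercept first), and
#'   \code{keep}: indices into \code{sampleIDs} of the retained samples.
#' @export
readPhenoCovar <- function(phenoPath, covarPath = NULL, sampleIDs) {
  ph <- utils::read.table(phenoPath, header = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = "NA")
  if (ncol(ph) < 3L) stop("phenotype file needs columns FID IID value")
  if (!is.numeric(ph[[3L]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(ph[[3L]]))) &
                   !is.na(ph[[3L]]))
    stop(sprintf("non-numeric phenotype value at line %d",
                 if (length(bad)) bad[1L] else 1L))
  }
  key <- paste(ph[[1L]], ph[[2L]], sep = "_")
  idx <- match(sampleIDs, key)
  y <- ph[[3L]][idx]
  Xextra <- NULL
  if (!is.null(covarPath)) {
    cv <- utils::read.table(covarPath, header = FALSE,
                            stringsAsFactors = FALSE,
                            na.strings = "NA")
    ckey <- paste(cv[[1L]], cv[[2L]], sep = "_")
    cidx <- match(sampleIDs, ckey)
    Xextra <- as.matrix(cv[cidx, -(1:2), drop = FALSE])
    storage.mode(Xextra) <- "double"
  }
  keep <- which(!is.na(y) &
                  (if (is.null(Xextra)) TRUE else rowSums(is.na(Xextra)) == 0))
  if (!length(keep)) stop("no overlapping samples with complete data")
  nDropped <- length(sampleIDs) - length(keep)
  if (nDropped > 0)
    message(sprintf("dropped %d sample(s) with missing phenotype/covariates",
                    nDropped))
  X <- cbind(intercept = rep(1, length(keep)))
  if (!is.null(Xextra)) X <- cbind(X, Xextra[keep, , drop = FALSE])
  list(y = y[keep], X = X, keep = keep)
}
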