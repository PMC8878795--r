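# Binary list-mode format, version 1.
#
# 64-byte header: magic "PETLMv01" (8 bytes), version uint32, count uint32,
# geometry hash (float64), reserved zeros to 64 bytes.
# Each coincidence is a fixed 24-byte little-endian packet:
#   offset 0  uint32  crystal_a flat id
#   offset 4  uint32  crystal_b flat id
#   offset 8  uint16  energy_a, keV (rounded, clamped to 65535)
#   offset 10 uint16  energy_b, keV
#   offset 12 uint64  timestamp, ps
#   offset 20 uint16  flags: bit0 prompt(1)/delayed(0), bits1-2 truth class
#                     (0 true, 1 scattered, 2 random), bit3 truth-valid
#   offset 22 uint16  reserved (zero)

LM_MAGIC <- "PETLMv01"
LM_VERSION <- 1L
LM_HEADER <- 64L
LM_PACKET <- 24L

u32raw <- function(x) {
  # vectorized unsigned 32-bit little-endian encoding
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  m <- rbind(b0, b1, b2, b3)
  as.raw(as.integer(m))
}
u16raw <- function(x) {
  x <- as.numeric(x)
  m <- rbind(x %% 256, x %/% 256)
  as.raw(as.integer(m))
}
rawToU <- function(r, nbytes) {
  m <- matrix(as.integer(r), nrow = nbytes)
  as.numeric(256^(seq_len(nbytes) - 1) %*% m)
}

#' Write coincidences to a binary list-mode file
#'
#' Fixed 24-byte packets (see the package vignette for the byte layout) after
#' a 64-byte header carrying a magic string, format version, packet count and
#' the geometry hash, so a file can never be rebinned against the wrong
#' crystal map.
#'
#' @param coinc coincidence data.frame (classified or not).
#' @param path output file.
#' @param geom the \code{ScannerGeometry} the crystal ids refer to.
#' @return invisibly, the number of bytes written.
#' @export
writeListmode <- function(coinc, path, geom) {
  n <- nrow(coinc)
  truthValid <- "truth" %in% names(coinc) && n > 0 && !anyNA(coinc$truth)
  truth <- if (truthValid)
    match(coinc$truth, c("true", "scattered", "random")) - 1L else rep(0L, n)
  flags <- as.integer(coinc$stream == "prompt") + 2L * truth +
    8L * as.integer(truthValid)
  ts_ps <- round(coinc$t_ns * 1000)
  pk <- matrix(as.raw(0), nrow = LM_PACKET, ncol = n)
  if (n > 0) {
    pk[1:4, ] <- matrix(u32raw(coinc$id_a), nrow = 4)
    pk[5:8, ] <- matrix(u32raw(coinc$id_b), nrow = 4)
    pk[9:10, ] <- matrix(u16raw(pmin(65535, pmax(0, round(coinc$e_a)))), nrow = 2)
    pk[11:12, ] <- matrix(u16raw(pmin(65535, pmax(0, round(coinc$e_b)))), nrow = 2)
    lo <- ts_ps %% 2^32
    hi <- ts_ps %/% 2^32
    pk[13:16, ] <- matrix(u32raw(lo), nrow = 4)
    pk[17:20, ] <- matrix(u32raw(hi), nrow = 4)
    pk[21:22, ] <- matrix(u16raw(flags), nrow = 2)
  }
  hdr <- raw(LM_HEADER)
  hdr[1:8] <- charToRaw(LM_MAGIC)
  hdr[9:12] <- u32raw(LM_VERSION)
  hdr[13:16] <- u32raw(n)
  hdr[17:24] <- writeBin(geometryHash(geom), raw(), size = 8,
                         endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  if (n > 0) writeBin(as.vector(pk), con)
  invisible(LM_HEADER + LM_PACKET * n)
}

#' Read a binary list-mode file
#'
#' @param path input file.
#' @param geom optional \code{ScannerGeometry}; if given, the stored geometry
#'   hash must match.
#' @return coincidence data.frame (with \code{truth} if the file carries
#'   valid ground truth).
#' @export
readListmode <- function(path, geom = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < LM_HEADER) stop("list-mode file truncated or missing")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", LM_HEADER)
  if (!identical(hdr[1:8], charToRaw(LM_MAGIC))) stop("bad list-mode magic")
  ver <- rawToU(hdr[9:12], 4)
  if (ver != LM_VERSION) stop("unsupported list-mode version: ", ver)
  n <- rawToU(hdr[13:16], 4)
  h <- readBin(hdr[17:24], "double", 1, size = 8, endian = "little")
  if (!is.null(geom) && abs(h - geometryHash(geom)) > 1e-6)
    stop("geometry hash mismatch: file was written for a different geometry")
  if (sz != LM_HEADER + LM_PACKET * n)
    stop("list-mode file truncated: payload size mismatch")
  if (n == 0)
    return(data.frame(id_a = integer(0), id_b = integer(0), e_a = numeric(0),
                      e_b = numeric(0), t_ns = numeric(0),
                      stream = character(0)))
  pk <- matrix(readBin(con, "raw", LM_PACKET * n), nrow = LM_PACKET)
  flags <- rawToU(pk[21:22, , drop = FALSE], 2)
  truthValid <- bitwAnd(as.integer(flags), 8L) > 0
  out <- data.frame(
    id_a = as.integer(rawToU(pk[1:4, , drop = FALSE], 4)),
    id_b = as.integer(rawToU(pk[5:8, , drop = FALSE], 4)),
    e_a = rawToU(pk[9:10, , drop = FALSE], 2),
    e_b = rawToU(pk[11:12, , drop = FALSE], 2),
    t_ns = (rawToU(pk[13:16, , drop = FALSE], 4) +
              rawToU(pk[17:20, , drop = FALSE], 4) * 2^32) / 1000,
    stream = ifelse(bitwAnd(as.integer(flags), 1L) > 0, "prompt", "delayed"))
  if (all(truthValid))
    out$truth <- c("true", "scattered", "random")[
      bitwAnd(as.integer(flags) %/% 2L, 3L) + 1L]
  out
}

#' List-mode payload data rate
#'
#' Payload bytes per second for a given prompt rate with 24-byte packets
#' (e.g. a 132 kHz prompt stream corresponds to ~3.2e6 bytes/s, about
#' 3.1 MiB/s).
#' @param prompts_per_s coincidence rate, 1/s.
#' @return bytes per second.
#' @export
listmodeDataRate <- function(prompts_per_s) prompts_per_s * LM_PACKET
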