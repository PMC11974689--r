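# Minimal deterministic ZIP writer (deflate entries).
#
# Archives are written with fixed timestamps so identical inputs produce
# byte-identical containers. The deflate stream and the CRC-32 of each
# entry are taken from the gzip wrapper produced by memCompress(): a gzip
# member is a 10-byte header, the raw deflate data, then an 8-byte trailer
# holding CRC-32 and uncompressed size (both little-endian).

.le_bytes <- function(x, n) {
  # x: non-negative double < 2^32; n bytes little-endian
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# 32-bit xor on doubles (values < 2^32)
.xor32 <- function(a, b) {
  r <- 0; m <- 1
  for (i in 1:4) {
    r <- r + bitwXor(as.integer(a %% 256), as.integer(b %% 256)) * m
    a <- a %/% 256; b <- b %/% 256; m <- m * 256
  }
  r
}

.crc32_table <- local({
  poly <- 3988292384  # 0xEDB88320
  tab <- numeric(256)
  for (n in 0:255) {
    cc <- n
    for (k in 1:8) {
      cc <- if (cc %% 2) .xor32(cc %/% 2, poly) else cc %/% 2
    }
    tab[n + 1] <- cc
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- 4294967295
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwXor(as.integer(crc %% 256), b[i])
    crc <- .xor32(crc %/% 256, .crc32_table[idx + 1])
  }
  4294967295 - crc
}

.deflate_with_crc <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")
  n <- length(z)
  if (n > 18L && z[1] == as.raw(0x1f) && z[2] == as.raw(0x8b) &&
      z[4] == as.raw(0x00)) {
    # true gzip member: 10-byte header, 8-byte trailer carrying the CRC-32
    crc <- sum(as.numeric(z[(n - 7):(n - 4)]) * 256^(0:3))
    return(list(deflate = z[11:(n - 8)], crc = crc, usize = length(bytes)))
  }
  # zlib stream (2-byte header, 4-byte Adler-32 trailer): strip the
  # framing and compute the CRC-32 ourselves
  stopifnot(n > 6L, bitwAnd(as.integer(z[1]), 0x0f) == 8L)
  list(deflate = z[3:(n - 4)], crc = .crc32(bytes), usize = length(bytes))
}

# entries: named list location -> raw vector (or character, UTF-8 encoded)
.write_zip <- function(path, entries) {
  # fixed DOS timestamp: 2023-04-01 00:00:00
  dos_time <- .le_bytes(0, 2)
  dos_date <- .le_bytes(bitwShiftL(2023L - 1980L, 9) + bitwShiftL(4L, 5) + 1L, 2)
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  metas <- vector("list", length(entries))
  offset <- 0
  for (i in seq_along(entries)) {
    name <- names(entries)[i]
    data <- entries[[i]]
    if (is.character(data)) data <- charToRaw(paste0(data, collapse = "\n"))
    z <- .deflate_with_crc(data)
    nm <- charToRaw(name)
    header <- c(.le_bytes(0x04034b50, 4), .le_bytes(20, 2), .le_bytes(0, 2),
                .le_bytes(8, 2), dos_time, dos_date, .le_bytes(z$crc, 4),
                .le_bytes(length(z$deflate), 4), .le_bytes(z$usize, 4),
                .le_bytes(length(nm), 2), .le_bytes(0, 2), nm)
    writeBin(c(header, z$deflate), con)
    offsets[i] <- offset
    metas[[i]] <- z
    offset <- offset + length(header) + length(z$deflate)
  }
  cd_start <- offset
  cd_size <- 0
  for (i in seq_along(entries)) {
    z <- metas[[i]]
    nm <- charToRaw(names(entries)[i])
    rec <- c(.le_bytes(0x02014b50, 4), .le_bytes(20, 2), .le_bytes(20, 2),
             .le_bytes(0, 2), .le_bytes(8, 2), dos_time, dos_date,
             .le_bytes(z$crc, 4), .le_bytes(length(z$deflate), 4),
             .le_bytes(z$usize, 4), .le_bytes(length(nm), 2),
             .le_bytes(0, 2), .le_bytes(0, 2), .le_bytes(0, 2),
             .le_bytes(0, 2), .le_bytes(0, 4), .le_bytes(offsets[i], 4), nm)
    writeBin(rec, con)
    cd_size <- cd_size + length(rec)
  }
  eocd <- c(.le_bytes(0x06054b50, 4), .le_bytes(0, 2), .le_bytes(0, 2),
            .le_bytes(length(entries), 2), .le_bytes(length(entries), 2),
            .le_bytes(cd_size, 4), .le_bytes(cd_start, 4), .le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

.is_zip <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  length(magic) == 4L && identical(magic, as.raw(c(0x50, 0x4b, 0x03, 0x04)))
}
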