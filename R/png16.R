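# Minimal 16-bit PNG writer (gray or RGB). The PNG stream uses stored
# (uncompressed) deflate blocks inside a zlib wrapper, which every PNG
# reader accepts; barycentric buffers need the full 16-bit depth that the
# common 8-bit writers cannot provide.

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (c %% 2 == 1) bitwXor64(3988292384, floor(c / 2))
        else floor(c / 2)
      }
      t[n + 1] <- c
    }
    tab <<- t
    tab
  }
})

crc32 <- function(bytes) {
  # table-driven CRC-32 on a raw vector, arithmetic in doubles
  tab <- crc32_table()
  c <- 2^32 - 1
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwXor(as.integer(c %% 256), b[i]) + 1
    c <- floor(c / 256)
    c <- bitwXor64(tab[idx], c)
  }
  (2^32 - 1) - c
}

bitwXor64 <- function(a, b) {
  # xor of two non-negative < 2^32 values held in doubles
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  if (hi < 0) hi <- hi + 2^32 / 65536
  hi * 65536 + lo
}

adler32 <- function(bytes) {
  b <- as.integer(bytes)
  a <- 1
  s <- 0
  # process in chunks to stay within double precision
  n <- length(b)
  i <- 1
  while (i <= n) {
    j <- min(n, i + 3800)
    seg <- b[i:j]
    a_prev <- a
    a <- (a + sum(seg)) %% 65521
    # s grows by sum of running prefixes; use cumulative sums
    s <- (s + length(seg) * a_prev + sum(cumsum(seg))) %% 65521
    i <- j + 1
  }
  s * 65536 + a
}

u32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

zlib_stored <- function(data) {
  n <- length(data)
  out <- list(as.raw(c(0x78, 0x01)))
  i <- 1
  while (i <= n || n == 0) {
    len <- min(65535, n - i + 1)
    if (len < 0) len <- 0
    final <- (i + len > n)
    header <- as.raw(c(if (final) 0x01 else 0x00,
                       len %% 256, len %/% 256,
                       255 - len %% 256, 255 - len %/% 256))
    out[[length(out) + 1]] <- header
    if (len > 0) out[[length(out) + 1]] <- data[i:(i + len - 1)]
    i <- i + len
    if (final) break
  }
  out[[length(out) + 1]] <- u32be(adler32(data))
  do.call(c, out)
}

# img: H x W (gray) or H x W x 3 array in [0, 1]
write_png16 <- function(img, path) {
  H <- dim(img)[1]
  W <- dim(img)[2]
  C <- if (length(dim(img)) == 3) dim(img)[3] else 1
  stopifnot(C %in% c(1, 3))
  v <- round(pmin(pmax(img, 0), 1) * 65535)
  # interleave samples row-major: for each row, W * C 16-bit big-endian
  if (C == 1) {
    m <- t(v)                       # W x H
    samples <- as.vector(m)         # column-major: rows of the image
  } else {
    arr <- aperm(v, c(3, 2, 1))     # C x W x H
    samples <- as.vector(arr)
  }
  hi <- as.raw(samples %/% 256)
  lo <- as.raw(samples %% 256)
  bytes <- as.vector(rbind(hi, lo))
  # one filter byte (0 = none) per scanline
  rowlen <- W * C * 2
  scan <- matrix(bytes, nrow = rowlen)
  raw_rows <- rbind(as.raw(0), scan)
  data <- as.vector(raw_rows)
  ihdr <- c(u32be(W), u32be(H), as.raw(16),
            as.raw(if (C == 1) 0 else 2), as.raw(c(0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_stored(data)),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
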