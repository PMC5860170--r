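# Minimal ZIP container writer (stored entries, CRC-32), used to emit OOXML
# packages. Entries are written uncompressed with a fixed timestamp so that
# identical content yields byte-identical archives. Reading archives back
# goes through utils::unzip(unzip = "internal") and needs nothing external.

# CRC-32 (IEEE 802.3 polynomial), table-driven over 16-bit halves so all
# intermediate values stay inside R's signed 32-bit integers.
crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(crc32_env$tlo)) {
    return(list(lo = crc32_env$tlo, hi = crc32_env$thi))
  }
  poly_lo <- 0x8320L
  poly_hi <- 0xEDB8L
  tlo <- integer(256)
  thi <- integer(256)
  for (n in 0:255) {
    lo <- n
    hi <- 0L
    for (k in 1:8) {
      odd <- lo %% 2L == 1L
      lo <- bitwOr(bitwShiftR(lo, 1L),
                   bitwShiftL(bitwAnd(hi, 1L), 15L))
      hi <- bitwShiftR(hi, 1L)
      if (odd) {
        lo <- bitwXor(lo, poly_lo)
        hi <- bitwXor(hi, poly_hi)
      }
    }
    tlo[n + 1L] <- lo
    thi[n + 1L] <- hi
  }
  crc32_env$tlo <- tlo
  crc32_env$thi <- thi
  list(lo = tlo, hi = thi)
}

# CRC-32 of a raw vector, returned as a double in [0, 2^32).
crc32 <- function(bytes) {
  tab <- crc32_table()
  tlo <- tab$lo
  thi <- tab$hi
  lo <- 0xFFFFL
  hi <- 0xFFFFL
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwXor(bitwAnd(lo, 0xFFL), b[i]) + 1L
    slo <- bitwOr(bitwShiftR(lo, 8L), bitwShiftL(bitwAnd(hi, 0xFFL), 8L))
    shi <- bitwShiftR(hi, 8L)
    lo <- bitwXor(slo, tlo[idx])
    hi <- bitwXor(shi, thi[idx])
  }
  lo <- bitwXor(lo, 0xFFFFL)
  hi <- bitwXor(hi, 0xFFFFL)
  hi * 65536 + lo
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                            endian = "little")
u32 <- function(x) {
  # accept doubles in [0, 2^32) and re-encode as signed 32-bit
  x <- as.numeric(x)
  if (x >= 2^31) x <- x - 2^32
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

# fixed DOS timestamp (2026-01-01 00:00:00) for reproducible archives
DOS_TIME <- 0L
DOS_DATE <- bitwOr(bitwOr(bitwShiftL(46L, 9L), bitwShiftL(1L, 5L)), 1L)

#' Write a ZIP archive with stored (uncompressed) entries
#'
#' @param path Output path.
#' @param entries Named list; each element is a raw vector or a character
#'   scalar (encoded as UTF-8). Names are the archive paths.
#' @return `path`, invisibly.
#' @keywords internal
zip_write <- function(path, entries) {
  stopifnot(is.list(entries), !is.null(names(entries)),
            all(nzchar(names(entries))))
  locals <- list()
  centrals <- list()
  offset <- 0
  for (name in names(entries)) {
    data <- entries[[name]]
    if (is.character(data)) data <- charToRaw(enc2utf8(data))
    stopifnot(is.raw(data))
    nm <- charToRaw(name)
    crc <- crc32(data)
    local <- c(u32(0x04034b50), u16(20L), u16(0L), u16(0L),
               u16(DOS_TIME), u16(DOS_DATE), u32(crc),
               u32(length(data)), u32(length(data)),
               u16(length(nm)), u16(0L), nm, data)
    central <- c(u32(0x02014b50), u16(20L), u16(20L), u16(0L), u16(0L),
                 u16(DOS_TIME), u16(DOS_DATE), u32(crc),
                 u32(length(data)), u32(length(data)),
                 u16(length(nm)), u16(0L), u16(0L), u16(0L), u16(0L),
                 u32(0), u32(offset), nm)
    locals[[length(locals) + 1L]] <- local
    centrals[[length(centrals) + 1L]] <- central
    offset <- offset + length(local)
  }
  cd <- do.call(c, centrals)
  eocd <- c(u32(0x06054b50), u16(0L), u16(0L),
            u16(length(entries)), u16(length(entries)),
            u32(length(cd)), u32(offset), u16(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(do.call(c, c(locals, list(cd, eocd))), con)
  invisible(path)
}

# Extract an archive written by zip_write (or any ordinary ZIP) into a
# fresh temporary directory; returns its path.
zip_extract <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  exdir <- tempfile("pptx-")
  dir.create(exdir)
  ok <- tryCatch({
    utils::unzip(path, exdir = exdir, unzip = "internal")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || length(list.files(exdir, recursive = TRUE)) == 0L) {
    stop("unreadable export: ", path, call. = FALSE)
  }
  exdir
}
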