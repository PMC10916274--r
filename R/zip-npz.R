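# Minimal ZIP writer + NumPy .npy/.npz reader-writer.
#
# Reading zip archives goes through base R's internal unzip(); writing needs a
# CRC-32 (src/crc32.c) and a raw deflate stream, which memCompress() provides
# inside its zlib wrapper (2-byte header, 4-byte Adler-32 trailer stripped).

crc32 <- function(data) {
  stopifnot(is.raw(data))
  .Call("histreg_crc32", data, PACKAGE = "histreg")
}

# little-endian unsigned integer -> raw
le_raw <- function(x, width) {
  out <- raw(width)
  x <- as.numeric(x)
  for (i in seq_len(width)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_deflate <- function(data) {
  z <- memCompress(data, type = "gzip")  # zlib stream despite the name
  z[seq.int(3L, length(z) - 4L)]
}

#' Write a ZIP archive from in-memory entries
#'
#' Entries are deflate-compressed and stamped with a fixed DOS timestamp so
#' that writing the same content twice yields byte-identical archives.
#'
#' @param path output file path.
#' @param entries named list of raw vectors; names become entry file names
#'   (forward-slash separated paths allowed).
#' @return `path`, invisibly.
#' @keywords internal
zip_write <- function(path, entries) {
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  con <- file(path, "wb")
  on.exit(close(con))
  # fixed timestamp: 2020-01-01 00:00:00 -> DOS date/time
  dos_time <- le_raw(0L, 2)
  dos_date <- le_raw(bitwOr(bitwShiftL(40L, 9), bitwOr(bitwShiftL(1L, 5), 1L)), 2)
  offsets <- integer(length(entries))
  centrals <- vector("list", length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    stopifnot(is.raw(data))
    comp <- raw_deflate(data)
    crc <- le_raw(crc32(data), 4)
    local <- c(
      charToRaw("PK\x03\x04"), le_raw(20L, 2), le_raw(0L, 2), le_raw(8L, 2),
      dos_time, dos_date, crc, le_raw(length(comp), 4), le_raw(length(data), 4),
      le_raw(length(nm), 2), le_raw(0L, 2), nm
    )
    offsets[i] <- pos
    writeBin(local, con)
    writeBin(comp, con)
    pos <- pos + length(local) + length(comp)
    centrals[[i]] <- c(
      charToRaw("PK\x01\x02"), le_raw(20L, 2), le_raw(20L, 2), le_raw(0L, 2),
      le_raw(8L, 2), dos_time, dos_date, crc, le_raw(length(comp), 4),
      le_raw(length(data), 4), le_raw(length(nm), 2), le_raw(0L, 2),
      le_raw(0L, 2), le_raw(0L, 2), le_raw(0L, 2), le_raw(0L, 4),
      le_raw(offsets[i], 4), nm
    )
  }
  cd <- do.call(c, centrals)
  writeBin(cd, con)
  end <- c(
    charToRaw("PK\x05\x06"), le_raw(0L, 2), le_raw(0L, 2),
    le_raw(length(entries), 2), le_raw(length(entries), 2),
    le_raw(length(cd), 4), le_raw(pos, 4), le_raw(0L, 2)
  )
  writeBin(end, con)
  invisible(path)
}

zip_read_entries <- function(path) {
  listing <- utils::unzip(path, list = TRUE)
  tmp <- tempfile("zipx")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, exdir = tmp)
  out <- lapply(listing$Name, function(nm) {
    f <- file.path(tmp, nm)
    readBin(f, "raw", n = file.size(f))
  })
  names(out) <- listing$Name
  out
}

# ---- npy ----

npy_dtype_info <- function(descr) {
  switch(descr,
    "|u1" = , "<u1" = list(what = "integer", size = 1L, signed = FALSE),
    "|i1" = , "<i1" = list(what = "integer", size = 1L, signed = TRUE),
    "<u2" = list(what = "integer", size = 2L, signed = FALSE),
    "<i2" = list(what = "integer", size = 2L, signed = TRUE),
    "<i4" = list(what = "integer", size = 4L, signed = TRUE),
    "<u4" = list(what = "u4", size = 4L, signed = FALSE),
    "<i8" = list(what = "i8", size = 8L, signed = TRUE),
    "<f4" = list(what = "double", size = 4L, signed = TRUE),
    "<f8" = list(what = "double", size = 8L, signed = TRUE),
    "|b1" = list(what = "logical", size = 1L, signed = FALSE),
    stop(sprintf("unsupported npy dtype '%s'", descr), call. = FALSE)
  )
}

npy_parse <- function(data) {
  if (length(data) < 10 || !identical(data[1:6], c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an npy stream (bad magic)", call. = FALSE)
  major <- as.integer(data[7])
  hlen_width <- if (major >= 2) 4L else 2L
  hlen <- sum(as.integer(data[9:(8 + hlen_width)]) * 256^(seq_len(hlen_width) - 1))
  header <- rawToChar(data[(9 + hlen_width):(8 + hlen_width + hlen)])
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  info <- npy_dtype_info(descr)
  body <- data[-seq_len(8 + hlen_width + hlen)]
  n <- if (length(shape)) prod(shape) else 1L
  vals <- switch(info$what,
    integer = readBin(body, "integer", n = n, size = info$size,
                      signed = info$signed, endian = "little"),
    double = readBin(body, "double", n = n, size = info$size, endian = "little"),
    logical = as.integer(readBin(body, "integer", n = n, size = 1L, signed = FALSE)),
    u4 = {
      # two uint16 halves avoid signed 32-bit overflow
      m <- matrix(readBin(body, "integer", n = 2L * n, size = 2L, signed = FALSE,
                          endian = "little"), nrow = 2L)
      m[1, ] + 65536 * m[2, ]
    },
    i8 = {
      m <- matrix(readBin(body, "integer", n = 2L * n, size = 4L, endian = "little"),
                  nrow = 2L)
      lo <- ifelse(m[1, ] < 0, m[1, ] + 2^32, m[1, ])
      lo + 2^32 * m[2, ]
    }
  )
  if (length(shape) <= 1L) return(as.vector(vals))
  if (fortran) {
    array(vals, dim = shape)
  } else {
    aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
  }
}

npy_build <- function(x) {
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  if (is.logical(x)) x <- as.integer(x)
  if (is.integer(x)) {
    descr <- "<i4"; size <- 4L
  } else {
    descr <- "<f8"; size <- 8L
  }
  shape <- paste0("(", paste(dims, collapse = ", "),
                  if (length(dims) == 1L) ",", ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  # pad so that total header (10 + len) is a multiple of 64, newline-terminated
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  vals <- if (length(dims) > 1L) as.vector(aperm(x, rev(seq_along(dims)))) else as.vector(x)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(1L), as.raw(0L)), con)
  writeBin(le_raw(nchar(header), 2), con)
  writeBin(charToRaw(header), con)
  writeBin(vals, con, size = size, endian = "little")
  rawConnectionValue(con)
}

#' Read a compressed multichannel array archive (.npz)
#'
#' @param path path to an `.npz` archive.
#' @return named list of arrays (one per archive entry, `.npy` suffix dropped).
#' @export
read_npz <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  entries <- tryCatch(zip_read_entries(path),
                      error = function(e) stop("not a readable npz archive: ",
                                               conditionMessage(e), call. = FALSE))
  if (!length(entries)) stop("empty npz archive", call. = FALSE)
  out <- lapply(entries, npy_parse)
  names(out) <- sub("\\.npy$", "", names(entries))
  out
}

#' Write arrays to a compressed .npz archive
#'
#' @param path output path.
#' @param ... named arrays, or a single named list of arrays.
#' @return `path`, invisibly.
#' @export
write_npz <- function(path, ...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.null(names(args[[1]])) &&
      !is.numeric(args[[1]]))
    args <- args[[1]]
  if (is.null(names(args)) || any(names(args) == ""))
    names(args) <- paste0("arr_", seq_along(args) - 1L)
  entries <- lapply(args, npy_build)
  names(entries) <- paste0(names(args), ".npy")
  zip_write(path, entries)
}
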