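## Minimal MAT-file v5 reader/writer.
##
## Supports the subset needed for session containers: real numeric arrays
## (any dimensionality, stored as double), character row vectors, cell
## arrays of strings, and (nested) 1x1 structs. Elements are written
## uncompressed; the reader handles both long and small data-element tags
## and either byte order, but rejects miCOMPRESSED elements.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L; MI_UTF16 <- 17L

MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L
MX_SINGLE <- 7L; MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L
MX_UINT16 <- 11L; MX_INT32 <- 12L; MX_UINT32 <- 13L

## ---- writer -----------------------------------------------------------

raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

raw_pad8 <- function(r) {
  extra <- length(r) %% 8L
  if (extra) c(r, raw(8L - extra)) else r
}

## tag + data, padded to an 8-byte boundary (always long-format tags)
mat5_subelement <- function(type, data_raw) {
  c(raw_u32(type), raw_u32(length(data_raw)), raw_pad8(data_raw))
}

mat5_flags <- function(class_id) {
  mat5_subelement(MI_UINT32, c(raw_u32(class_id), raw_u32(0L)))
}

mat5_dims <- function(dims) {
  mat5_subelement(MI_INT32, writeBin(as.integer(dims), raw(), size = 4L,
                                     endian = "little"))
}

mat5_name <- function(name) {
  mat5_subelement(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0))
}

## `x` is numeric array / character scalar / mat_cellstr / named list (struct)
mat5_array_raw <- function(x, name) {
  body <-
    if (is.character(x) && length(x) == 1L && !inherits(x, "mat_cellstr")) {
      codes <- utf8ToInt(x)
      dat <- writeBin(as.integer(codes), raw(), size = 2L, endian = "little")
      c(mat5_flags(MX_CHAR), mat5_dims(c(1L, length(codes))), mat5_name(name),
        mat5_subelement(MI_UINT16, dat))
    } else if (inherits(x, "mat_cellstr")) {
      cells <- lapply(unclass(x), mat5_array_raw, name = "")
      c(mat5_flags(MX_CELL), mat5_dims(c(1L, length(cells))), mat5_name(name),
        do.call(c, c(list(raw(0)), cells)))
    } else if (is.list(x)) {
      fnames <- names(x)
      if (is.null(fnames) || any(!nzchar(fnames)))
        structural_error("struct fields must be named")
      nmraw <- do.call(c, lapply(fnames, function(f) {
        b <- charToRaw(f)
        if (length(b) > 31L) structural_error("struct field name too long")
        c(b, raw(32L - length(b)))
      }))
      fields <- lapply(x, mat5_array_raw, name = "")
      c(mat5_flags(MX_STRUCT), mat5_dims(c(1L, 1L)), mat5_name(name),
        mat5_subelement(MI_INT32, raw_u32(32L)),
        mat5_subelement(MI_INT8, nmraw),
        do.call(c, c(list(raw(0)), fields)))
    } else if (is.numeric(x)) {
      dims <- dim(x) %||% c(1L, length(x))
      if (length(dims) == 1L) dims <- c(1L, dims)
      dat <- writeBin(as.double(x), raw(), size = 8L, endian = "little")
      c(mat5_flags(MX_DOUBLE), mat5_dims(dims), mat5_name(name),
        mat5_subelement(MI_DOUBLE, dat))
    } else {
      structural_error(sprintf("cannot store object of class '%s' in MAT file",
                               class(x)[1L]))
    }
  c(raw_u32(MI_MATRIX), raw_u32(length(body)), body)
}

#' @noRd
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)))
  hdr_txt <- sprintf("MATLAB 5.0 MAT-file, created by emgpr %s",
                     as.character(packageVersion("emgpr")))
  hdr <- charToRaw(hdr_txt)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  hdr <- c(hdr, raw(8L),                                  # subsystem offset
           writeBin(256L, raw(), size = 2L, endian = "little"),  # version 0x0100
           charToRaw("IM"))                               # little-endian marker
  body <- do.call(c, lapply(names(vars), function(nm)
    mat5_array_raw(vars[[nm]], nm)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(body, con)
  invisible(path)
}

## ---- reader -----------------------------------------------------------

mat5_read_numeric <- function(raw, type, endian) {
  switch(as.character(type),
    "1"  = as.double(readBin(raw, "integer", length(raw), 1L, TRUE,  endian)),
    "2"  = as.double(readBin(raw, "integer", length(raw), 1L, FALSE, endian)),
    "3"  = as.double(readBin(raw, "integer", length(raw) / 2L, 2L, TRUE,  endian)),
    "4"  = as.double(readBin(raw, "integer", length(raw) / 2L, 2L, FALSE, endian)),
    "5"  = as.double(readBin(raw, "integer", length(raw) / 4L, 4L, TRUE,  endian)),
    "6"  = as.double(readBin(raw, "integer", length(raw) / 4L, 4L, TRUE,  endian)),
    "7"  = readBin(raw, "double", length(raw) / 4L, 4L, endian = endian),
    "9"  = readBin(raw, "double", length(raw) / 8L, 8L, endian = endian),
    "12" = as.double(readBin(raw, "double", length(raw) / 8L, 8L, endian = endian)),
    "13" = as.double(readBin(raw, "double", length(raw) / 8L, 8L, endian = endian)),
    structural_error(sprintf("unsupported MAT data type %d", type)))
}

## read one data element starting at `pos` (1-based); returns value + next pos
mat5_read_element <- function(buf, pos, endian) {
  v <- readBin(buf[pos:(pos + 3L)], "integer", 1L, 4L, TRUE, endian)
  small_nbytes <- v %/% 65536L
  if (small_nbytes > 0L) {          # small data element format
    type <- v %% 65536L
    nbytes <- small_nbytes
    data <- if (nbytes) buf[(pos + 4L):(pos + 3L + nbytes)] else raw(0)
    nxt <- pos + 8L
  } else {
    type <- v
    nbytes <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", 1L, 4L, TRUE, endian)
    data <- if (nbytes) buf[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    nxt <- pos + 8L + nbytes
    if (nxt %% 8L != 1L) nxt <- nxt + (8L - (nxt - 1L) %% 8L)
  }
  if (type == MI_COMPRESSED)
    structural_error("compressed MAT elements are not supported; write the file uncompressed")
  list(type = type, data = data, next_pos = nxt)
}

mat5_parse_matrix <- function(data, endian) {
  pos <- 1L
  flags <- mat5_read_element(data, pos, endian); pos <- flags$next_pos
  class_id <- readBin(flags$data[1:4], "integer", 1L, 4L, TRUE, endian) %% 256L
  dims_el <- mat5_read_element(data, pos, endian); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4L, 4L,
                  TRUE, endian)
  name_el <- mat5_read_element(data, pos, endian); pos <- name_el$next_pos
  name <- if (length(name_el$data)) rawToChar(name_el$data) else ""

  value <-
    if (class_id == MX_CHAR) {
      el <- mat5_read_element(data, pos, endian)
      if (el$type == MI_UTF8) rawToChar(el$data)
      else intToUtf8(mat5_read_numeric(el$data, MI_UINT16, endian))
    } else if (class_id == MX_CELL) {
      n <- prod(dims)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        el <- mat5_read_element(data, pos, endian); pos <- el$next_pos
        out[[i]] <- mat5_parse_matrix(el$data, endian)$value
      }
      if (all(vapply(out, is.character, logical(1L)))) unlist(out) else out
    } else if (class_id == MX_STRUCT) {
      fl <- mat5_read_element(data, pos, endian); pos <- fl$next_pos
      flen <- readBin(fl$data, "integer", 1L, 4L, TRUE, endian)
      nm <- mat5_read_element(data, pos, endian); pos <- nm$next_pos
      nf <- length(nm$data) %/% flen
      fnames <- vapply(seq_len(nf), function(i) {
        b <- nm$data[((i - 1L) * flen + 1L):(i * flen)]
        rawToChar(b[b != as.raw(0)])
      }, character(1L))
      out <- setNames(vector("list", nf), fnames)
      for (i in seq_len(nf)) {
        el <- mat5_read_element(data, pos, endian); pos <- el$next_pos
        out[[i]] <- mat5_parse_matrix(el$data, endian)$value
      }
      out
    } else if (class_id %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8,
                               MX_INT16, MX_UINT16, MX_INT32, MX_UINT32)) {
      el <- mat5_read_element(data, pos, endian)
      x <- mat5_read_numeric(el$data, el$type, endian)
      if (length(dims) > 2L) array(x, dims)
      else if (all(dims == 1L)) x
      else matrix(x, dims[1L], dims[2L])
    } else {
      structural_error(sprintf("unsupported MAT array class %d", class_id))
    }
  list(name = name, value = value)
}

#' @noRd
read_mat5 <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 128L) structural_error("file too short to be a MAT-file v5")
  marker <- rawToChar(buf[127:128])
  endian <- if (marker == "IM") "little" else if (marker == "MI") "big" else
    structural_error("not a MAT-file v5 (bad endian marker)")
  pos <- 129L
  out <- list()
  while (pos <= length(buf)) {
    el <- mat5_read_element(buf, pos, endian)
    pos <- el$next_pos
    if (el$type != MI_MATRIX)
      structural_error(sprintf("unexpected top-level MAT element type %d", el$type))
    parsed <- mat5_parse_matrix(el$data, endian)
    out[[parsed$name]] <- parsed$value
  }
  out
}

mat_cellstr <- function(x) structure(as.list(as.character(x)), class = "mat_cellstr")
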