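# Minimal MAT v5 (Level 5 MAT-file) reader/writer.
#
# Covers what the DCE analysis contract needs: full numeric arrays
# (written as double, read from any integer/float type), character
# vectors, and logical arrays (written as double 0/1). Cell arrays,
# structs, sparse and complex arrays are out of scope. Written files are
# plain little-endian; the reader additionally understands the small
# data element format and zlib-compressed (miCOMPRESSED) elements.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L
MI_COMPRESSED <- 15L; MI_UTF8 <- 16L; MI_UTF16 <- 17L
MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

pad8 <- function(n) (8L - n %% 8L) %% 8L

mat5_element <- function(type, payload) {
  c(writeBin(as.integer(c(type, length(payload))), raw(), size = 4L,
             endian = "little"),
    payload, raw(pad8(length(payload))))
}

mat5_matrix_raw <- function(name, value) {
  if (is.character(value)) {
    s <- paste(value, collapse = "")
    codes <- utf8ToInt(s)
    dims <- c(1L, length(codes))
    cls <- MX_CHAR
    datapay <- writeBin(as.integer(codes), raw(), size = 2L,
                        endian = "little")
    datatype <- MI_UINT16
  } else {
    value <- if (is.logical(value)) array(as.numeric(value),
                                          dim = dim2(value)) else value
    dims <- dim(value)
    if (is.null(dims)) dims <- c(1L, length(value))
    if (length(dims) == 1L) dims <- c(1L, dims)
    cls <- MX_DOUBLE
    datapay <- writeBin(as.numeric(value), raw(), size = 8L,
                        endian = "little")
    datatype <- MI_DOUBLE
  }
  flags <- writeBin(as.integer(c(cls, 0L)), raw(), size = 4L,
                    endian = "little")
  payload <- c(
    mat5_element(MI_UINT32, flags),
    mat5_element(MI_INT32,
                 writeBin(as.integer(dims), raw(), size = 4L,
                          endian = "little")),
    mat5_element(MI_INT8, charToRaw(name)),
    mat5_element(datatype, datapay))
  mat5_element(MI_MATRIX, payload)
}

#' Write variables to a MAT v5 file
#'
#' Writes a named list of numeric/logical arrays and character strings to
#' a Level 5 MAT-file readable by MATLAB, Octave, scipy.io and this
#' package's [read_mat5()]. Numeric data are stored as double, logicals
#' as double 0/1; array dimensions are preserved (vectors become 1 x n
#' row vectors).
#'
#' @param vars Named list of variables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  if (is.null(names(vars)) || any(!nzchar(names(vars))))
    stop("all variables must be named", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- sprintf("MATLAB 5.0 MAT-file, created by dcefit on %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  htxt <- charToRaw(header)
  htxt <- c(htxt, rep(as.raw(0x20), 116L - length(htxt)))
  writeBin(htxt, con)
  writeBin(raw(8L), con)                                   # subsys offset
  writeBin(as.integer(0x0100), con, size = 2L, endian = "little")
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars))
    writeBin(mat5_matrix_raw(nm, vars[[nm]]), con)
  invisible(path)
}

mat5_read_num <- function(buf, type, nbytes, off, swap) {
  endian <- if (swap) "big" else "little"
  slice <- buf[off + seq_len(nbytes)]
  switch(as.character(type),
    "1" = as.numeric(readBin(slice, "integer", nbytes, 1L, TRUE, endian)),
    "2" = as.numeric(readBin(slice, "integer", nbytes, 1L, FALSE, endian)),
    "3" = as.numeric(readBin(slice, "integer", nbytes / 2L, 2L, TRUE, endian)),
    "4" = as.numeric(readBin(slice, "integer", nbytes / 2L, 2L, FALSE, endian)),
    "5" = as.numeric(readBin(slice, "integer", nbytes / 4L, 4L, TRUE, endian)),
    "6" = {
      v <- readBin(slice, "integer", nbytes / 4L, 4L, TRUE, endian)
      ifelse(v < 0, v + 2^32, v)
    },
    "7" = readBin(slice, "double", nbytes / 4L, 4L, endian = endian),
    "9" = readBin(slice, "double", nbytes / 8L, 8L, endian = endian),
    stop("unsupported MAT data type ", type, call. = FALSE))
}

# parse one tag at offset; returns list(type, nbytes, data_off, next_off)
mat5_tag <- function(buf, off, swap) {
  endian <- if (swap) "big" else "little"
  t1 <- readBin(buf[off + 1:4], "integer", 1L, 4L, endian = endian)
  small <- bitwAnd(bitwShiftR(t1, 16L), 0xFFFFL)
  if (small != 0L) {
    list(type = bitwAnd(t1, 0xFFFFL), nbytes = small,
         data_off = off + 4L, next_off = off + 8L)
  } else {
    nb <- readBin(buf[off + 5:8], "integer", 1L, 4L, endian = endian)
    list(type = t1, nbytes = nb, data_off = off + 8L,
         next_off = off + 8L + nb + pad8(nb))
  }
}

mat5_parse_matrix <- function(buf, off, end, swap) {
  tg <- mat5_tag(buf, off, swap)                     # array flags
  flags <- mat5_read_num(buf, MI_UINT32, 8L, tg$data_off, swap)
  cls <- bitwAnd(as.integer(flags[1L]), 0xFFL)
  tg2 <- mat5_tag(buf, tg$next_off, swap)            # dimensions
  dims <- as.integer(mat5_read_num(buf, MI_INT32, tg2$nbytes,
                                   tg2$data_off, swap))
  tg3 <- mat5_tag(buf, tg2$next_off, swap)           # name
  name <- rawToChar(buf[tg3$data_off + seq_len(tg3$nbytes)])
  tg4 <- mat5_tag(buf, tg3$next_off, swap)           # real part
  if (cls == MX_CHAR) {
    value <- if (tg4$type == MI_UTF8)
      rawToChar(buf[tg4$data_off + seq_len(tg4$nbytes)])
    else intToUtf8(mat5_read_num(buf, MI_UINT16, tg4$nbytes,
                                 tg4$data_off, swap))
  } else if (cls %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                        MX_UINT16, MX_INT32, MX_UINT32)) {
    value <- mat5_read_num(buf, tg4$type, tg4$nbytes, tg4$data_off, swap)
    logical_flag <- bitwAnd(bitwShiftR(as.integer(flags[1L]), 8L), 0x02L)
    if (logical_flag != 0L) value <- value != 0
    value <- if (length(dims) > 2L || all(dims > 1L))
      array(value, dim = dims) else as.vector(value)
  } else {
    stop("unsupported MAT array class ", cls, " for variable '", name, "'",
         call. = FALSE)
  }
  list(name = name, value = value)
}

#' Read a MAT v5 file
#'
#' Reads full numeric, logical and character arrays from a Level 5
#' MAT-file (little- or big-endian, plain or zlib-compressed elements).
#' Numeric data are returned as double; 1 x n / n x 1 arrays are
#' simplified to plain vectors; higher-dimensional arrays keep their
#' dimensions (MATLAB and R share column-major order).
#'
#' @param path Path to a MAT v5 file.
#' @return Named list of variables.
#' @export
read_mat5 <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 128L) stop("not a MAT v5 file (too short)", call. = FALSE)
  endmark <- rawToChar(buf[127:128])
  if (!endmark %in% c("IM", "MI"))
    stop("not a MAT v5 file (bad endian indicator)", call. = FALSE)
  swap <- endmark == "MI"
  out <- list()
  off <- 128L
  while (off + 8L <= length(buf)) {
    tg <- mat5_tag(buf, off, swap)
    if (tg$type == MI_COMPRESSED) {
      comp <- buf[tg$data_off + seq_len(tg$nbytes)]
      inner <- tryCatch(
        memDecompress(comp, type = "gzip"),
        error = function(e)
          stop("failed to decompress MAT element: ", conditionMessage(e),
               call. = FALSE))
      itg <- mat5_tag(inner, 0L, swap)
      if (itg$type == MI_MATRIX) {
        v <- mat5_parse_matrix(inner, itg$data_off, itg$next_off, swap)
        out[[v$name]] <- v$value
      }
    } else if (tg$type == MI_MATRIX) {
      v <- mat5_parse_matrix(buf, tg$data_off, tg$next_off, swap)
      out[[v$name]] <- v$value
    }
    off <- tg$next_off
  }
  out
}
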