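# Minimal single-frame DICOM reader/writer (little endian, explicit or
# implicit VR) covering the tags a dynamic phantom series needs: instance
# number, timing, TR, flip angle, image geometry and unencapsulated
# integer pixel data. Sequences are skipped. The writer emits explicit VR
# little endian and exists for phantom export and for building test
# fixtures in code.

dcm_tags <- list(
  acq_time = c(0x0008L, 0x0032L),
  te_ms = c(0x0018L, 0x0081L),
  tr_ms = c(0x0018L, 0x0080L),
  flip_deg = c(0x0018L, 0x1314L),
  instance = c(0x0020L, 0x0013L),
  rows = c(0x0028L, 0x0010L),
  cols = c(0x0028L, 0x0011L),
  bits = c(0x0028L, 0x0100L),
  pixrep = c(0x0028L, 0x0103L),
  intercept = c(0x0028L, 0x1052L),
  slope = c(0x0028L, 0x1053L),
  pixel = c(0x7FE0L, 0x0010L))

#' Read a single DICOM file
#'
#' Parses one little-endian DICOM part-10 file (explicit or implicit VR;
#' headerless streams are accepted too) and returns the acquisition tags
#' relevant to dynamic phantom series plus the pixel matrix. Rescale
#' slope/intercept are applied when present.
#'
#' @param path Path to a DICOM file.
#' @return List with `instance`, `acq_time_s`, `tr_ms`, `flip_deg`,
#'   `te_ms` (NA when absent) and `pixels` (numeric rows x cols matrix).
#' @export
read_dicom <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  off <- 0L
  explicit <- TRUE
  if (length(buf) > 132L && rawToChar(buf[129:132]) == "DICM") off <- 132L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  found <- list()
  ts_uid <- NULL
  u16 <- function(o) readBin(buf[o + 1:2], "integer", 1L, 2L, FALSE,
                             "little")
  u32 <- function(o) readBin(buf[o + 1:4], "integer", 1L, 4L, TRUE,
                             "little")
  # sniff implicit vs explicit on the first dataset element later
  sniffed <- FALSE
  while (off + 8L <= length(buf)) {
    group <- u16(off); elem <- u16(off + 2L)
    in_meta <- group == 0x0002L
    if (!in_meta && !sniffed) {
      vr_try <- rawToChar(buf[off + 5:6])
      explicit <- grepl("^[A-Z]{2}$", vr_try)
      if (!is.null(ts_uid)) {
        if (ts_uid == "1.2.840.10008.1.2") explicit <- FALSE
        else if (ts_uid == "1.2.840.10008.1.2.1") explicit <- TRUE
        else if (!ts_uid %in% c("1.2.840.10008.1.2",
                                "1.2.840.10008.1.2.1"))
          stop("unsupported DICOM transfer syntax ", ts_uid, call. = FALSE)
      }
      sniffed <- TRUE
    }
    if (in_meta || explicit) {
      vr <- rawToChar(buf[off + 5:6])
      if (vr %in% long_vrs) {
        len <- u32(off + 8L); data_off <- off + 12L
      } else {
        len <- u16(off + 6L); data_off <- off + 8L
      }
    } else {
      vr <- ""
      len <- u32(off + 4L); data_off <- off + 8L
    }
    if (!is.na(len) && len == -1L) {             # undefined length: skip SQ
      off <- skip_undefined(buf, data_off)
      next
    }
    val_raw <- buf[data_off + seq_len(len)]
    key <- match_tag(group, elem)
    if (group == 0x0002L && elem == 0x0010L)
      ts_uid <- sub("\\x00+$", "", rawToChar(val_raw))
    if (!is.null(key)) {
      found[[key]] <- list(vr = vr, raw = val_raw)
      if (key == "pixel") break
    }
    off <- data_off + len
  }
  get_num <- function(key, default = NA_real_) {
    f <- found[[key]]
    if (is.null(f)) return(default)
    if (f$vr %in% c("US", "") && length(f$raw) == 2L)
      return(as.numeric(readBin(f$raw, "integer", 1L, 2L, FALSE, "little")))
    if (length(f$raw) %in% c(2L, 4L) && f$vr %in% c("US", "UL", "SS", "SL"))
      return(as.numeric(readBin(f$raw, "integer", 1L,
                                length(f$raw), f$vr %in% c("SS", "SL"),
                                "little")))
    txt <- trimws(gsub("\\x00", "", rawToChar(f$raw)))
    suppressWarnings(as.numeric(txt))
  }
  get_txt <- function(key) {
    f <- found[[key]]
    if (is.null(f)) return(NA_character_)
    trimws(gsub("\\x00", "", rawToChar(f$raw)))
  }
  rows <- as.integer(get_num("rows")); cols <- as.integer(get_num("cols"))
  if (is.na(rows) || is.na(cols) || is.null(found$pixel))
    stop("DICOM file lacks image geometry or pixel data: ", path,
         call. = FALSE)
  bits <- get_num("bits", 16)
  signed <- isTRUE(get_num("pixrep", 0) == 1)
  px <- readBin(found$pixel$raw, "integer", rows * cols,
                size = bits / 8, signed = if (bits == 8) signed else signed,
                endian = "little")
  if (!signed && bits == 16) px <- ifelse(px < 0, px + 65536, px)
  slope <- get_num("slope", 1); inter <- get_num("intercept", 0)
  pixels <- t(matrix(px * slope + inter, nrow = cols, ncol = rows))
  acq_time <- get_txt("acq_time")
  acq_time_s <- if (is.na(acq_time) || !nzchar(acq_time)) NA_real_ else {
    h <- as.numeric(substr(acq_time, 1, 2))
    m <- as.numeric(substr(acq_time, 3, 4))
    s <- as.numeric(substring(acq_time, 5))
    h * 3600 + m * 60 + ifelse(is.na(s), 0, s)
  }
  list(instance = as.integer(get_num("instance")),
       acq_time_s = acq_time_s,
       tr_ms = get_num("tr_ms"), flip_deg = get_num("flip_deg"),
       te_ms = get_num("te_ms"), pixels = pixels)
}

match_tag <- function(group, elem) {
  for (nm in names(dcm_tags)) {
    tg <- dcm_tags[[nm]]
    if (group == tg[1L] && elem == tg[2L]) return(nm)
  }
  NULL
}

skip_undefined <- function(buf, off) {
  # scan for the sequence delimitation item (FFFE, E0DD), length 0
  u16 <- function(o) readBin(buf[o + 1:2], "integer", 1L, 2L, FALSE,
                             "little")
  while (off + 8L <= length(buf)) {
    if (u16(off) == 0xFFFEL && u16(off + 2L) == 0xE0DDL)
      return(off + 8L)
    off <- off + 2L
  }
  length(buf)
}

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, if (vr %in% c("UI")) as.raw(0)
                   else charToRaw(" "))
  head <- writeBin(as.integer(c(group, elem)), raw(), size = 2L,
                   endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, charToRaw(vr), raw(2L),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(as.integer(length(value_raw)), raw(), size = 2L,
               endian = "little"),
      value_raw)
  }
}

dcm_str <- function(x) charToRaw(as.character(x))
dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                               endian = "little")

#' Write a single-frame DICOM file
#'
#' Emits an explicit VR little endian part-10 file with the minimal tag
#' set used by [read_dicom()] / [load_qiba_dicom()]: timing, TR, flip
#' angle, instance number, geometry, and 16-bit unsigned pixel data.
#' Pixel values are rounded and clipped to \[0, 65535\].
#'
#' @param pixels Numeric rows x cols matrix.
#' @param path Output path.
#' @param instance Instance number (order in the time series).
#' @param tr_ms Repetition time in ms.
#' @param flip_deg Flip angle in degrees.
#' @param te_ms Echo time in ms.
#' @param acq_time_s Acquisition clock time in seconds of day, written as
#'   a TM tag when not NA.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, instance, tr_ms = 5, flip_deg = 30,
                        te_ms = 1.3, acq_time_s = NA) {
  stopifnot(is.matrix(pixels))
  px <- pmin(pmax(round(as.vector(t(pixels))), 0), 65535)
  px[px > 32767] <- px[px > 32767] - 65536     # two's complement for writeBin
  body <- c(
    if (!is.na(acq_time_s)) {
      h <- floor(acq_time_s / 3600)
      m <- floor((acq_time_s - 3600 * h) / 60)
      s <- acq_time_s - 3600 * h - 60 * m
      dcm_element(0x0008L, 0x0032L, "TM",
                  dcm_str(sprintf("%02d%02d%09.6f", h, m, s)))
    },
    dcm_element(0x0018L, 0x0080L, "DS", dcm_str(format(tr_ms))),
    dcm_element(0x0018L, 0x0081L, "DS", dcm_str(format(te_ms))),
    dcm_element(0x0018L, 0x1314L, "DS", dcm_str(format(flip_deg))),
    dcm_element(0x0020L, 0x0013L, "IS", dcm_str(instance)),
    dcm_element(0x0028L, 0x0010L, "US", dcm_us(nrow(pixels))),
    dcm_element(0x0028L, 0x0011L, "US", dcm_us(ncol(pixels))),
    dcm_element(0x0028L, 0x0100L, "US", dcm_us(16L)),
    dcm_element(0x0028L, 0x0101L, "US", dcm_us(16L)),
    dcm_element(0x0028L, 0x0102L, "US", dcm_us(15L)),
    dcm_element(0x0028L, 0x0103L, "US", dcm_us(0L)),
    dcm_element(0x7FE0L, 0x0010L, "OW",
                writeBin(as.integer(px), raw(), size = 2L,
                         endian = "little")))
  ts <- c(charToRaw("1.2.840.10008.1.2.1"), as.raw(0))
  meta <- dcm_element(0x0002L, 0x0010L, "UI", ts)
  meta <- c(dcm_element(0x0002L, 0x0000L, "UL",
                        writeBin(length(meta), raw(), size = 4L,
                                 endian = "little")),
            meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

#' Export a phantom as a DICOM series
#'
#' Writes one DICOM file per dynamic of a generated phantom (instance
#' numbers 1..n, acquisition-time tags from the time vector), producing a
#' directory that [load_qiba_dicom()] / [load_qiba_phantom()] can read
#' back. Useful for exercising the DICOM validation path without
#' downloaded data; the result is a synthetic stand-in, not a real
#' reference object.
#'
#' @param phantom A `dce_phantom` from [generate_phantom()].
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
export_phantom_dicom <- function(phantom, directory) {
  stopifnot(inherits(phantom, "dce_phantom"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$spec
  n <- phantom$series$n_time
  for (i in seq_len(n)) {
    frame <- phantom$series$data[i, , ]
    write_dicom(frame,
                file.path(directory, sprintf("frame_%05d.dcm", i)),
                instance = i, tr_ms = sp$acq$tr * 1000,
                flip_deg = sp$acq$flip_deg,
                acq_time_s = 3600 + phantom$series$t[i])
  }
  invisible(directory)
}

#' Load a dynamic DICOM series
#'
#' Reads every DICOM file in a directory, orders the frames by instance
#' number, and assembles a time-first [dynamic_series()] plus the
#' acquisition parameters from the headers. The time vector comes from
#' the acquisition-time tags when they are present and distinct,
#' otherwise from a uniform `dt` fallback. Missing or duplicate instance
#' numbers are an error (the gaps are listed).
#'
#' @param directory Directory containing a single-series DICOM stack.
#' @param dt Fallback frame spacing in seconds, default 0.5.
#' @param pattern Filename filter, default all files.
#' @return List with `series` ([dynamic_series()]) and `acq`
#'   ([acq_params()]).
#' @export
load_qiba_dicom <- function(directory, dt = 0.5, pattern = NULL) {
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 1L)
    stop("no DICOM files found in ", directory, call. = FALSE)
  frames <- lapply(files, read_dicom)
  inst <- vapply(frames, `[[`, integer(1), "instance")
  if (anyNA(inst)) stop("DICOM frames without instance numbers",
                        call. = FALSE)
  if (anyDuplicated(inst))
    stop("duplicate instance numbers: ",
         paste(unique(inst[duplicated(inst)]), collapse = ", "),
         call. = FALSE)
  expected <- seq(min(inst), max(inst))
  if (!setequal(inst, expected))
    stop("missing instance numbers: ",
         paste(setdiff(expected, inst), collapse = ", "), call. = FALSE)
  ord <- order(inst)
  frames <- frames[ord]
  at <- vapply(frames, `[[`, numeric(1), "acq_time_s")
  n <- length(frames)
  t_s <- if (!anyNA(at) && length(unique(at)) == n) at - at[1L]
         else (seq_len(n) - 1L) * dt
  pix <- vapply(frames, function(f) f$pixels,
                matrix(0, nrow(frames[[1L]]$pixels),
                       ncol(frames[[1L]]$pixels)))
  data <- aperm(pix, c(3L, 1L, 2L))
  tr_ms <- frames[[1L]]$tr_ms
  flip <- frames[[1L]]$flip_deg
  acq <- acq_params(tr = ifelse(is.na(tr_ms), 5, tr_ms) / 1000,
                    flip_deg = ifelse(is.na(flip), 30, flip),
                    te = frames[[1L]]$te_ms / 1000)
  list(series = dynamic_series(t_s, data), acq = acq)
}

#' Load a QIBA-layout DICOM phantom as a validation phantom
#'
#' Wraps [load_qiba_dicom()] into a `dce_phantom` usable by
#' [run_validation()]: the DICOM stack supplies the signal and
#' acquisition parameters, while the parameter grids, patch geometry and
#' vessel-strip location come from `spec` (defaults: the QIBA layout for
#' the chosen `layout`, vessel strip at the bottom of the image).
#'
#' @param directory DICOM directory.
#' @param layout `"standard"` (v6-style) or `"extended"` (v4-style).
#' @param spec Optional [phantom_spec()] overriding the layout defaults;
#'   geometry/grid fields are used, acquisition comes from the headers.
#' @param tissue_origin Row/col offset (0-based) of the first patch,
#'   default `c(0, 0)`.
#' @param dt Fallback frame spacing for the time vector.
#' @return A `dce_phantom`.
#' @export
load_qiba_phantom <- function(directory, layout = c("standard", "extended"),
                              spec = NULL, tissue_origin = c(0L, 0L),
                              dt = 0.5) {
  layout <- match.arg(layout)
  loaded <- load_qiba_dicom(directory, dt = dt)
  if (is.null(spec)) spec <- phantom_spec(layout)
  spec$acq <- loaded$acq
  spec$n_time <- loaded$series$n_time
  spec$dt <- if (loaded$series$n_time > 1L) diff(loaded$series$t)[1L] else dt
  regions <- phantom_regions(spec)
  d <- dim(loaded$series$data)
  h <- d[2L]; w <- d[3L]
  pr <- spec$patch_shape[1L]; pc <- spec$patch_shape[2L]
  region_map <- matrix(NA_integer_, h, w)
  for (i in seq_len(nrow(regions))) {
    rows <- tissue_origin[1L] + (regions$patch_row[i] - 1L) * pr +
      seq_len(pr)
    cols <- tissue_origin[2L] + (regions$patch_col[i] - 1L) * pc +
      seq_len(pc)
    if (max(rows) > h || max(cols) > w)
      stop("phantom layout exceeds the DICOM image extent", call. = FALSE)
    region_map[rows, cols] <- regions$region[i]
  }
  tissue_bottom <- tissue_origin[1L] + max(regions$patch_row) * pr
  vessel_rows <- seq(tissue_bottom + 1L, h)
  if (length(vessel_rows) < 1L)
    stop("no rows left below the tissue block for the vessel strip",
         call. = FALSE)
  truth_maps <- lapply(c("ktrans", "ve", "vp", "kep"), function(nm) {
    m <- matrix(NA_real_, h, w)
    ok <- !is.na(region_map)
    m[ok] <- regions[[nm]][region_map[ok]]
    m
  })
  names(truth_maps) <- c("ktrans", "ve", "vp", "kep")
  structure(
    list(series = loaded$series, truth = regions, truth_maps = truth_maps,
         tissue_mask = !is.na(region_map), region_map = region_map,
         vessel_rows = vessel_rows,
         aif = NULL, spec = spec),
    class = "dce_phantom")
}
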