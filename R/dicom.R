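# Minimal DICOM CT series codec: Explicit VR Little Endian, one
# single-frame file per slice, the tag subset needed for quantitative CT
# volumes (geometry, rescale, 16-bit pixel data). Values are HU in memory;
# the integer stored values and rescale slope/intercept exist only here.

UID_ROOT <- "1.2.826.0.1.3680043.9999"
UID_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")

evenPad <- function(bytes, pad = as.raw(0)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

# One data element, Explicit VR Little Endian.
dicomElement <- function(group, elem, vr, value) {
  bytes <- switch(vr,
    UI = evenPad(charToRaw(value), as.raw(0)),
    DS = , IS = , CS = , LO = , SH = evenPad(charToRaw(value),
                                             charToRaw(" ")),
    US = uint16le(value),
    OB = evenPad(value),
    OW = value,
    stop("unsupported VR: ", vr))
  hdr <- c(uint16le(group), uint16le(elem), charToRaw(vr))
  if (vr %in% LONG_VRS)
    c(hdr, as.raw(c(0, 0)), uint32le(length(bytes)), bytes)
  else
    c(hdr, uint16le(length(bytes)), bytes)
}

ds <- function(x) paste(formatC(x, format = "g", digits = 10),
                        collapse = "\\")

#' Write a volume as a DICOM CT series
#'
#' One Explicit-VR-little-endian file per slice, 16-bit signed stored
#' values with `HU = slope * stored + intercept`. By default slope 1 /
#' intercept -1000 is used when the HU range fits the 16-bit span (so air
#' is stored as 0), otherwise a wider slope is chosen automatically; an
#' explicitly requested rescale that cannot represent the HU range is a
#' hard error. Uncovered voxels are written as air (-1000 HU): DICOM has
#' no mask channel, the coverage mask is an in-memory concept.
#'
#' @param v a [CTVolume-class], finite wherever covered.
#' @param directory output directory (created if needed).
#' @param slope,intercept optional fixed rescale.
#' @param seriesUID optional series instance UID (deterministic default).
#' @return invisibly, the vector of file paths written.
#' @seealso [readDicomSeries()]
#' @export
writeDicomSeries <- function(v, directory, slope = NULL, intercept = NULL,
                             seriesUID = NULL) {
  stopifnot(is(v, "CTVolume"))
  hu <- v@values
  hu[!v@coverage] <- -1000
  if (any(!is.finite(hu))) stop("volume must be finite where covered")
  rng <- range(hu)
  auto <- is.null(slope) && is.null(intercept)
  if (auto) {
    slope <- 1; intercept <- -1000
    if ((rng[2] - intercept) / slope > 32767 ||
        (rng[1] - intercept) / slope < -32768) {
      intercept <- mean(rng)
      slope <- max((rng[2] - rng[1]) / 65000, 1e-6)
    }
  }
  slope <- slope %||% 1; intercept <- intercept %||% -1000
  stored <- round((hu - intercept) / slope)
  if (max(stored) > 32767 || min(stored) < -32768)
    stop("HU range [", rng[1], ", ", rng[2],
         "] exceeds the 16-bit span at slope ", slope,
         ", intercept ", intercept)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  d <- dim(v)
  if (is.null(seriesUID)) seriesUID <- paste0(UID_ROOT, ".1.1")
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sop <- paste0(seriesUID, ".", k)
    ipp <- c(v@origin[1], v@origin[2],
             v@origin[3] + (k - 1) * v@spacing[3]) * 10  # cm -> mm
    meta <- c(
      dicomElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dicomElement(0x0002, 0x0002, "UI", UID_CT_IMAGE),
      dicomElement(0x0002, 0x0003, "UI", sop),
      dicomElement(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
      dicomElement(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".0.1")))
    # (0002,0000) group length, UL (4-byte value), built by hand
    metaLen <- c(uint16le(0x0002), uint16le(0x0000), charToRaw("UL"),
                 uint16le(4L), uint32le(length(meta)))
    pix <- writeBin(as.integer(stored[, , k]), raw(), size = 2,
                    endian = "little")
    dataset <- c(
      dicomElement(0x0008, 0x0016, "UI", UID_CT_IMAGE),
      dicomElement(0x0008, 0x0018, "UI", sop),
      dicomElement(0x0008, 0x0060, "CS", "CT"),
      dicomElement(0x0018, 0x0050, "DS", ds(v@spacing[3] * 10)),
      dicomElement(0x0020, 0x000D, "UI", paste0(seriesUID, ".0")),
      dicomElement(0x0020, 0x000E, "UI", seriesUID),
      dicomElement(0x0020, 0x0013, "IS", as.character(k)),
      dicomElement(0x0020, 0x0032, "DS", ds(ipp)),
      dicomElement(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0))),
      dicomElement(0x0028, 0x0002, "US", 1L),
      dicomElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dicomElement(0x0028, 0x0010, "US", d[2]),  # rows (y)
      dicomElement(0x0028, 0x0011, "US", d[1]),  # columns (x)
      dicomElement(0x0028, 0x0030, "DS", ds(c(v@spacing[2], v@spacing[1]) * 10)),
      dicomElement(0x0028, 0x0100, "US", 16L),
      dicomElement(0x0028, 0x0101, "US", 16L),
      dicomElement(0x0028, 0x0102, "US", 15L),
      dicomElement(0x0028, 0x0103, "US", 1L),
      dicomElement(0x0028, 0x1052, "DS", ds(intercept)),
      dicomElement(0x0028, 0x1053, "DS", ds(slope)),
      dicomElement(0x7FE0, 0x0010, "OW", pix))
    path <- file.path(directory, sprintf("slice%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), metaLen, meta, dataset), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

# Parse one DICOM file into a named list of the tags we understand.
parseDicomFile <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 160 ||
      rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list()
  n <- length(bytes)
  u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) encoding in ", path)
    if (vr %in% LONG_VRS) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1L > n)
      stop("corrupt element length in ", path)
    val <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- switch(vr,
      UI = rawToChar(val[val != as.raw(0)]),
      DS = , IS = , CS = , LO = , SH = trimws(rawToChar(val)),
      US = readBin(val, "integer", n = len / 2, size = 2, signed = FALSE,
                   endian = "little"),
      UL = readBin(val, "integer", n = len / 4, size = 4,
                   endian = "little"),
      OW = , OB = val,
      trimws(rawToChar(val)))
    pos <- vstart + len
  }
  out
}

dsNum <- function(x) as.numeric(strsplit(x, "\\\\")[[1]])

#' Read a DICOM CT series as a volume
#'
#' Reads all `*.dcm` files in a directory as one axial CT series: slices
#' are sorted by position along the slice normal, the rescale
#' slope/intercept is applied so returned values are HU, and coverage is
#' all-true. Mixed series UIDs, duplicate or missing slice positions, and
#' non-uniform spacing are hard errors.
#'
#' @param directory directory containing one CT series.
#' @return a [CTVolume-class].
#' @export
readDicomSeries <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", directory)
  parsed <- lapply(files, parseDicomFile)
  ts <- vapply(parsed, function(p) p[["00020010"]] %||% "", "")
  if (any(ts != UID_EXPLICIT_VR_LE))
    stop("unsupported transfer syntax: ",
         paste(unique(ts[ts != UID_EXPLICIT_VR_LE]), collapse = ", "))
  series <- vapply(parsed, function(p) p[["0020000E"]] %||% "", "")
  if (length(unique(series)) != 1L)
    stop("mixed series UIDs in ", directory, ": ",
         paste(unique(series), collapse = ", "))
  orient <- vapply(parsed, function(p) p[["00200037"]], "")
  if (any(vapply(orient,
                 function(o) max(abs(dsNum(o) - c(1, 0, 0, 0, 1, 0))) > 1e-6,
                 TRUE)))
    stop("only axial orientation (1\\0\\0\\0\\1\\0) is supported")
  z <- vapply(parsed, function(p) dsNum(p[["00200032"]])[3], 0)
  ord <- order(z)
  parsed <- parsed[ord]; z <- z[ord]
  if (anyDuplicated(signif(z, 10)))
    stop("duplicate slice position at z = ",
         z[duplicated(signif(z, 10))][1], " mm")
  if (length(z) > 2) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-4 * max(abs(dz)))
      stop("missing or unevenly spaced slice near z = ",
           z[which.max(abs(dz - stats::median(dz)))], " mm")
  }
  first <- parsed[[1]]
  nxy <- c(first[["00280011"]], first[["00280010"]])  # columns (x), rows (y)
  px <- dsNum(first[["00280030"]])  # row spacing (y), column spacing (x)
  sliceTh <- if (length(z) > 1) diff(z)[1] else dsNum(first[["00180050"]])
  vals <- array(0, c(nxy[1], nxy[2], length(parsed)))
  for (k in seq_along(parsed)) {
    p <- parsed[[k]]
    if (!identical(c(p[["00280011"]], p[["00280010"]]), nxy))
      stop("inconsistent slice dimensions in series")
    signed <- identical(p[["00280103"]], 1L)
    stored <- readBin(p[["7FE00010"]], "integer",
                      n = prod(nxy), size = 2, signed = signed,
                      endian = "little")
    slope <- dsNum(p[["00281053"]] %||% "1")
    intercept <- dsNum(p[["00281052"]] %||% "0")
    vals[, , k] <- slope * stored + intercept
  }
  ipp <- dsNum(first[["00200032"]])
  ctVolume(vals, spacing = c(px[2], px[1], sliceTh) / 10,
           origin = ipp / 10)
}
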