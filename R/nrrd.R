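# Minimal NRRD I/O for 3D scalar volumes and masks. Covers the subset this
# pipeline writes and reads back: attached header, raw little-endian or
# ascii encoding, types double/float/int/short/uchar, 3D sizes, per-axis
# spacings (either `spacings:` or diagonal `space directions:`).

nrrd_type_map <- list(
  "double" = list(what = "double", size = 8L),
  "float"  = list(what = "double", size = 4L),
  "int"    = list(what = "integer", size = 4L),
  "int32"  = list(what = "integer", size = 4L),
  "short"  = list(what = "integer", size = 2L),
  "int16"  = list(what = "integer", size = 2L),
  "uchar"  = list(what = "integer", size = 1L),
  "uint8"  = list(what = "integer", size = 1L)
)

parse_nrrd_vector <- function(s) {
  s <- gsub("[()]", "", s)
  as.numeric(strsplit(trimws(s), "[, ]+")[[1]])
}

#' Read a 3D volume from an NRRD file
#'
#' @param path path to an NRRD file with an attached header.
#' @param label if not NULL, the payload is returned as a [roi_mask()] with
#'   this label instead of an [image_volume()].
#' @return An [image_volume()] (or [roi_mask()] when \code{label} is given).
#' @export
read_volume <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.null(ndim) || is.na(ndim)) stop("missing 'dimension' field")
  if (ndim != 3L) stop("expected 3 dimensions, got ", ndim)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("bad 'sizes' field")

  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L) stop("bad 'space directions' field")
    m <- vapply(vecs, parse_nrrd_vector, numeric(3))
    spacing <- sqrt(colSums(m^2))
  }
  if (is.null(spacing)) stop("missing spacing metadata (spacings/space directions)")

  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vector(fields[["space origin"]])

  typ <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  n <- prod(sizes)
  if (enc %in% c("raw")) {
    tm <- nrrd_type_map[[typ]]
    if (is.null(tm)) stop("unsupported NRRD type: ", typ)
    endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
    values <- readBin(con, what = tm$what, n = n, size = tm$size,
                      endian = endian,
                      signed = !(typ %in% c("uchar", "uint8")))
  } else if (enc %in% c("ascii", "txt", "text")) {
    values <- scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(values) != n) stop("payload shorter than sizes in ", path)
  arr <- array(as.double(values), dim = sizes)
  if (is.null(label)) image_volume(arr, spacing, origin)
  else roi_mask(arr != 0, label, spacing, origin)
}

#' Write a 3D volume or mask to an NRRD file
#'
#' Integer-valued data are stored as 32-bit integers so a write/read cycle
#' is bit-exact; anything else is stored as double. Masks are written as
#' uchar 0/1.
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output path.
#' @param encoding \code{"raw"} (default) or \code{"ascii"}.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(x, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  is_mask <- inherits(x, "roi_mask")
  if (!is_mask && !inherits(x, "image_volume"))
    stop("x must be an image_volume or roi_mask")
  v <- x$voxels
  if (is_mask) {
    type <- "uchar"; values <- as.integer(v)
  } else if (all(v == round(v)) && max(abs(v)) < 2^31 - 1) {
    type <- "int"; values <- as.integer(v)
  } else {
    type <- "double"; values <- as.double(v)
  }
  d <- dim(v)
  hdr <- c(
    "NRRD0004",
    "# written by dceradiomics",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("spacings: ", paste(format(x$spacing, digits = 17), collapse = " ")),
    paste0("space origin: (", paste(format(x$origin, digits = 17), collapse = ","), ")"),
    paste0("encoding: ", encoding)
  )
  if (encoding == "raw") hdr <- c(hdr, "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con)
  if (encoding == "raw") {
    size <- if (type == "uchar") 1L else if (type == "int") 4L else 8L
    writeBin(values, con, size = size, endian = "little")
  } else {
    writeLines(paste(format(values, digits = 17), collapse = " "), con)
  }
  invisible(path)
}
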