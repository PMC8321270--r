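# Minimal MetaImage (.mhd/.raw) reader and writer, enough for uncompressed
# 3D volumes as produced by common CT tooling. Little-endian only.

mhd_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- function(key) {
    if (is.null(kv[[key]])) stop("MetaImage header ", path, " lacks ", key)
    kv[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (!identical(ndims, 3L))
    stop("expected a 3D volume in ", path, " but NDims = ", ndims)
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.null(kv$CompressedData) && toupper(kv$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported: ", path)
  msb <- kv$ElementByteOrderMSB
  if (is.null(msb)) msb <- kv$BinaryDataByteOrderMSB
  if (!is.null(msb) && toupper(msb) == "TRUE")
    stop("big-endian MetaImage data is not supported: ", path)
  ty <- mhd_types[[need("ElementType")]]
  if (is.null(ty)) stop("unsupported ElementType ", kv$ElementType, " in ", path)
  datafile <- need("ElementDataFile")
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) stop("raw data file missing: ", raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = ty$what, n = n, size = ty$size,
                  signed = ty$signed, endian = "little")
  if (length(vals) != n)
    stop("raw file ", raw_path, " holds ", length(vals),
         " values, expected ", n)
  list(data = array(as.numeric(vals), dims), spacing = spacing, origin = origin)
}

write_mhd <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      type = "MET_FLOAT") {
  ty <- mhd_types[[type]]
  if (is.null(ty)) stop("unsupported ElementType ", type)
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(data), collapse = " ")),
    paste("ElementSpacing =", paste(spacing, collapse = " ")),
    paste("Offset =", paste(origin, collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", raw_name))
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  vals <- as.vector(data)
  if (ty$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = ty$size, endian = "little")
  invisible(path)
}
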