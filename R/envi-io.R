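## ENVI cube I/O: text .hdr + flat binary. Supported dialects: data
## types 4 (32-bit float) and 12 (16-bit unsigned), interleaves BIL,
## BIP, BSQ, both byte orders.

.parseEnviHeader <- function(headerPath) {
  txt <- readLines(headerPath, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  ## join { ... } blocks and split into key = value entries
  getField <- function(key) {
    m <- regmatches(txt, regexpr(
      paste0("(?mi)^\\s*", key, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"),
      txt, perl = TRUE))
    if (!length(m)) return(NULL)
    val <- sub(paste0("(?i)^\\s*", key, "\\s*=\\s*"), "", m, perl = TRUE)
    trimws(val)
  }
  num <- function(key) {
    v <- getField(key)
    if (is.null(v)) NULL else as.numeric(v)
  }
  wl <- getField("wavelength")
  if (is.null(wl)) stop("ENVI header missing 'wavelength' field")
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", wl), ",")[[1]])
  list(samples = num("samples"), lines = num("lines"), bands = num("bands"),
       dataType = num("data type"),
       interleave = toupper(getField("interleave")),
       byteOrder = { b <- num("byte order"); if (is.null(b)) 0 else b },
       wavelength = wl)
}

#' Read an ENVI hyperspectral cube
#'
#' Reads a text `.hdr` header plus flat binary pair. The header must
#' declare `samples`, `lines`, `bands`, `data type` (4 = float32 or
#' 12 = uint16), `interleave` (BIL/BIP/BSQ) and a `wavelength` list
#' whose length matches `bands`.
#'
#' @param headerPath path to the `.hdr` file; the binary is the same
#'   path without the `.hdr` extension (or with `.dat`).
#' @param kind cube kind tag, default `"raw"`.
#' @return A [SpectralCube-class] with dimensions lines x samples x bands.
#' @export
readENVI <- function(headerPath, kind = "raw") {
  h <- .parseEnviHeader(headerPath)
  if (is.null(h$samples) || is.null(h$lines) || is.null(h$bands))
    stop("ENVI header missing samples/lines/bands")
  if (!h$interleave %in% c("BIL", "BIP", "BSQ"))
    stop("unsupported interleave: ", h$interleave)
  if (!h$dataType %in% c(4, 12))
    stop("unsupported ENVI data type ", h$dataType,
         " (only 4 = float32 and 12 = uint16 are supported)")
  if (length(h$wavelength) != h$bands)
    stop("wavelength list length does not match 'bands'")
  binPath <- sub("\\.hdr$", "", headerPath)
  if (!file.exists(binPath)) {
    binPath2 <- paste0(binPath, ".dat")
    if (!file.exists(binPath2)) stop("ENVI binary not found for ", headerPath)
    binPath <- binPath2
  }
  nel <- h$samples * h$lines * h$bands
  bytes <- if (h$dataType == 4) 4L else 2L
  if (file.size(binPath) != nel * bytes)
    stop("ENVI binary size (", file.size(binPath),
         ") does not match header dimensions (expected ", nel * bytes, ")")
  endian <- if (h$byteOrder == 1) "big" else "little"
  con <- file(binPath, "rb")
  on.exit(close(con))
  raw <- if (h$dataType == 4)
    readBin(con, "numeric", n = nel, size = 4, endian = endian)
  else
    readBin(con, "integer", n = nel, size = 2, signed = FALSE,
            endian = endian)
  ## fastest-varying first per interleave; target array is
  ## (lines, samples, bands)
  arr <- switch(h$interleave,
    BSQ = aperm(array(raw, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    BIL = aperm(array(raw, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    BIP = aperm(array(raw, dim = c(h$bands, h$samples, h$lines)), c(3, 2, 1)))
  SpectralCube(arr, h$wavelength, kind)
}

#' Write an ENVI hyperspectral cube
#'
#' @param cube a [SpectralCube-class].
#' @param path output binary path; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave `"BSQ"` (default), `"BIL"` or `"BIP"`.
#' @param dataType 4 (float32, default) or 12 (uint16).
#' @return Invisibly, the header path.
#' @export
writeENVI <- function(cube, path, interleave = "BSQ", dataType = 4L) {
  stopifnot(methods::is(cube, "SpectralCube"))
  interleave <- toupper(interleave)
  if (!interleave %in% c("BIL", "BIP", "BSQ"))
    stop("unsupported interleave: ", interleave)
  if (!dataType %in% c(4, 12)) stop("unsupported ENVI data type ", dataType)
  d <- dim(cube@values)
  perm <- switch(interleave,
    BSQ = c(2, 1, 3), BIL = c(2, 3, 1), BIP = c(3, 2, 1))
  flat <- as.vector(aperm(cube@values, perm))
  con <- file(path, "wb")
  if (dataType == 4) {
    writeBin(as.numeric(flat), con, size = 4, endian = "little")
  } else {
    if (any(flat < 0 | flat > 65535))
      stop("values outside uint16 range for data type 12")
    writeBin(as.integer(round(flat)), con, size = 2, endian = "little")
  }
  close(con)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", dataType),
           paste0("interleave = ", tolower(interleave)),
           "byte order = 0",
           paste0("wavelength = {",
                  paste(signif(cube@wavelength, 7), collapse = ", "), "}"))
  hdrPath <- paste0(path, ".hdr")
  writeLines(hdr, hdrPath)
  invisible(hdrPath)
}
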