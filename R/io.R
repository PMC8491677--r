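# File readers/writers for the standard surface-analysis formats consumed and
# produced by the pipeline: GIFTI (surface + per-vertex data arrays),
# FreeSurfer binary surfaces / curvature / annotation files, and delimited
# text for endpoint records, connectomes, profiles and labels.
#
# Vertex indices are 0-based on disk (GIFTI triangles, annot vertex ids) and
# converted to 1-based at this boundary.

# ---------------------------------------------------------------------------
# GIFTI

gii_decode_data <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  dims <- c(as.integer(xml2::xml_attr(node, "Dim0")),
            as.integer(xml2::xml_attr(node, "Dim1")))
  dims <- dims[!is.na(dims)]
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//Data"))
  n <- prod(dims)
  vals <- if (identical(enc, "ASCII")) {
    scan(text = txt, quiet = TRUE)
  } else {
    raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (identical(enc, "GZipBase64Binary")) {
      raw <- memDecompress(raw, type = "gzip")
    } else if (!identical(enc, "Base64Binary")) {
      stop("unsupported GIFTI encoding: ", enc)
    }
    endian <- if (identical(xml2::xml_attr(node, "Endian"), "BigEndian")) {
      "big"
    } else {
      "little"
    }
    if (grepl("FLOAT32", dtype)) {
      readBin(raw, "numeric", n = n, size = 4L, endian = endian)
    } else if (grepl("FLOAT64", dtype)) {
      readBin(raw, "numeric", n = n, size = 8L, endian = endian)
    } else {
      readBin(raw, "integer", n = n, size = 4L, endian = endian)
    }
  }
  if (length(vals) != n) stop("GIFTI data array length mismatch")
  if (length(dims) == 2L) {
    order <- xml2::xml_attr(node, "ArrayIndexingOrder")
    matrix(vals, nrow = dims[1L], ncol = dims[2L],
           byrow = !identical(order, "ColumnMajorOrder"))
  } else {
    vals
  }
}

#' Read a GIFTI surface file
#'
#' Supports ASCII, Base64Binary and GZipBase64Binary data arrays. Triangle
#' indices are converted from the file's 0-based convention.
#'
#' @param path path to a `.surf.gii` file.
#' @param roi_mask,hemisphere passed to [surface_mesh()]; hemisphere defaults
#'   to the file's `AnatomicalStructurePrimary` metadata when present.
#' @return a `surface_mesh`.
#' @export
read_gifti_surface <- function(path, roi_mask = NULL, hemisphere = NULL) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) == 0L || length(it) == 0L) {
    stop("GIFTI file lacks POINTSET/TRIANGLE arrays: ", path)
  }
  verts <- gii_decode_data(arrays[[ip[1L]]])
  tris <- gii_decode_data(arrays[[it[1L]]]) + 1L
  if (is.null(hemisphere)) {
    md <- xml2::xml_text(xml2::xml_find_all(doc, ".//MD/Value"))
    hemisphere <- if (any(grepl("Right", md))) "right" else "left"
  }
  surface_mesh(verts, tris, roi_mask = roi_mask, hemisphere = hemisphere)
}

#' Read per-vertex data arrays from a GIFTI func/shape file
#'
#' @param path path to a `.func.gii` / `.shape.gii` file.
#' @return numeric vector (one data array) or matrix (vertices x arrays).
#' @export
read_gifti_data <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  cols <- lapply(arrays, gii_decode_data)
  if (length(cols) == 1L) return(cols[[1L]])
  do.call(cbind, cols)
}

gii_array_xml <- function(values, intent, dtype) {
  if (is.matrix(values)) {
    dims <- sprintf(' Dim0="%d" Dim1="%d" Dimensionality="2"',
                    nrow(values), ncol(values))
    flat <- as.vector(t(values))
  } else {
    dims <- sprintf(' Dim0="%d" Dimensionality="1"', length(values))
    flat <- values
  }
  txt <- if (grepl("INT", dtype)) {
    paste(format(as.integer(flat), scientific = FALSE), collapse = " ")
  } else {
    paste(format(flat, digits = 17), collapse = " ")
  }
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder"',
    '%s Encoding="ASCII" Endian="LittleEndian" ExternalFileName=""',
    ' ExternalFileOffset=""><Data>%s</Data></DataArray>'),
    intent, dtype, dims, txt)
}

gii_write_doc <- function(path, arrays_xml) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0" encoding="UTF-8"?>', con)
  writeLines('<GIFTI Version="1.0" NumberOfDataArrays="0">', con)
  for (a in arrays_xml) writeLines(a, con)
  writeLines("</GIFTI>", con)
  invisible(path)
}

#' Write a surface mesh as an ASCII-encoded GIFTI file
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @export
write_gifti_surface <- function(mesh, path) {
  gii_write_doc(path, list(
    gii_array_xml(mesh$vertices, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32"),
    gii_array_xml(mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                  "NIFTI_TYPE_INT32")
  ))
}

#' Write per-vertex data as an ASCII-encoded GIFTI file
#'
#' @param values numeric vector or vertices x k matrix.
#' @param path output path.
#' @export
write_gifti_data <- function(values, path) {
  cols <- if (is.matrix(values)) {
    lapply(seq_len(ncol(values)), function(j) values[, j])
  } else {
    list(values)
  }
  gii_write_doc(path, lapply(cols, gii_array_xml,
                             intent = "NIFTI_INTENT_NONE",
                             dtype = "NIFTI_TYPE_FLOAT32"))
}

# ---------------------------------------------------------------------------
# FreeSurfer binary formats (big-endian throughout)

fs_read_int3 <- function(con) {
  b <- as.integer(readBin(con, "raw", n = 3L))
  b[1L] * 65536L + b[2L] * 256L + b[3L]
}

fs_write_int3 <- function(con, x) {
  writeBin(as.raw(c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L)), con)
}

#' Read a FreeSurfer binary surface file
#'
#' @param path path to e.g. `lh.white`.
#' @inheritParams read_gifti_surface
#' @return a `surface_mesh`.
#' @export
read_freesurfer_surface <- function(path, roi_mask = NULL,
                                    hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- fs_read_int3(con)
  if (magic != 16777214L) stop("not a FreeSurfer triangle surface: ", path)
  # comment line terminated by \n\n
  prev <- as.raw(0L)
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (ch == as.raw(10L) && prev == as.raw(10L)) break
    prev <- ch
  }
  vcount <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  fcount <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  verts <- matrix(readBin(con, "numeric", n = 3L * vcount, size = 4L,
                          endian = "big"), ncol = 3L, byrow = TRUE)
  tris <- matrix(readBin(con, "integer", n = 3L * fcount, size = 4L,
                         endian = "big"), ncol = 3L, byrow = TRUE) + 1L
  surface_mesh(verts, tris, roi_mask = roi_mask, hemisphere = hemisphere)
}

#' Write a FreeSurfer binary surface file
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @export
write_freesurfer_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  fs_write_int3(con, 16777214L)
  writeBin(charToRaw("created by conngrad\n\n"), con)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(mesh$triangles)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$triangles) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer curvature/morphometry file (new binary format)
#'
#' @param path path to e.g. `lh.curv`.
#' @return numeric per-vertex vector.
#' @export
read_freesurfer_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- fs_read_int3(con)
  if (magic != 16777215L) stop("not a new-format curv file: ", path)
  vcount <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  readBin(con, "integer", n = 2L, size = 4L, endian = "big")  # fnum, per-vertex
  readBin(con, "numeric", n = vcount, size = 4L, endian = "big")
}

#' Write a FreeSurfer curvature/morphometry file
#'
#' @param values numeric per-vertex vector.
#' @param path output path.
#' @export
write_freesurfer_curv <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  fs_write_int3(con, 16777215L)
  writeBin(as.integer(c(length(values), 0L, 1L)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer annotation (label) file
#'
#' Returns labels by colortable structure name when a colortable is present,
#' otherwise the raw packed RGB label integers. Vertices are returned in
#' 1-based order.
#'
#' @param path path to e.g. `lh.aparc.annot`.
#' @return factor of per-vertex labels.
#' @export
read_freesurfer_annot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  pairs <- matrix(readBin(con, "integer", n = 2L * n, size = 4L,
                          endian = "big"), ncol = 2L, byrow = TRUE)
  labels <- integer(n)
  labels[pairs[, 1L] + 1L] <- pairs[, 2L]
  tag <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(tag) == 0L || tag == 0L) return(factor(labels))
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (version != -2L) stop("unsupported annot colortable version: ", version)
  readBin(con, "integer", n = 1L, size = 4L, endian = "big")  # max structure
  flen <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  readBin(con, "raw", n = flen)
  n_entries <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  names <- character(n_entries)
  values <- integer(n_entries)
  for (i in seq_len(n_entries)) {
    readBin(con, "integer", n = 1L, size = 4L, endian = "big")  # structure id
    len <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    nm <- readBin(con, "raw", n = len)
    names[i] <- rawToChar(nm[nm != as.raw(0L)])
    rgba <- readBin(con, "integer", n = 4L, size = 4L, endian = "big")
    values[i] <- rgba[1L] + rgba[2L] * 256L + rgba[3L] * 65536L
  }
  factor(labels, levels = values, labels = names)
}

#' Write a FreeSurfer annotation (label) file
#'
#' Each label level receives a distinct packed-RGB value and a colortable
#' entry named after the level.
#'
#' @param labels factor (or coercible) of per-vertex labels.
#' @param path output path.
#' @export
write_freesurfer_annot <- function(labels, path) {
  labels <- as.factor(labels)
  lev <- levels(labels)
  # distinct RGB triplets per level
  idx <- seq_along(lev)
  r <- (idx * 53L) %% 256L
  g <- (idx * 97L) %% 256L
  b <- (idx * 151L) %% 256L
  packed <- r + g * 256L + b * 65536L
  if (anyDuplicated(packed)) stop("colortable collision; too many levels")
  vals <- packed[as.integer(labels)]
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(labels)
  writeBin(as.integer(n), con, size = 4L, endian = "big")
  writeBin(as.integer(t(cbind(seq_len(n) - 1L, vals))), con, size = 4L,
           endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")          # colortable tag
  writeBin(-2L, con, size = 4L, endian = "big")         # version
  writeBin(as.integer(length(lev)), con, size = 4L, endian = "big")
  fname <- charToRaw("conngrad.ctab")
  writeBin(as.integer(length(fname)), con, size = 4L, endian = "big")
  writeBin(fname, con)
  writeBin(as.integer(length(lev)), con, size = 4L, endian = "big")
  for (i in seq_along(lev)) {
    writeBin(as.integer(i - 1L), con, size = 4L, endian = "big")
    nm <- charToRaw(lev[i])
    writeBin(as.integer(length(nm)), con, size = 4L, endian = "big")
    writeBin(nm, con)
    writeBin(as.integer(c(r[i], g[i], b[i], 0L)), con, size = 4L,
             endian = "big")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Delimited text

#' Read streamline endpoint records from delimited text
#'
#' Format: one streamline per line, `x1 y1 z1 x2 y2 z2 weight`, whitespace or
#' comma delimited, `#` comment lines ignored.
#'
#' @param path input path.
#' @return an `endpoint_set` (see [endpoint_set()]).
#' @export
read_endpoints <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind,
               lapply(strsplit(trimws(lines), "[,[:space:]]+"), as.numeric))
  if (ncol(m) != 7L) stop("endpoint records need 7 columns, got ", ncol(m))
  endpoint_set(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], m[, 7L])
}

#' Write streamline endpoint records as delimited text
#'
#' @param endpoints an `endpoint_set`.
#' @param path output path.
#' @export
write_endpoints <- function(endpoints, path) {
  m <- cbind(endpoints$termini_a, endpoints$termini_b, endpoints$weight)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x1 y1 z1 x2 y2 z2 weight", con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read a numeric matrix as tab-separated text
#'
#' @param m numeric matrix.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = !is.null(colnames(m)), quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param header whether the file carries a header row.
#' @export
read_matrix_tsv <- function(path, header = FALSE) {
  as.matrix(utils::read.table(path, sep = "\t", header = header))
}
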