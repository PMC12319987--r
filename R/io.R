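#' Read a surface mesh
#'
#' Supported formats: GIFTI surface (`.surf.gii`; ASCII, Base64Binary and
#' GZipBase64Binary encodings), FreeSurfer binary surface (`lh.white`
#' style, the triangle-file magic), and OFF (plain-text, used for small
#' fixtures). On-disk 0-based triangle indices are translated to the
#' package's 1-based convention.
#'
#' @param path file path.
#' @param format `"gifti"`, `"freesurfer"` or `"off"`.
#' @param hemisphere hemisphere tag to attach (`"left"` or `"right"`).
#' @return a [surface_mesh()].
#' @export
load_surface <- function(path, format = c("gifti", "freesurfer", "off"),
                         hemisphere = c("left", "right")) {
  format <- match.arg(format)
  hemisphere <- match.arg(hemisphere)
  if (!file.exists(path)) stop("file not found: ", path)
  geo <- switch(format,
                gifti = read_gifti_surface(path),
                freesurfer = read_fs_surface(path),
                off = read_off(path))
  surface_mesh(geo$vertices, geo$faces + 1L, hemisphere)
}

#' Write a surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format see [load_surface()].
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = c("gifti", "freesurfer", "off")) {
  format <- match.arg(format)
  faces0 <- mesh$faces - 1L
  switch(format,
         gifti = write_gifti_surface(mesh$vertices, faces0, path),
         freesurfer = write_fs_surface(mesh$vertices, faces0, path),
         off = write_off(mesh$vertices, faces0, path))
  invisible(path)
}

#' Read a label map
#'
#' Supported formats: GIFTI label (`.label.gii`) and FreeSurfer `.annot`.
#'
#' @param path file path.
#' @param format `"gifti"` or `"annot"`.
#' @param hemisphere hemisphere tag.
#' @return a [parcellation()].
#' @export
load_labels <- function(path, format = c("gifti", "annot"),
                        hemisphere = c("left", "right")) {
  format <- match.arg(format)
  hemisphere <- match.arg(hemisphere)
  if (!file.exists(path)) stop("file not found: ", path)
  lab <- switch(format,
                gifti = read_gifti_labels(path),
                annot = read_fs_annot(path))
  parcellation(lab$labels, lab$label_table, hemisphere)
}

#' Write a label map
#'
#' @param parc a [parcellation()].
#' @param path output path.
#' @param format `"gifti"` or `"annot"`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(parc, path, format = c("gifti", "annot")) {
  format <- match.arg(format)
  switch(format,
         gifti = write_gifti_labels(parc$labels, parc$label_table, path),
         annot = write_fs_annot(parc$labels, parc$label_table, path))
  invisible(path)
}

## ---- OFF ------------------------------------------------------------------

read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!identical(trimws(lines[1L]), "OFF")) stop("not an OFF file: ", path)
  counts <- scan(text = lines[2L], quiet = TRUE)
  nv <- as.integer(counts[1L]); nf <- as.integer(counts[2L])
  if (is.na(nv) || nv < 1L) stop("zero vertices in OFF file")
  v <- matrix(scan(text = lines[2L + seq_len(nv)], quiet = TRUE),
              nv, 3L, byrow = TRUE)
  f <- matrix(0L, nf, 3L)
  if (nf > 0L) {
    fr <- matrix(scan(text = lines[2L + nv + seq_len(nf)], quiet = TRUE),
                 nf, 4L, byrow = TRUE)
    if (any(fr[, 1L] != 3)) stop("only triangular OFF faces are supported")
    f <- matrix(as.integer(fr[, 2:4]), nf, 3L)
  }
  list(vertices = v, faces = f)
}

write_off <- function(vertices, faces0, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", paste(nrow(vertices), nrow(faces0), 0L)), con)
  writeLines(apply(vertices, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  if (nrow(faces0))
    writeLines(apply(faces0, 1L, function(r)
      paste(c(3L, r), collapse = " ")), con)
}

## ---- GIFTI ----------------------------------------------------------------

gifti_decode <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  dim0 <- as.integer(xml2::xml_attr(node, "Dim0"))
  ndim <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  dim1 <- if (!is.na(ndim) && ndim >= 2L)
    as.integer(xml2::xml_attr(node, "Dim1")) else 1L
  data_node <- xml2::xml_find_first(node, ".//*[local-name()='Data']")
  txt <- xml2::xml_text(data_node)
  what <- if (grepl("FLOAT", dtype)) "double" else "integer"
  size <- if (grepl("FLOAT64", dtype)) 8L else 4L
  values <- if (identical(enc, "ASCII")) {
    scan(text = txt, what = double(), quiet = TRUE)
  } else {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (identical(enc, "GZipBase64Binary"))
      raw <- memDecompress(raw, type = "gzip")
    readBin(raw, what = what, n = length(raw) %/% size, size = size,
            endian = if (identical(endian, "BigEndian")) "big" else "little")
  }
  if (is.na(dim1) || dim1 == 1L) return(as.vector(values))
  byrow <- !identical(order, "ColumnMajorOrder")
  matrix(values, nrow = dim0, ncol = dim1, byrow = byrow)
}

gifti_find_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='DataArray']")
  intents <- xml2::xml_attr(nodes, "Intent")
  list(doc = doc, nodes = nodes, intents = intents)
}

read_gifti_surface <- function(path) {
  g <- gifti_find_arrays(path)
  ip <- which(g$intents == "NIFTI_INTENT_POINTSET")
  it <- which(g$intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(ip) || !length(it))
    stop("GIFTI file lacks POINTSET/TRIANGLE arrays: ", path)
  v <- gifti_decode(g$nodes[[ip[1L]]])
  f <- gifti_decode(g$nodes[[it[1L]]])
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

gifti_header <- '<?xml version="1.0" encoding="UTF-8"?>\n<GIFTI xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" Version="1.0" NumberOfDataArrays="%d">\n'

gifti_array_ascii <- function(values, intent, dtype) {
  if (is.matrix(values)) {
    dims <- sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"',
                    nrow(values), ncol(values))
    body <- apply(values, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
  } else {
    dims <- sprintf('Dimensionality="1" Dim0="%d"', length(values))
    body <- paste(sprintf("%.17g", as.numeric(values)), collapse = " ")
  }
  paste0('<DataArray Intent="', intent, '" DataType="', dtype,
         '" ArrayIndexingOrder="RowMajorOrder" ', dims,
         ' Encoding="ASCII" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n<Data>',
         paste(body, collapse = "\n"), "</Data>\n</DataArray>\n")
}

write_gifti_surface <- function(vertices, faces0, path) {
  txt <- paste0(
    sprintf(gifti_header, 2L),
    gifti_array_ascii(vertices, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT64"),
    gifti_array_ascii(faces0, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32"),
    "</GIFTI>\n")
  writeLines(txt, path, sep = "")
}

read_gifti_labels <- function(path) {
  g <- gifti_find_arrays(path)
  il <- which(g$intents == "NIFTI_INTENT_LABEL")
  if (!length(il)) stop("GIFTI file lacks a LABEL array: ", path)
  labels <- as.integer(gifti_decode(g$nodes[[il[1L]]]))
  lab_nodes <- xml2::xml_find_all(g$doc, ".//*[local-name()='Label']")
  keys <- as.integer(xml2::xml_attr(lab_nodes, "Key"))
  nm <- xml2::xml_text(lab_nodes)
  keep <- keys != 0L
  label_table <- stats::setNames(nm[keep], as.character(keys[keep]))
  list(labels = labels, label_table = label_table)
}

write_gifti_labels <- function(labels, label_table, path) {
  entries <- c(
    '<Label Key="0" Red="0" Green="0" Blue="0" Alpha="0">Unassigned</Label>',
    sprintf('<Label Key="%s" Red="%.4f" Green="%.4f" Blue="%.4f" Alpha="1">%s</Label>',
            names(label_table),
            (as.integer(names(label_table)) %% 7L) / 7,
            (as.integer(names(label_table)) %% 5L) / 5,
            (as.integer(names(label_table)) %% 3L) / 3,
            unname(label_table)))
  txt <- paste0(
    sprintf(gifti_header, 1L),
    "<LabelTable>\n", paste(entries, collapse = "\n"), "\n</LabelTable>\n",
    gifti_array_ascii(as.numeric(labels), "NIFTI_INTENT_LABEL",
                      "NIFTI_TYPE_INT32"),
    "</GIFTI>\n")
  writeLines(txt, path, sep = "")
}

## ---- FreeSurfer binary surface -------------------------------------------

TRIANGLE_FILE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(magic, TRIANGLE_FILE_MAGIC))
    stop("not a FreeSurfer triangle surface: ", path)
  # comment line terminated by "\n\n"
  prev <- as.raw(0L)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("truncated FreeSurfer surface: ", path)
    if (b == as.raw(10L) && prev == as.raw(10L)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (is.na(nv) || nv < 1L) stop("zero vertices in FreeSurfer surface")
  v <- matrix(readBin(con, "double", nv * 3L, size = 4L, endian = "big"),
              nv, 3L, byrow = TRUE)
  f <- matrix(readBin(con, "integer", nf * 3L, size = 4L, endian = "big"),
              nf, 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

write_fs_surface <- function(vertices, faces0, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(TRIANGLE_FILE_MAGIC, con)
  writeBin(charToRaw("created by latnet\n\n"), con)
  writeBin(as.integer(nrow(vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(faces0)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(faces0)), con, size = 4L, endian = "big")
}

## ---- FreeSurfer annot -----------------------------------------------------

# Label codes are RGB-packed (R + 256 G + 65536 B); ids map to a
# deterministic colour so code <-> id is invertible via the colortable.
annot_color <- function(id) {
  c(id %% 256L, (id %/% 256L) %% 256L, (id %/% 65536L) %% 256L)
}

read_fs_annot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  dat <- matrix(readBin(con, "integer", nv * 2L, size = 4L, endian = "big"),
                nv, 2L, byrow = TRUE)
  codes <- dat[order(dat[, 1L]), 2L]
  tag <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (!length(tag) || tag != 1L) stop("annot file lacks a colortable: ", path)
  version <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (version != -2L) stop("unsupported annot colortable version: ", version)
  readBin(con, "integer", 1L, size = 4L, endian = "big")  # max structure id
  flen <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  readBin(con, "raw", flen)                                # orig ctab filename
  nentries <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  ids <- integer(nentries); nms <- character(nentries); code <- integer(nentries)
  for (i in seq_len(nentries)) {
    ids[i] <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    slen <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    nms[i] <- rawToChar(readBin(con, "raw", slen)[seq_len(slen - 1L)])
    rgbt <- readBin(con, "integer", 4L, size = 4L, endian = "big")
    code[i] <- rgbt[1L] + 256L * rgbt[2L] + 65536L * rgbt[3L]
  }
  labels <- ids[match(codes, code)]
  if (anyNA(labels)) stop("annot label code not present in colortable")
  keep <- ids != 0L
  list(labels = labels,
       label_table = stats::setNames(nms[keep], as.character(ids[keep])))
}

write_fs_annot <- function(labels, label_table, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "big")
  nv <- length(labels)
  wint(nv)
  codes <- vapply(labels, function(id) {
    rgb <- annot_color(id); rgb[1L] + 256L * rgb[2L] + 65536L * rgb[3L]
  }, 0L)
  wint(as.vector(rbind(seq_len(nv) - 1L, codes)))
  wint(1L)    # colortable tag
  wint(-2L)   # version
  ids <- c(0L, as.integer(names(label_table)))
  nms <- c("Unassigned", unname(label_table))
  wint(max(ids) + 1L)
  fname <- "latnet.ctab"
  wint(nchar(fname)); writeBin(charToRaw(fname), con)
  wint(length(ids))
  for (i in seq_along(ids)) {
    wint(ids[i])
    nm <- nms[i]
    wint(nchar(nm) + 1L)
    writeBin(c(charToRaw(nm), as.raw(0L)), con)
    wint(c(annot_color(ids[i]), 0L))
  }
}
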