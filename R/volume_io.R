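#' Read and write CT volumes and label masks
#'
#' Volumes are stored as NIfTI (`.nii`, `.nii.gz`) through RNifti or as
#' MetaImage (`.mha` single file, `.mhd` + `.raw` pair). Doubles are written
#' at full precision so a write-then-read round trip preserves voxel values
#' bit-exactly and spacing to better than 1e-6 mm. Masks additionally carry a
#' JSON sidecar (`<path>.labels.json`) with the label dictionary.
#'
#' @param x A [ct_volume()] or [label_mask()].
#' @param path File path; the extension selects the format.
#' @return `read_volume()` returns a [ct_volume()]; `read_mask()` a
#'   [label_mask()]; the writers return `path` invisibly.
#' @name volume_io
NULL

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.mha$", lower)) return("mha")
  if (grepl("\\.mhd$", lower)) return("mhd")
  abort(sprintf("unsupported volume format: '%s' (use .nii, .nii.gz, .mha or .mhd)",
                basename(path)),
        class = "vertefail_format_error")
}

#' @rdname volume_io
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "label_mask"))
  arr <- if (inherits(x, "ct_volume")) x$voxels else x$labels
  integer_data <- is.integer(arr)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    tmpl <- RNifti::niftiHeader(list(
      dim = c(3L, dim(arr), 1L, 1L, 1L, 1L),
      pixdim = c(1, x$spacing, 0, 0, 0, 0),
      qform_code = 2L,
      qoffset_x = x$origin[1], qoffset_y = x$origin[2], qoffset_z = x$origin[3]
    ))
    img <- RNifti::asNifti(arr, reference = tmpl,
                           datatype = if (integer_data) "int" else "double")
    RNifti::writeNifti(img, path)
  } else {
    write_metaimage(arr, x$spacing, x$origin, path, fmt)
  }
  invisible(path)
}

#' @rdname volume_io
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vertefail_format_error")
  }
  fmt <- volume_format(path)
  raw <- if (fmt == "nifti") read_nifti_raw(path) else read_metaimage(path)
  ct_volume(raw$arr, spacing = raw$spacing, origin = raw$origin)
}

#' @rdname volume_io
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "label_mask"))
  write_volume(x, path)
  jsonlite::write_json(as.list(x$dictionary), sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_mask <- function(path) {
  fmt <- volume_format(path)
  raw <- if (fmt == "nifti") read_nifti_raw(path) else read_metaimage(path)
  side <- sidecar_path(path)
  dict <- if (file.exists(side)) {
    unlist(jsonlite::read_json(side, simplifyVector = TRUE))
  } else {
    label_dictionary()
  }
  storage.mode(dict) <- "integer"
  label_mask(round(raw$arr), spacing = raw$spacing, origin = raw$origin,
             dictionary = dict)
}

sidecar_path <- function(path) {
  paste0(sub("\\.(nii\\.gz|nii|mha|mhd)$", "", path, ignore.case = TRUE),
         ".labels.json")
}

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) abort("expected a 3D NIfTI volume",
                                   class = "vertefail_format_error")
  attributes(arr) <- list(dim = dim(arr))
  list(arr = arr, spacing = RNifti::pixdim(img)[1:3],
       origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
}

# --- MetaImage (.mha/.mhd) ---------------------------------------------------
# Plain ITK-style header; payload is raw little-endian, x fastest (the same
# linearization R uses for arrays), MET_DOUBLE for HU and MET_INT for masks.

write_metaimage <- function(arr, spacing, origin, path, fmt) {
  integer_data <- is.integer(arr)
  data_file <- if (fmt == "mha") "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(arr), collapse = " ")),
    paste("ElementType =", if (integer_data) "MET_INT" else "MET_DOUBLE"),
    paste("ElementDataFile =", data_file)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  payload_con <- con
  if (fmt == "mhd") {
    payload_con <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(payload_con), add = TRUE)
  }
  writeBin(as.vector(arr), payload_con, size = if (integer_data) 4L else 8L,
           endian = "little")
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) abort("truncated MetaImage header",
                                 class = "vertefail_format_error")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort("malformed MetaImage header line",
                              class = "vertefail_format_error")
    key <- trimws(kv[1])
    fields[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(fields$Offset)) {
    as.numeric(strsplit(fields$Offset, "\\s+")[[1]])
  } else c(0, 0, 0)
  type <- fields$ElementType
  if (!type %in% c("MET_DOUBLE", "MET_INT", "MET_FLOAT", "MET_SHORT")) {
    abort(sprintf("unsupported MetaImage element type %s", type),
          class = "vertefail_format_error")
  }
  n <- prod(dims)
  payload_con <- con
  if (fields$ElementDataFile != "LOCAL") {
    payload_con <- file(file.path(dirname(path), fields$ElementDataFile), "rb")
    on.exit(close(payload_con), add = TRUE)
  }
  vec <- switch(type,
    MET_DOUBLE = readBin(payload_con, "double", n, size = 8L, endian = "little"),
    MET_FLOAT  = readBin(payload_con, "double", n, size = 4L, endian = "little"),
    MET_INT    = readBin(payload_con, "integer", n, size = 4L, endian = "little"),
    MET_SHORT  = readBin(payload_con, "integer", n, size = 2L, signed = TRUE,
                         endian = "little")
  )
  if (length(vec) != n) abort("truncated MetaImage payload",
                              class = "vertefail_format_error")
  list(arr = array(vec, dims), spacing = spacing, origin = origin)
}
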