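# Shared 3D grid containers and file I/O. Every stage of the pipeline passes
# volumes around as `scalar_volume` (CT in Hounsfield units, or appearance
# maps in filter-response units) and `binary_mask` objects: a 3D array plus
# voxel spacing (mm) and the physical origin of voxel (1,1,1). Filters operate
# in voxel units; spacing is carried as metadata and used for physical lengths
# (tree length, leak volume).

#' Scalar 3D volume
#'
#' Container for a 3D scalar grid (CT intensities in HU, or filter responses)
#' with voxel spacing in millimetres and the physical origin of the first
#' voxel. All pipeline stages share this container and its (i, j, k) axis
#' convention with 1-based indexing.
#'
#' @param data 3D numeric array, all values finite.
#' @param spacing Numeric length-3, voxel size in mm along each axis,
#'   strictly positive.
#' @param origin Numeric length-3, physical coordinates of voxel (1,1,1).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("volume data must be a 3D array with positive extents")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values (NaN/Inf)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "scalar_volume")
}

#' Binary 3D mask
#'
#' A 3D mask aligned to a reference [scalar_volume()]. Values are stored as
#' logical in memory and written to disk as 8-bit integers.
#'
#' @param data 3D array of logical values (or 0/1 numerics).
#' @param spacing,origin Grid metadata, as in [scalar_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("mask data must be a 3D array")
  if (is.numeric(data)) {
    if (any(!data %in% c(0, 1)))
      stop("mask values must be exactly 0 or 1")
    data <- array(data > 0, dim(data))
  }
  if (!is.logical(data)) stop("mask data must be logical or 0/1")
  if (anyNA(data)) stop("mask contains missing values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

is_mask <- function(x) inherits(x, "binary_mask")

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data))
}

vol_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.mh[ad]$", lp)) return("metaimage")
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  stop("unsupported volume format for path: ", path,
       " (expected .nii/.nii.gz, .mha/.mhd or .nrrd)")
}

#' Read a 3D volume
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`), MetaImage (`.mha`, `.mhd`) or NRRD
#' (`.nrrd`) volumes. Spacing and origin are taken from the file header;
#' intensities are returned unchanged.
#'
#' @param path Path to the volume file.
#' @param na_action What to do with non-finite voxels: `"error"` (default)
#'   or `"zero"` to replace them with 0.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, na_action = c("error", "zero")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("cannot read volume, no such file: ", path)
  fmt <- vol_format(path)
  parsed <- switch(fmt,
    nifti = {
      img <- RNifti::readNifti(path)
      list(data = array(as.numeric(img), dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3],
           origin = nifti_origin(img))
    },
    metaimage = read_metaimage(path),
    nrrd = read_nrrd(path)
  )
  if (!all(is.finite(parsed$data))) {
    if (na_action == "error")
      stop("volume ", path, " contains non-finite voxels; ",
           "use na_action = 'zero' to replace them")
    parsed$data[!is.finite(parsed$data)] <- 0
  }
  scalar_volume(parsed$data, parsed$spacing, parsed$origin)
}

nifti_origin <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
}

#' Write a 3D volume or mask
#'
#' Writes a [scalar_volume()] (32-bit float) or [binary_mask()] (8-bit
#' integer) to NIfTI-1, MetaImage or NRRD, chosen by file extension.
#'
#' @param vol A [scalar_volume()] or [binary_mask()].
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  fmt <- vol_format(path)
  if (!dir.exists(dirname(path)))
    stop("cannot write volume, directory does not exist: ", dirname(path))
  mask <- is_mask(vol)
  data <- if (mask) array(as.integer(vol$data), dim(vol$data)) else vol$data
  switch(fmt,
    nifti = {
      img <- RNifti::asNifti(data)
      RNifti::pixdim(img) <- vol$spacing
      img <- RNifti::asNifti(img, reference = list(
        srow_x = c(vol$spacing[1], 0, 0, vol$origin[1]),
        srow_y = c(0, vol$spacing[2], 0, vol$origin[2]),
        srow_z = c(0, 0, vol$spacing[3], vol$origin[3]),
        sform_code = 2L))
      RNifti::writeNifti(img, path,
                         datatype = if (mask) "uint8" else "float")
    },
    metaimage = write_metaimage(data, vol$spacing, vol$origin, path,
                                uchar = mask),
    nrrd = write_nrrd(data, vol$spacing, vol$origin, path, uchar = mask)
  )
  invisible(path)
}

# --- MetaImage (.mha local / .mhd detached) ---------------------------------
# Minimal reader/writer for uncompressed MetaImage files; covers the element
# types this package emits plus MET_SHORT/MET_DOUBLE for external inputs.

met_types <- list(MET_FLOAT = list(what = "numeric", size = 4L),
                  MET_DOUBLE = list(what = "numeric", size = 8L),
                  MET_UCHAR = list(what = "integer", size = 1L),
                  MET_CHAR = list(what = "integer", size = 1L),
                  MET_SHORT = list(what = "integer", size = 2L),
                  MET_USHORT = list(what = "integer", size = 2L),
                  MET_INT = list(what = "integer", size = 4L))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated MetaImage header in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported: ", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- met_types[[hdr$ElementType]]
  if (is.null(type)) stop("unsupported MetaImage element type: ", hdr$ElementType)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, type$what, n = n, size = type$size,
                   signed = !hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT"),
                   endian = "little")
  } else {
    dfile <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(dfile)) stop("MetaImage data file not found: ", dfile)
    raw <- readBin(dfile, type$what, n = n, size = type$size,
                   signed = !hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT"),
                   endian = "little")
  }
  if (length(raw) != n) stop("MetaImage data shorter than DimSize in ", path)
  list(data = array(as.numeric(raw), dims), spacing = spacing, origin = origin)
}

write_metaimage <- function(data, spacing, origin, path, uchar = FALSE) {
  dims <- dim(data)
  detached <- grepl("\\.mhd$", tolower(path))
  dataname <- if (detached) sub("\\.mhd$", ".raw", basename(path),
                                ignore.case = TRUE) else "LOCAL"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(origin, trim = TRUE), collapse = " ")),
           paste("ElementSpacing =",
                 paste(format(spacing, trim = TRUE), collapse = " ")),
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementType =", if (uchar) "MET_UCHAR" else "MET_FLOAT"),
           paste("ElementDataFile =", dataname))
  con <- file(path, "wb")
  writeLines(hdr, con)
  payload <- if (uchar) as.integer(data) else as.numeric(data)
  if (detached) {
    close(con)
    con2 <- file(file.path(dirname(path), dataname), "wb")
    writeBin(payload, con2, size = if (uchar) 1L else 4L, endian = "little")
    close(con2)
  } else {
    writeBin(payload, con, size = if (uchar) 1L else 4L, endian = "little")
    close(con)
  }
  invisible(path)
}

# --- NRRD -------------------------------------------------------------------
# Minimal NRRD reader/writer: raw or gzip encoding, little-endian, diagonal
# space directions only.

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed NRRD header line: ", line)
    hdr[[trimws(kv[2])]] <- trimws(kv[3])
  }
  dims <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  spacing <- c(1, 1, 1)
  if (!is.null(hdr$spacings))
    spacing <- as.numeric(strsplit(hdr$spacings, "\\s+")[[1]])
  if (!is.null(hdr[["space directions"]])) {
    rows <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1]]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(mat^2))
  }
  origin <- c(0, 0, 0)
  if (!is.null(hdr[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]),
                                  ",")[[1]])
  type <- switch(hdr$type,
    float = list(what = "numeric", size = 4L, signed = TRUE),
    double = list(what = "numeric", size = 8L, signed = TRUE),
    uchar = , `unsigned char` = , uint8 = ,
    uint8_t = list(what = "integer", size = 1L, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
    int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
    stop("unsupported NRRD type: ", hdr$type))
  n <- prod(dims)
  enc <- hdr$encoding
  if (identical(enc, "raw")) {
    raw <- readBin(con, type$what, n = n, size = type$size,
                   signed = type$signed, endian = "little")
  } else if (enc %in% c("gzip", "gz")) {
    blob <- readBin(con, "raw", n = file.size(path))
    gcon <- gzcon(rawConnection(blob))
    on.exit(close(gcon), add = TRUE)
    raw <- readBin(gcon, type$what, n = n, size = type$size,
                   signed = type$signed, endian = "little")
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(raw) != n) stop("NRRD data shorter than sizes in ", path)
  list(data = array(as.numeric(raw), dims), spacing = spacing, origin = origin)
}

write_nrrd <- function(data, spacing, origin, path, uchar = FALSE) {
  dims <- dim(data)
  hdr <- c("NRRD0004",
           "# written by the picasso package",
           paste("type:", if (uchar) "uchar" else "float"),
           "dimension: 3",
           paste("sizes:", paste(dims, collapse = " ")),
           paste("spacings:", paste(format(spacing, trim = TRUE), collapse = " ")),
           paste0("space origin: (", paste(format(origin, trim = TRUE),
                                           collapse = ","), ")"),
           "endian: little",
           "encoding: raw",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  payload <- if (uchar) as.integer(data) else as.numeric(data)
  writeBin(payload, con, size = if (uchar) 1L else 4L, endian = "little")
  invisible(path)
}

#' Write a skeleton or airway graph to GraphML
#'
#' Exports node positions, appearance values and radii together with edge
#' lengths (mm) and a graph-level directedness flag, so segmentation graphs
#' can be inspected in external graph tools.
#'
#' @param graph A [skeleton_graph] or [airway_graph] object.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path) {
  g <- if (inherits(graph, c("skeleton_graph", "airway_graph"))) graph$graph
       else graph
  if (!igraph::is_igraph(g)) stop("not a graph object")
  igraph::graph_attr(g, "directed") <- igraph::is_directed(g)
  # GraphML holds scalar attributes only; drop voxel chains and other
  # non-atomic payloads
  for (a in igraph::edge_attr_names(g))
    if (!is.atomic(igraph::edge_attr(g, a)))
      g <- igraph::delete_edge_attr(g, a)
  for (a in igraph::graph_attr_names(g))
    if (!is.atomic(igraph::graph_attr(g, a)) ||
        length(igraph::graph_attr(g, a)) != 1L)
      g <- igraph::delete_graph_attr(g, a)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML graph written by [write_graph_file()]
#'
#' @param path Path to a `.graphml` file.
#' @return An igraph object.
#' @export
read_graph_file <- function(path) {
  if (!file.exists(path)) stop("cannot read graph, no such file: ", path)
  igraph::read_graph(path, format = "graphml")
}
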