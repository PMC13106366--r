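# Readers and writers for the two interchange formats the pipeline touches:
# PLY (element vertex with x,y,z[,red,green,blue][,nx,ny,nz], ASCII or
# binary little-endian) and PCD v0.7 ASCII. Instance labels travel in a CSV
# sidecar with header `point_index,label`, point_index 0-based.

.ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

.ply_is_float <- function(type) type %in% c("float", "float32", "double", "float64")
.ply_is_signed <- function(type) type %in% c("char", "int8", "short", "int16", "int", "int32")

#' Read the vertex table of a PLY file
#'
#' Low-level reader returning every per-vertex property as a column of a
#' data frame. Handles ASCII and binary little-endian PLY; the vertex
#' element must be the first data element (true of this package's writer
#' and of Gaussian-splat scene exports).
#'
#' @param path PLY file path.
#' @return data.frame with one column per vertex property.
#' @export
read_ply_vertices <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("malformed header: not a PLY file")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed header: no end_header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- length(elements) + 1L
      elements[[cur]] <- list(name = tok[2], count = as.integer(tok[3]),
                              types = character(), names = character())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        elements[[cur]]$types <- c(elements[[cur]]$types, "list")
        elements[[cur]]$names <- c(elements[[cur]]$names, tok[5])
      } else {
        elements[[cur]]$types <- c(elements[[cur]]$types, tok[2])
        elements[[cur]]$names <- c(elements[[cur]]$names, tok[3])
      }
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (is.null(fmt) || !length(elements)) stop("malformed header")
  if (!identical(elements[[1]]$name, "vertex"))
    stop("first PLY element must be 'vertex'")
  el <- elements[[1]]
  if (any(el$types == "list")) stop("list properties unsupported for vertex")
  n <- el$count
  p <- length(el$names)

  if (fmt == "ascii") {
    vals <- scan(con, what = double(), n = n * p, quiet = TRUE)
    if (length(vals) < n * p) stop("malformed PLY: truncated vertex data")
    m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
    out <- as.data.frame(m)
    names(out) <- el$names
    return(out)
  }
  if (fmt != "binary_little_endian")
    stop("unsupported PLY format: ", fmt)

  sizes <- .ply_type_size[el$types]
  if (anyNA(sizes)) stop("unknown PLY property type")
  stride <- sum(sizes)
  bytes <- readBin(con, "raw", n = n * stride)
  if (length(bytes) < n * stride) stop("malformed PLY: truncated vertex data")
  offs <- c(0L, cumsum(sizes))[seq_len(p)]
  out <- vector("list", p)
  rec0 <- (seq_len(n) - 1L) * stride
  for (j in seq_len(p)) {
    w <- sizes[j]
    sel <- rep(rec0, each = w) + rep(seq_len(w) + offs[j], times = n)
    bj <- bytes[sel]
    ty <- el$types[j]
    out[[j]] <- if (.ply_is_float(ty)) {
      readBin(bj, "double", n = n, size = w, endian = "little")
    } else if (w == 4L) {
      readBin(bj, "integer", n = n, size = 4L, endian = "little")
    } else {
      readBin(bj, "integer", n = n, size = w, endian = "little",
              signed = .ply_is_signed(ty))
    }
  }
  names(out) <- el$names
  as.data.frame(out)
}

#' Read a point cloud from PLY or PCD
#'
#' Colors default to mid-gray (0.5, 0.5, 0.5) when the file carries none;
#' 8-bit colors are rescaled to \[0, 1\]. If `label_path` is given, instance
#' labels are attached from the sidecar (points not listed get label 0).
#'
#' @param path file path ending in `.ply` or `.pcd`.
#' @param label_path optional CSV sidecar with header `point_index,label`
#'   (0-based indices).
#' @return a [point_cloud].
#' @export
read_point_cloud <- function(path, label_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    v <- read_ply_vertices(path)
    need <- c("x", "y", "z")
    if (!all(need %in% names(v))) stop("PLY vertex lacks x/y/z")
    pts <- cbind(v$x, v$y, v$z)
    cols <- NULL
    if (all(c("red", "green", "blue") %in% names(v))) {
      cols <- cbind(v$red, v$green, v$blue)
      if (max(cols) > 1 + 1e-9) cols <- cols / 255
    }
    nrms <- NULL
    if (all(c("nx", "ny", "nz") %in% names(v))) {
      nrms <- cbind(v$nx, v$ny, v$nz)
      len <- sqrt(rowSums(nrms^2))
      len[len == 0] <- 1
      nrms <- nrms / len
    }
    pc <- point_cloud(pts, cols, normals = nrms)
  } else if (ext == "pcd") {
    pc <- read_pcd(path)
  } else {
    stop("unsupported extension: .", ext, " (want .ply or .pcd)")
  }
  if (!is.null(label_path)) {
    pc$labels <- read_label_sidecar(label_path, n_points(pc))
  }
  pc
}

#' Write a point cloud to PLY (optionally with a label sidecar)
#'
#' @param cloud non-empty [point_cloud].
#' @param path output `.ply` path.
#' @param with_labels write `<path sans ext>_labels.csv` when the cloud
#'   carries labels.
#' @param format `"binary"` (little-endian, default) or `"ascii"`.
#' @return character vector of the file path(s) written.
#' @export
write_point_cloud <- function(cloud, path, with_labels = FALSE,
                              format = c("binary", "ascii")) {
  format <- match.arg(format)
  if (n_points(cloud) == 0L) stop("refusing to write an empty point cloud")
  n <- n_points(cloud)
  has_n <- !is.null(cloud$normals)
  props <- c("x", "y", "z", if (has_n) c("nx", "ny", "nz"),
             "red", "green", "blue")
  col8 <- round(pmin(pmax(cloud$colors, 0), 1) * 255)

  header <- c(
    "ply",
    paste("format", if (format == "binary") "binary_little_endian" else "ascii",
          "1.0"),
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (has_n) c("property float nx", "property float ny", "property float nz"),
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header"
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    num <- cloud$points
    if (has_n) num <- cbind(num, cloud$normals)
    lines <- paste(
      apply(num, 1L, function(r) paste(sprintf("%.8g", r), collapse = " ")),
      col8[, 1], col8[, 2], col8[, 3]
    )
    writeLines(lines, con, sep = "\n")
  } else {
    fl <- cloud$points
    if (has_n) fl <- cbind(fl, cloud$normals)
    nf <- ncol(fl)
    stride <- 4L * nf + 3L
    fbytes <- writeBin(as.vector(t(fl)), raw(), size = 4L, endian = "little")
    rec <- raw(n * stride)
    rec0 <- (seq_len(n) - 1L) * stride
    sel <- rep(rec0, each = 4L * nf) + rep(seq_len(4L * nf), times = n)
    rec[sel] <- fbytes
    for (c3 in 1:3) {
      rec[rec0 + 4L * nf + c3] <- as.raw(col8[, c3])
    }
    writeBin(rec, con)
  }
  out <- path
  if (with_labels && !is.null(cloud$labels)) {
    lp <- paste0(tools::file_path_sans_ext(path), "_labels.csv")
    write_label_sidecar(cloud$labels, lp)
    out <- c(out, lp)
  }
  out
}

#' Read a label sidecar CSV
#' @param path CSV with header `point_index,label`, 0-based indices.
#' @param n number of points in the target cloud.
#' @return integer label vector of length `n` (unlisted points get 0).
#' @export
read_label_sidecar <- function(path, n) {
  d <- read.csv(path)
  if (!all(c("point_index", "label") %in% names(d)))
    stop("sidecar must have columns point_index,label")
  idx <- as.integer(d$point_index)
  if (anyDuplicated(idx)) stop("sidecar indices must be unique")
  if (any(idx < 0L) || any(idx >= n))
    stop("sidecar index out of range [0, ", n - 1L, "]")
  labels <- integer(n)
  labels[idx + 1L] <- as.integer(d$label)
  labels
}

#' Write a label sidecar CSV
#' @param labels integer label vector.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_sidecar <- function(labels, path) {
  d <- data.frame(point_index = seq_along(labels) - 1L,
                  label = as.integer(labels))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- PCD v0.7 ASCII ---------------------------------------------------------

pack_rgb_float <- function(colors) {
  col8 <- round(pmin(pmax(colors, 0), 1) * 255)
  ints <- as.integer(col8[, 1]) * 65536L + as.integer(col8[, 2]) * 256L +
    as.integer(col8[, 3])
  readBin(writeBin(ints, raw(), size = 4L, endian = "little"),
          "double", n = length(ints), size = 4L, endian = "little")
}

unpack_rgb_float <- function(x) {
  ints <- readBin(writeBin(x, raw(), size = 4L, endian = "little"),
                  "integer", n = length(x), size = 4L, endian = "little")
  unpack_rgb_int(ints)
}

unpack_rgb_int <- function(ints) {
  r <- ints %/% 65536L %% 256L
  g <- ints %/% 256L %% 256L
  b <- ints %% 256L
  cbind(r, g, b) / 255
}

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  hdr_keys <- c("FIELDS", "SIZE", "TYPE", "COUNT", "WIDTH", "HEIGHT",
                "VIEWPOINT", "POINTS", "DATA", "VERSION")
  is_hdr <- grepl(paste0("^(", paste(hdr_keys, collapse = "|"), ")\\b"), lines)
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, key)]
    if (!length(ln)) return(NULL)
    strsplit(trimws(ln[1]), "\\s+")[[1]][-1]
  }
  fields <- get("FIELDS")
  if (is.null(fields)) stop("malformed header: PCD without FIELDS")
  data_mode <- get("DATA")
  if (!identical(tolower(data_mode), "ascii"))
    stop("only ASCII PCD is supported")
  npts <- as.integer(get("POINTS")[1])
  types <- get("TYPE")
  vals <- scan(text = body, what = double(), quiet = TRUE)
  m <- matrix(vals, ncol = length(fields), byrow = TRUE)
  if (nrow(m) != npts) stop("malformed PCD: point count mismatch")
  colnames(m) <- fields
  pts <- m[, c("x", "y", "z"), drop = FALSE]
  cols <- NULL
  if ("rgb" %in% fields) {
    ti <- which(fields == "rgb")
    ty <- if (!is.null(types)) types[ti] else "F"
    cols <- if (identical(ty, "U")) unpack_rgb_int(as.integer(m[, "rgb"]))
            else unpack_rgb_float(m[, "rgb"])
  } else if (all(c("red", "green", "blue") %in% fields)) {
    cols <- m[, c("red", "green", "blue"), drop = FALSE]
    if (max(cols) > 1 + 1e-9) cols <- cols / 255
  }
  point_cloud(pts, cols)
}

#' Write a point cloud to PCD v0.7 ASCII
#'
#' Colors are stored in the PCL packed-`rgb` float field.
#'
#' @param cloud non-empty [point_cloud].
#' @param path output `.pcd` path.
#' @return `path`, invisibly.
#' @export
write_pcd <- function(cloud, path) {
  if (n_points(cloud) == 0L) stop("refusing to write an empty point cloud")
  n <- n_points(cloud)
  rgb <- pack_rgb_float(cloud$colors)
  hdr <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    "FIELDS x y z rgb",
    "SIZE 4 4 4 4",
    "TYPE F F F F",
    "COUNT 1 1 1 1",
    sprintf("WIDTH %d", n),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    sprintf("POINTS %d", n),
    "DATA ascii"
  )
  body <- paste(sprintf("%.8g", cloud$points[, 1]),
                sprintf("%.8g", cloud$points[, 2]),
                sprintf("%.8g", cloud$points[, 3]),
                sprintf("%.9e", rgb))
  writeLines(c(hdr, body), path)
  invisible(path)
}
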