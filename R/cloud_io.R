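#' Load a point cloud from disk
#'
#' Supported dialects: PLY (ASCII and binary-little-endian, `element vertex`
#' with `x/y/z` float or double properties and optional `red/green/blue`
#' uchar), PCD v0.7 ASCII (`FIELDS x y z` plus an optional packed 24-bit
#' decimal `rgb` field), and whitespace-separated XYZ text with 3 (x y z) or
#' 6 (x y z r g b) columns. PLY carries no unit metadata; coordinates are
#' taken to be meters throughout.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`; `"auto"`
#'   dispatches on the file extension.
#' @return a [point_cloud()].
#' @export
load_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_input("file not found: %s", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", pcd = "pcd",
                     xyz = "xyz", txt = "xyz",
                     abort_input("cannot infer format from extension of %s", path))
  }
  switch(format,
         ply = read_ply(path),
         pcd = read_pcd(path),
         xyz = read_xyz(path))
}

#' Write a point cloud to disk
#'
#' Inverse of [load_cloud()]: the written file parses back to an equal cloud
#' within the numeric precision of the dialect. PLY is written
#' binary-little-endian with float32 coordinates by default (the round-trip
#' precision bound); `binary = FALSE` selects ASCII PLY with full
#' double precision.
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`.
#' @param binary write binary PLY (ignored for other formats).
#' @return the path, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                        binary = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", pcd = "pcd",
                     xyz = "xyz", txt = "xyz",
                     abort_input("cannot infer format from extension of %s", path))
  }
  switch(format,
         ply = write_ply(cloud, path, binary = binary),
         pcd = write_pcd(cloud, path),
         xyz = write_xyz(cloud, path))
  invisible(path)
}

# ---- numeric text table parsing shared by the ASCII dialects ----------------

parse_numeric_rows <- function(lines, n_cols, path, line_offset = 0L) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_input("%s contains zero points", path)
  sp <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(sp)
  bad <- which(lens != n_cols)
  if (length(bad) > 0L)
    abort_input("%s: line %d has %d fields, expected %d",
                path, bad[1] + line_offset, lens[bad[1]], n_cols)
  vals <- suppressWarnings(as.numeric(unlist(sp, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    abort_input("%s: non-numeric value on line %d",
                path, ceiling(bad / n_cols) + line_offset)
  }
  matrix(vals, ncol = n_cols, byrow = TRUE)
}

# ---- PLY --------------------------------------------------------------------

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr_end <- grepRaw("end_header\n", raw, fixed = TRUE)
  if (length(hdr_end) == 0L) abort_input("%s: no PLY end_header found", path)
  hdr_len <- hdr_end[1] + nchar("end_header\n") - 1L
  header <- strsplit(rawToChar(raw[seq_len(hdr_len)]), "\n", fixed = TRUE)[[1]]
  header <- sub("\r$", "", header)
  if (!identical(header[1], "ply")) abort_input("%s: missing 'ply' magic", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) abort_input("%s: missing format line", path)
  fmt <- strsplit(fmt_line, " +")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    abort_input("%s: unsupported PLY format '%s'", path, fmt)

  vert_i <- grep("^element vertex ", header)
  if (length(vert_i) != 1L) abort_input("%s: expected one 'element vertex'", path)
  n <- as.integer(strsplit(header[vert_i], " +")[[1]][3])
  if (is.na(n) || n < 1L) abort_input("%s contains zero points", path)
  other_elem <- setdiff(grep("^element ", header), vert_i)
  if (any(other_elem > vert_i))
    abort_input("%s: only 'element vertex' is supported", path)

  prop_lines <- header[seq(vert_i + 1L, length(header))]
  prop_lines <- prop_lines[grepl("^property ", prop_lines)]
  props <- do.call(rbind, strsplit(prop_lines, " +"))
  if (is.null(props) || nrow(props) < 3L)
    abort_input("%s: vertex element lacks x/y/z properties", path)
  types <- props[, 2]
  names_ <- props[, 3]
  coord_ok <- identical(names_[1:3], c("x", "y", "z")) &&
    all(types[1:3] %in% c("float", "float32", "double", "float64")) &&
    length(unique(types[1:3])) == 1L
  if (!coord_ok)
    abort_input("%s: vertex properties must start with x, y, z of one float type", path)
  has_color <- FALSE
  if (nrow(props) > 3L) {
    extra <- nrow(props) - 3L
    if (extra == 3L && identical(names_[4:6], c("red", "green", "blue")) &&
        all(types[4:6] %in% c("uchar", "uint8"))) {
      has_color <- TRUE
    } else {
      abort_input("%s: unsupported vertex properties beyond x/y/z[/red/green/blue]", path)
    }
  }
  coord_size <- if (types[1] %in% c("float", "float32")) 4L else 8L

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw[(hdr_len + 1L):length(raw)]), "\n", fixed = TRUE)[[1]]
    m <- parse_numeric_rows(body, if (has_color) 6L else 3L, path,
                            line_offset = length(header))
    if (nrow(m) != n)
      abort_input("%s: header declares %d vertices but %d rows found", path, n, nrow(m))
    return(point_cloud(m[, 1:3, drop = FALSE],
                       if (has_color) m[, 4:6, drop = FALSE] else NULL))
  }

  rec <- 3L * coord_size + if (has_color) 3L else 0L
  body <- raw[(hdr_len + 1L):length(raw)]
  if (length(body) < as.numeric(rec) * n)
    abort_input("%s: truncated binary vertex data", path)
  starts <- (seq_len(n) - 1L) * rec
  pts <- matrix(0, n, 3)
  for (j in 1:3) {
    off <- (j - 1L) * coord_size
    idx <- as.vector(outer(seq_len(coord_size), starts + off, `+`))
    pts[, j] <- readBin(body[idx], "numeric", size = coord_size, n = n,
                        endian = "little")
  }
  colors <- NULL
  if (has_color) {
    colors <- matrix(0L, n, 3)
    for (j in 1:3) {
      off <- 3L * coord_size + (j - 1L)
      colors[, j] <- as.integer(body[starts + off + 1L])
    }
  }
  point_cloud(pts, colors)
}

write_ply <- function(cloud, path, binary = TRUE) {
  n <- n_points(cloud)
  has_color <- !is.null(cloud$colors)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", n),
    if (binary) c("property float x", "property float y", "property float z")
    else c("property double x", "property double y", "property double z"),
    if (has_color) c("property uchar red", "property uchar green",
                     "property uchar blue"),
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  if (binary) {
    # interleave records: per point 3 float32 (+ 3 uchar)
    coord_raw <- writeBin(as.vector(t(cloud$points)), raw(), size = 4L,
                          endian = "little")
    coord_raw <- matrix(coord_raw, nrow = 12L)
    if (has_color) {
      col_raw <- matrix(as.raw(t(cloud$colors)), nrow = 3L)
      rec <- rbind(coord_raw, col_raw)
    } else {
      rec <- coord_raw
    }
    writeBin(as.vector(rec), con)
  } else {
    rows <- apply(cloud$points, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
    if (has_color)
      rows <- paste(rows, apply(cloud$colors, 1, paste, collapse = " "))
    writeBin(charToRaw(paste0(paste(rows, collapse = "\n"), "\n")), con)
  }
  invisible(path)
}

# ---- PCD --------------------------------------------------------------------

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  di <- grep("^DATA ", lines)
  if (length(di) != 1L) abort_input("%s: missing DATA line in PCD header", path)
  header <- lines[seq_len(di)]
  get_field <- function(key) {
    l <- grep(paste0("^", key, " "), header, value = TRUE)
    if (length(l) != 1L) abort_input("%s: missing %s in PCD header", path, key)
    strsplit(l, " +")[[1]][-1]
  }
  if (!identical(get_field("DATA"), "ascii"))
    abort_input("%s: only ASCII PCD is supported", path)
  fields <- get_field("FIELDS")
  n <- as.integer(get_field("POINTS")[1])
  if (is.na(n) || n < 1L) abort_input("%s contains zero points", path)
  has_color <- FALSE
  if (identical(fields, c("x", "y", "z"))) {
    k <- 3L
  } else if (identical(fields, c("x", "y", "z", "rgb"))) {
    k <- 4L
    has_color <- TRUE
  } else {
    abort_input("%s: unsupported PCD fields (%s)", path, paste(fields, collapse = " "))
  }
  m <- parse_numeric_rows(lines[-seq_len(di)], k, path, line_offset = di)
  if (nrow(m) != n)
    abort_input("%s: header declares %d points but %d rows found", path, n, nrow(m))
  colors <- NULL
  if (has_color) {
    packed <- as.integer(round(m[, 4]))
    colors <- cbind(packed %/% 65536L, (packed %/% 256L) %% 256L, packed %% 256L)
  }
  point_cloud(m[, 1:3, drop = FALSE], colors)
}

write_pcd <- function(cloud, path) {
  n <- n_points(cloud)
  has_color <- !is.null(cloud$colors)
  fields <- if (has_color) "x y z rgb" else "x y z"
  k <- if (has_color) 4L else 3L
  header <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    paste("FIELDS", fields),
    paste("SIZE", paste(rep("4", k), collapse = " ")),
    paste("TYPE", paste(rep("F", k), collapse = " ")),
    paste("COUNT", paste(rep("1", k), collapse = " ")),
    sprintf("WIDTH %d", n),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    sprintf("POINTS %d", n),
    "DATA ascii")
  rows <- apply(cloud$points, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  if (has_color) {
    packed <- cloud$colors[, 1] * 65536L + cloud$colors[, 2] * 256L + cloud$colors[, 3]
    rows <- paste(rows, packed)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---- XYZ --------------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_input("%s contains zero points", path)
  k <- length(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
  if (!k %in% c(3L, 6L))
    abort_input("%s: XYZ rows must have 3 (x y z) or 6 (x y z r g b) columns", path)
  m <- parse_numeric_rows(lines, k, path)
  point_cloud(m[, 1:3, drop = FALSE],
              if (k == 6L) m[, 4:6, drop = FALSE] else NULL)
}

write_xyz <- function(cloud, path) {
  rows <- apply(cloud$points, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  if (!is.null(cloud$colors))
    rows <- paste(rows, apply(cloud$colors, 1, paste, collapse = " "))
  writeLines(rows, path)
  invisible(path)
}
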