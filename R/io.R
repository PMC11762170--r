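#' Read and write sparse voxel coordinate tables
#'
#' The coordinate CSV holds one occupied voxel per row in columns
#' `x, y, z` (0-based), preceded by a comment line `# dims: nx ny nz`
#' recording the volume dimensions. [read_voxel_coords()] accepts files
#' without the dims line if `dims` is supplied.
#'
#' @param grid A [voxel_grid].
#' @param path File path.
#' @return `write_voxel_coords()` returns `path` invisibly;
#'   `read_voxel_coords()` returns a [voxel_grid].
#' @export
write_voxel_coords <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  d <- dim(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims: %d %d %d", d[1], d[2], d[3]), con)
  df <- as.data.frame(occupied_coords(grid) - 1L)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voxel_coords
#' @param dims Volume dimensions; required when the file lacks a
#'   `# dims:` header line.
#' @export
read_voxel_coords <- function(path, dims = NULL) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("dims:\\s*(\\d+)\\s+(\\d+)\\s+(\\d+)", lines[1]))[[1]]
    if (length(m) != 4) {
      stop("line 1: malformed dims header: ", lines[1], call. = FALSE)
    }
    dims <- as.integer(m[2:4])
    lines <- lines[-1]
  }
  if (is.null(dims)) {
    stop("file has no dims header; supply `dims`", call. = FALSE)
  }
  df <- read.csv(text = lines)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("coordinate file must have columns x, y, z", call. = FALSE)
  }
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      bad <- which(!is.numeric(v) | is.na(v) | v != round(v))[1]
      stop(sprintf("non-integer value in column %s, data row %d", col, bad),
           call. = FALSE)
    }
  }
  if (nrow(df) == 0) return(voxel_grid(dims))
  voxel_grid(dims, coords = as.matrix(df[, need]) + 1L)
}

#' Read and write dense volume files
#'
#' A small self-describing plain-text container for dense binary volumes:
#' the first line is `nx ny nz`, followed by `nz * ny` lines of `nx`
#' space-separated 0/1 values (x fastest, then y, then z).
#'
#' @param grid A [voxel_grid].
#' @param path File path.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [voxel_grid].
#' @export
write_volume <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  d <- dim(grid)
  arr <- unclass(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(d, collapse = " "), con)
  for (z in seq_len(d[3])) {
    writeLines(apply(arr[, , z, drop = FALSE], 2,
                     function(col) paste(col, collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty volume file", call. = FALSE)
  d <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(d) != 3 || any(is.na(d)) || any(d < 1)) {
    stop("line 1: expected three positive integers (nx ny nz)", call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) != d[2] * d[3]) {
    stop(sprintf("expected %d data lines, found %d", d[2] * d[3], length(body)),
         call. = FALSE)
  }
  vals <- suppressWarnings(
    as.integer(unlist(strsplit(trimws(body), "\\s+")))
  )
  if (length(vals) != prod(d)) {
    stop(sprintf("expected %d values, found %d", prod(d), length(vals)),
         call. = FALSE)
  }
  if (any(is.na(vals)) || !all(vals %in% c(0L, 1L))) {
    bad <- which(is.na(vals) | !(vals %in% c(0L, 1L)))[1]
    stop(sprintf("non-binary value at position %d (line %d)",
                 bad, 1 + ceiling(bad / d[1])), call. = FALSE)
  }
  as_voxel_grid(array(vals, dim = d))
}

#' Read and write ascii PLY point clouds
#'
#' Minimal ascii PLY support: a `vertex` element with float properties
#' `x`, `y`, `z` and, when the cloud is labeled, an additional string-free
#' `uchar` property `positive` (1/0). Coordinates are 0-based geometric
#' coordinates, matching [to_point_cloud()].
#'
#' @param cloud A [point_cloud].
#' @param path File path.
#' @return `write_ply()` returns `path` invisibly; `read_ply()` returns a
#'   [point_cloud].
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  labeled <- !is.null(cloud$label)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              if (labeled) "property uchar positive",
              "end_header")
  body <- character(0)
  if (n > 0) {
    body <- apply(cloud$points, 1, paste, collapse = " ")
    if (labeled) {
      body <- paste(body, as.integer(cloud$label == "positive"))
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply") {
    stop("line 1: not an ascii PLY file", call. = FALSE)
  }
  if (!grepl("^format ascii", lines[2])) {
    stop("line 2: only ascii PLY is supported", call. = FALSE)
  }
  endh <- which(lines == "end_header")[1]
  if (is.na(endh)) stop("missing end_header", call. = FALSE)
  header <- lines[seq_len(endh)]
  vline <- grep("^element vertex ", header, value = TRUE)
  if (length(vline) != 1) {
    stop("header must declare exactly one vertex element", call. = FALSE)
  }
  n <- as.integer(sub("^element vertex ", "", vline))
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  if (!identical(props[1:3], c("x", "y", "z"))) {
    stop("vertex properties must start with x, y, z", call. = FALSE)
  }
  labeled <- "positive" %in% props
  body <- lines[seq(endh + 1, length.out = n)]
  if (length(body) != n || any(is.na(body))) {
    stop(sprintf("expected %d vertex records after the header", n),
         call. = FALSE)
  }
  if (n == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  toks <- strsplit(trimws(body), "\\s+")
  nf <- lengths(toks)
  if (any(nf < length(props))) {
    bad <- which(nf < length(props))[1]
    stop(sprintf("line %d: truncated vertex record", endh + bad), call. = FALSE)
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(toks, `[`, 1:3))), ncol = 3, byrow = TRUE)
  )
  if (any(is.na(num))) {
    bad <- which(apply(is.na(num), 1, any))[1]
    stop(sprintf("line %d: non-numeric coordinate in vertex record %d",
                 endh + bad, bad), call. = FALSE)
  }
  label <- NULL
  if (labeled) {
    li <- which(props == "positive")
    lv <- vapply(toks, `[`, character(1), li)
    label <- ifelse(lv == "1", "positive", "negative")
  }
  point_cloud(num, label = label)
}

#' Read and write XYZ point-cloud text files
#'
#' One point per line, whitespace-separated `x y z` (0-based geometric
#' coordinates).
#'
#' @param cloud A [point_cloud].
#' @param path File path.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` returns a
#'   [point_cloud].
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  body <- if (n_points(cloud) > 0) {
    apply(cloud$points, 1, paste, collapse = " ")
  } else character(0)
  writeLines(body, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  toks <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(toks) != 3)) {
    bad <- which(lengths(toks) != 3)[1]
    stop(sprintf("line %d: expected three coordinates", bad), call. = FALSE)
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 3, byrow = TRUE)
  )
  if (any(is.na(num))) {
    bad <- which(apply(is.na(num), 1, any))[1]
    stop(sprintf("line %d: non-numeric coordinate", bad), call. = FALSE)
  }
  point_cloud(num)
}

#' Write a recognition result as JSON
#'
#' Emits the record `{responses: [13 numbers], predicted, n_centers}`;
#' a `NONE` prediction is written as JSON `null`.
#'
#' @param result An `avs_recognition` from [classify_orientation()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_recognition_json <- function(result, path) {
  stopifnot(inherits(result, "avs_recognition"))
  rec <- list(responses = unname(result$responses),
              predicted = if (is.na(result$predicted)) NULL else result$predicted,
              n_centers = result$n_centers)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Classify a batch of volumes into a results table
#'
#' @param grids A list of [voxel_grid]s.
#' @param params A [cell_params] object.
#' @param ids Optional identifiers (defaults to the list names or indices).
#' @return A data frame with one row per volume: `id`, `predicted`
#'   (template id or `NA`), `n_centers`, and `c1..c13` response columns.
#' @export
recognize_batch <- function(grids, params = cell_params(), ids = NULL) {
  stopifnot(is.list(grids))
  if (is.null(ids)) ids <- if (!is.null(names(grids))) names(grids) else seq_along(grids)
  rows <- lapply(seq_along(grids), function(i) {
    r <- classify_orientation(grids[[i]], params)
    cbind(data.frame(id = ids[i], predicted = r$predicted,
                     n_centers = r$n_centers),
          as.data.frame(as.list(setNames(r$responses, paste0("c", 1:13)))))
  })
  do.call(rbind, rows)
}
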