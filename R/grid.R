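#' Regular grid specification
#'
#' Planar-meter grid with lower-left corner `(xll, yll)`, square cells of
#' side `cell_size`, and cell centers at
#' `(xll + (j - 0.5) * cell_size, yll + (i - 0.5) * cell_size)`. Layers
#' are stored as `nrows x ncols` matrices with row 1 at the *top* (north),
#' matching the ESRI ASCII raster convention.
#'
#' @param xll,yll Lower-left corner (m).
#' @param cell_size Cell side (m), default 1000.
#' @param ncols,nrows Positive cell counts.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(xll, yll, cell_size = 1000, ncols, nrows) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (ncols < 1L || nrows < 1L) stop("ncols and nrows must be >= 1")
  structure(list(xll = as.numeric(xll), yll = as.numeric(yll),
                 cell_size = as.numeric(cell_size),
                 ncols = ncols, nrows = nrows),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d cells of %g m, lower-left (%g, %g)\n",
              x$ncols, x$nrows, x$cell_size, x$xll, x$yll))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' Row-major from the top (north) row, matching the layer matrix layout.
#'
#' @param grid A [grid_spec()].
#' @return Data frame `x, y` with `ncols * nrows` rows.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cx <- grid$xll + (seq_len(grid$ncols) - 0.5) * grid$cell_size
  cy <- grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cell_size
  data.frame(x = rep(cx, times = grid$nrows),
             y = rep(cy, each = grid$ncols))
}

#' Smallest grid covering an extent or a set of wells
#'
#' @param x A wells data frame, or numeric extent
#'   `c(xmin, xmax, ymin, ymax)` (m).
#' @param cell_size Cell side (m), default 1000 (1 km).
#' @param padding Margin added on every side before gridding (m);
#'   defaults to one cell.
#' @return A [grid_spec()] whose cell count is the ceiling of the padded
#'   extent over `cell_size`.
#' @export
make_grid <- function(x, cell_size = 1000, padding = cell_size) {
  if (is.data.frame(x)) {
    if (nrow(x) < 1L) stop("no wells to grid")
    ext <- c(min(x$x), max(x$x), min(x$y), max(x$y))
  } else {
    ext <- as.numeric(x)
    if (length(ext) != 4L) stop("extent must be c(xmin, xmax, ymin, ymax)")
  }
  ext <- ext + c(-padding, padding, -padding, padding)
  if (ext[2L] <= ext[1L] || ext[4L] <= ext[3L])
    stop("empty extent")
  ncols <- max(1L, ceiling((ext[2L] - ext[1L]) / cell_size - 1e-9))
  nrows <- max(1L, ceiling((ext[4L] - ext[3L]) / cell_size - 1e-9))
  grid_spec(ext[1L], ext[3L], cell_size, ncols, nrows)
}

#' @export
print.concentration_grid <- function(x, ...) {
  g <- x$grid
  cat(sprintf("concentration grid (%s): %d x %d cells of %g m\n",
              x$method, g$ncols, g$nrows, g$cell_size))
  cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  conc <- x$layers$conc_ugL
  cat(sprintf("  conc range: %.3g - %.3g ug/L\n", min(conc), max(conc)))
  invisible(x)
}

#' Read and write well tables as CSV
#'
#' The wells dialect has header `well_id,x,y,conc_ugL,censored` with
#' planar-meter coordinates. Malformed files error with the offending
#' line number.
#'
#' @param wells A wells data frame.
#' @param path File path.
#' @return `read_wells()` returns a `wells` data frame.
#' @export
write_wells <- function(wells, path) {
  out <- as.data.frame(wells)[, c("well_id", "x", "y", "conc_ugL",
                                  "censored")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wells
#' @export
read_wells <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "x", "y", "conc_ugL", "censored")
  if (!all(need %in% names(x)))
    stop(sprintf("line 1: wells CSV must have header %s",
                 paste(need, collapse = ",")))
  for (col in c("x", "y", "conc_ugL")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("line %d: non-numeric %s value '%s'",
                   bad[1L] + 1L, col, x[[col]][bad[1L]]))
    x[[col]] <- v
  }
  x$censored <- as.logical(x$censored)
  if (anyNA(x$censored))
    stop(sprintf("line %d: censored flag not TRUE/FALSE",
                 which(is.na(x$censored))[1L] + 1L))
  x <- x[, need]
  class(x) <- c("wells", "data.frame")
  x
}

#' Read and write a single grid layer as an ESRI ASCII raster
#'
#' Standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by rows from north to south.
#'
#' @param values `nrows x ncols` matrix (row 1 = top) ; `NA` written as
#'   the NODATA value.
#' @param grid A [grid_spec()].
#' @param path File path.
#' @param nodata NODATA sentinel (default -9999).
#' @return `read_grid_asc()` returns `list(grid, values)` with NODATA
#'   cells as `NA`.
#' @export
write_grid_asc <- function(values, grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"),
            nrow(values) == grid$nrows, ncol(values) == grid$ncols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncols),
               sprintf("nrows %d", grid$nrows),
               sprintf("xllcorner %.10g", grid$xll),
               sprintf("yllcorner %.10g", grid$yll),
               sprintf("cellsize %.10g", grid$cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1L, function(r)
    paste(formatC(r, format = "g", digits = 15), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: malformed ASCII grid header", i))
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("line 1-6: incomplete ASCII grid header")
  grid <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                    hdr$ncols, hdr$nrows)
  vals <- matrix(NA_real_, grid$nrows, grid$ncols)
  for (i in seq_len(grid$nrows)) {
    row <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[6L + i]), "\\s+")[[1L]]))
    if (length(row) != grid$ncols || anyNA(row))
      stop(sprintf("line %d: expected %d numeric values", 6L + i,
                   grid$ncols))
    vals[i, ] <- row
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  list(grid = grid, values = vals)
}

#' Write all grid layers as one long-format CSV
#'
#' One row per cell with its center coordinates followed by every layer,
#' in the row-major (north first) order of [grid_centers()].
#'
#' @param cgrid A `concentration_grid`.
#' @param path File path.
#' @return `read_grid_csv()` returns a data frame.
#' @export
write_grid_csv <- function(cgrid, path) {
  stopifnot(inherits(cgrid, "concentration_grid"))
  out <- grid_centers(cgrid$grid)
  for (nm in names(cgrid$layers))
    out[[nm]] <- as.numeric(t(cgrid$layers[[nm]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Contiguous same-class zones as GeoJSON polygons
#'
#' Finds 4-connected components of equal classification value and writes
#' each as a GeoJSON Feature whose polygon is the union outline of its
#' cells (outer ring plus holes), with properties `class` and `n_cells`.
#'
#' @param class_values `nrows x ncols` matrix of integer/factor codes
#'   (row 1 = top); `NA` cells belong to no zone.
#' @param grid A [grid_spec()].
#' @param path Output file.
#' @return Invisibly, the number of zones written.
#' @export
write_zones <- function(class_values, grid, path) {
  stopifnot(inherits(grid, "grid_spec"),
            nrow(class_values) == grid$nrows,
            ncol(class_values) == grid$ncols)
  comp <- label_components(class_values)
  cs <- grid$cell_size
  features <- list()
  for (id in seq_len(max(comp, 0, na.rm = TRUE))) {
    cells <- which(comp == id, arr.ind = TRUE)
    if (!nrow(cells)) next
    rings <- cell_union_rings(cells, grid)
    cls <- class_values[cells[1L, 1L], cells[1L, 2L]]
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      properties = list(class = unname(cls), n_cells = nrow(cells)),
      geometry = list(type = "Polygon", coordinates = rings))
  }
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = 10)
  invisible(length(features))
}

# 4-connected components of equal value; returns an integer matrix with
# 0 for NA cells.
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(!is.na(m))) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    val <- m[start]
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[cur] != 0L) next
      lab[cur] <- nxt
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1L]; jj <- j + d[2L]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          idx <- (jj - 1L) * nr + ii
          if (lab[idx] == 0L && !is.na(m[idx]) && m[idx] == val)
            stack <- c(stack, idx)
        }
      }
    }
  }
  lab
}

# Union outline of a set of cells: every cell contributes its four
# counter-clockwise edges; edges shared by two cells cancel; the
# survivors chain into rings. The ring with the largest |area| is the
# outer boundary, the rest are holes. Coordinates in grid units are
# integers, so exact matching is safe.
cell_union_rings <- function(cells, grid) {
  nr <- grid$nrows; cs <- grid$cell_size
  # cell (row i from top, col j): x in [j-1, j], y in [nr - i, nr - i + 1]
  e_from <- character(0); e_to <- character(0)
  key <- function(p) paste(p[, 1L], p[, 2L])
  pts_from <- NULL; pts_to <- NULL
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1L]; j <- cells[k, 2L]
    x0 <- j - 1L; x1 <- j; y0 <- nr - i; y1 <- nr - i + 1L
    corners <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
    pts_from <- rbind(pts_from, corners)
    pts_to <- rbind(pts_to, corners[c(2L, 3L, 4L, 1L), ])
  }
  kf <- key(pts_from); kt <- key(pts_to)
  # an interior edge appears once as a->b and once as b->a
  fwd <- paste(kf, kt); rev <- paste(kt, kf)
  keep <- !(fwd %in% rev)
  pts_from <- pts_from[keep, , drop = FALSE]
  pts_to <- pts_to[keep, , drop = FALSE]
  kf <- kf[keep]; kt <- kt[keep]
  rings <- list()
  used <- rep(FALSE, length(kf))
  repeat {
    s <- which(!used)[1L]
    if (is.na(s)) break
    ring <- list(pts_from[s, ])
    used[s] <- TRUE
    cur <- kt[s]
    while (cur != kf[s]) {
      nxt <- which(!used & kf == cur)[1L]
      if (is.na(nxt)) break  # should not happen for valid unions
      ring[[length(ring) + 1L]] <- pts_from[nxt, ]
      used[nxt] <- TRUE
      cur <- kt[nxt]
    }
    ring[[length(ring) + 1L]] <- ring[[1L]]  # close
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  # to map units
  rings <- lapply(rings, function(r)
    cbind(grid$xll + r[, 1L] * cs, grid$yll + r[, 2L] * cs))
  if (length(rings) > 1L) {
    area <- vapply(rings, function(r) {
      n <- nrow(r)
      abs(sum(r[-n, 1L] * r[-1L, 2L] - r[-1L, 1L] * r[-n, 2L]) / 2)
    }, numeric(1))
    rings <- rings[order(-area)]
  }
  # jsonlite writes an n x 2 matrix as an array of [x, y] pairs
  lapply(rings, unname)
}
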