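# Trait extraction from fused LiDAR + multispectral point clouds.
#
# A plot's point cloud carries per-point geometry (x, y, z in mm; z is
# height above ground, normalization is assumed done upstream) and four
# reflectance bands in [0, 1]: blue, green, red, near-infrared.

pc_cols <- c("x", "y", "z", "b", "g", "r", "nir")

validate_cloud <- function(cloud, require_points = TRUE) {
  if (!is.data.frame(cloud) || !all(pc_cols %in% names(cloud))) {
    stop2(paste0("a point cloud needs columns ", paste(pc_cols, collapse = ", ")),
          "cropmtl_format")
  }
  if (require_points && nrow(cloud) == 0) {
    stop2("point cloud is empty", "cropmtl_empty_input")
  }
  refl <- as.matrix(cloud[, c("b", "g", "r", "nir")])
  bad <- which(rowSums(refl < 0 | refl > 1 | !is.finite(refl)) > 0)
  if (length(bad) > 0) {
    stop2(sprintf("reflectance outside [0, 1] at %d point(s); first rows: %s",
                  length(bad),
                  paste(utils::head(bad, 10), collapse = ", ")),
          "cropmtl_validation")
  }
  invisible(cloud)
}

#' Read a fused point cloud
#'
#' Supports ASCII or binary little-endian PLY with vertex properties
#' x, y, z and blue/green/red/nir (aliases `b`,`g`,`r`, `red`, `green`,
#' `blue`, `near_infrared` accepted), or a CSV/XYZ text file with header
#' `x,y,z,b,g,r,nir`. Coordinates are in mm, reflectances in \[0, 1\].
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"ply"` or `"xyz"`.
#' @return A tibble with columns `x,y,z,b,g,r,nir` (one row per point, in
#'   file order). An empty file yields a zero-row cloud.
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop2(sprintf("file '%s' does not exist", path), "cropmtl_io")
  }
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  }
  cloud <- if (format == "ply") read_ply_cloud(path) else read_xyz_cloud(path)
  validate_cloud(cloud, require_points = FALSE)
  cloud
}

# Band-name aliases accepted in PLY headers / CSV headers.
canon_band <- function(nm) {
  nm <- tolower(nm)
  map <- c(x = "x", y = "y", z = "z",
           b = "b", blue = "b",
           g = "g", green = "g",
           r = "r", red = "r",
           nir = "nir", near_infrared = "nir")
  unname(map[nm])
}

read_xyz_cloud <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(first)) {
    return(tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(numeric(0), 0, 7)), pc_cols)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- canon_band(names(df))
  missing <- setdiff(pc_cols, names(df))
  if (length(missing) > 0) {
    stop2(sprintf("point file '%s' lacks column(s): %s", path,
                  paste(missing, collapse = ", ")),
          "cropmtl_format")
  }
  tibble::as_tibble(df[, pc_cols])
}

read_ply_cloud <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) == 0) {
    return(tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(numeric(0), 0, 7)), pc_cols)))
  }
  if (!identical(trimws(magic), "ply")) {
    stop2(sprintf("'%s' is not a PLY file", path), "cropmtl_format")
  }
  fmt <- NULL
  n_vertex <- NULL
  props <- character(0)
  types <- character(0)
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop2("truncated PLY header", "cropmtl_format")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
    }
    if (tok[1] == "property" && in_vertex) {
      types <- c(types, tok[2])
      props <- c(props, tok[3])
    }
    if (tok[1] == "end_header") break
  }
  cn <- canon_band(props)
  if (anyNA(cn) || length(setdiff(pc_cols, cn)) > 0) {
    stop2(sprintf("PLY vertex properties must include x,y,z,b,g,r,nir; found: %s",
                  paste(props, collapse = ", ")),
          "cropmtl_format")
  }
  np <- length(props)
  if (identical(fmt, "ascii")) {
    vals <- scan(con, what = numeric(), n = n_vertex * np, quiet = TRUE)
    if (length(vals) < n_vertex * np) {
      stop2("PLY body shorter than declared vertex count", "cropmtl_format")
    }
    mat <- matrix(vals, ncol = np, byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    sz <- sizes[types]
    if (anyNA(sz)) {
      stop2("binary PLY supports float/double vertex properties only",
            "cropmtl_format")
    }
    mat <- matrix(NA_real_, n_vertex, np)
    for (i in seq_len(n_vertex)) {
      for (j in seq_len(np)) {
        mat[i, j] <- readBin(con, what = "numeric", n = 1L,
                             size = sz[j], endian = "little")
      }
    }
  } else {
    stop2(sprintf("unsupported PLY format '%s'", fmt), "cropmtl_format")
  }
  df <- as.data.frame(mat)
  names(df) <- cn
  tibble::as_tibble(df[, pc_cols])
}

#' Plot-mean spectral indices of a point cloud
#'
#' Computes per-point indices from the four PlantEye bands and averages over
#' points. Points where an index's denominator is zero are excluded from
#' that index's mean; the exclusion counts are attached as attribute
#' `n_excluded` and reported via a message when nonzero.
#'
#' Formulas: `GNDVI = (NIR - G)/(NIR + G)`; `CVI = (NIR/G) * (R/G)`;
#' `NCPI = (R - B)/(R + B)`; `MCARI = ((NIR - R) - 0.2*(NIR - G)) * (NIR/R)`.
#'
#' @param cloud A point cloud (see [read_point_cloud()]); must be nonempty.
#' @return Named numeric vector `c(GNDVI=, CVI=, NCPI=, MCARI=)` with
#'   attribute `n_excluded`.
#' @export
compute_spectral_indices <- function(cloud) {
  validate_cloud(cloud)
  b <- cloud$b; g <- cloud$g; r <- cloud$r; nir <- cloud$nir
  per_point <- list(
    GNDVI = (nir - g) / (nir + g),
    CVI = (nir / g) * (r / g),
    NCPI = (r - b) / (r + b),
    MCARI = ((nir - r) - 0.2 * (nir - g)) * (nir / r)
  )
  excluded <- vapply(per_point, function(v) sum(!is.finite(v)), integer(1))
  out <- vapply(per_point, function(v) mean(v[is.finite(v)]), numeric(1))
  if (any(excluded > 0)) {
    message(sprintf("excluded points with zero denominators: %s",
                    paste(sprintf("%s=%d", names(excluded), excluded)[excluded > 0],
                          collapse = ", ")))
  }
  attr(out, "n_excluded") <- excluded
  out
}

#' Structural traits of a point cloud
#'
#' `Hmean` is the mean point height and `H99` the 99th percentile of point
#' heights (linear interpolation between order statistics, the default
#' sample-quantile convention). `PLA` (projected leaf area) is the number of
#' occupied xy grid cells times the cell area; `Volume` is the number of
#' occupied xyz voxels times the voxel volume.
#'
#' @param cloud A nonempty point cloud; coordinates in mm.
#' @param grid_cell Ground-grid cell size in mm (default 5).
#' @param voxel Voxel edge length in mm (default 10).
#' @return Named numeric vector `c(Hmean=, H99=, PLA=, Volume=)`; heights in
#'   mm, PLA in m^2, Volume in m^3.
#' @export
compute_structural_traits <- function(cloud, grid_cell = 5, voxel = 10) {
  validate_cloud(cloud)
  if (!is.numeric(grid_cell) || grid_cell <= 0 ||
      !is.numeric(voxel) || voxel <= 0) {
    stop2("grid_cell and voxel must be positive", "cropmtl_invalid_argument")
  }
  z <- cloud$z
  hmean <- mean(z)
  h99 <- unname(stats::quantile(z, 0.99, type = 7))
  gx <- floor(cloud$x / grid_cell)
  gy <- floor(cloud$y / grid_cell)
  n_cells <- nrow(unique(cbind(gx, gy)))
  pla <- n_cells * grid_cell^2 * 1e-6          # mm^2 -> m^2
  vx <- floor(cloud$x / voxel)
  vy <- floor(cloud$y / voxel)
  vz <- floor(cloud$z / voxel)
  n_vox <- nrow(unique(cbind(vx, vy, vz)))
  volume <- n_vox * voxel^3 * 1e-9             # mm^3 -> m^3
  c(Hmean = hmean, H99 = h99, PLA = pla, Volume = volume)
}

#' All eight traits of one plot's point cloud
#'
#' @inheritParams compute_structural_traits
#' @return Named numeric vector over [trait_names()].
#' @export
extract_plot_traits <- function(cloud, grid_cell = 5, voxel = 10) {
  c(compute_spectral_indices(cloud)[trait_names("spectral")],
    compute_structural_traits(cloud, grid_cell, voxel))
}
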