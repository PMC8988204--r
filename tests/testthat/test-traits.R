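write_ascii_ply <- function(path, mat, props = c("x", "y", "z", "blue",
                                                 "green", "red", "nir")) {
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(mat)),
           sprintf("property float %s", props),
           "end_header")
  body <- apply(mat, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
}

write_binary_ply <- function(path, mat, props = c("x", "y", "z", "blue",
                                                  "green", "red", "nir")) {
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(mat)),
           sprintf("property double %s", props),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.vector(t(mat)), con, size = 8, endian = "little")
}

cloud_mat <- function(cloud) as.matrix(cloud[, c("x", "y", "z", "b", "g",
                                                 "r", "nir")])

test_that("ASCII PLY files round-trip", {
  cl <- make_cloud(x = c(1, 2, 3), y = c(4, 5, 6), z = c(10, 20, 30),
                   b = c(0.1, 0.2, 0.3), g = 0.4, r = 0.5, nir = 0.6)
  path <- tempfile(fileext = ".ply")
  write_ascii_ply(path, cloud_mat(cl))
  back <- read_point_cloud(path)
  expect_equal(nrow(back), 3)
  expect_equal(as.matrix(back), cloud_mat(cl), ignore_attr = TRUE)
})

test_that("binary little-endian PLY files round-trip", {
  cl <- make_cloud(x = c(1.5, 2.25), y = c(0, 7), z = c(11, 22),
                   b = 0.25, g = 0.5, r = 0.125, nir = 0.75)
  path <- tempfile(fileext = ".ply")
  write_binary_ply(path, cloud_mat(cl))
  back <- read_point_cloud(path)
  expect_equal(as.matrix(back), cloud_mat(cl), ignore_attr = TRUE)
})

test_that("CSV point files round-trip and are validated", {
  cl <- make_cloud(x = 1:4, y = 1:4, z = c(5, 6, 7, 8))
  path <- tempfile(fileext = ".csv")
  write.csv(cl, path, row.names = FALSE)
  back <- read_point_cloud(path)
  expect_equal(as.matrix(back), cloud_mat(cl), ignore_attr = TRUE)
  # missing column -> format error
  write.csv(cl[, 1:6], path, row.names = FALSE)
  expect_error(read_point_cloud(path), class = "cropmtl_format")
  # reflectance outside [0,1] -> validation error naming rows
  bad <- cl
  bad$nir[2] <- 1.5
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_point_cloud(path), "2", class = "cropmtl_validation")
  # empty file -> empty cloud
  writeLines(character(0), path)
  expect_equal(nrow(read_point_cloud(path)), 0)
  expect_error(read_point_cloud(tempfile()), class = "cropmtl_io")
})

test_that("malformed PLY files raise format errors", {
  path <- tempfile(fileext = ".ply")
  writeLines(c("not a ply", "at all"), path)
  expect_error(read_point_cloud(path), class = "cropmtl_format")
  # too few properties
  write_ascii_ply(path, matrix(1, 1, 6),
                  props = c("x", "y", "z", "blue", "green", "red"))
  expect_error(read_point_cloud(path), class = "cropmtl_format")
  # body shorter than declared
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               sprintf("property float %s",
                       c("x", "y", "z", "blue", "green", "red", "nir")),
               "end_header", "1 1 1 0 0 0 0"), path)
  expect_error(read_point_cloud(path), class = "cropmtl_format")
})

test_that("spectral indices match hand-computed values", {
  one <- make_cloud(1, 1, 1, b = 0.2, g = 0.25, r = 0.2, nir = 0.5)
  idx <- compute_spectral_indices(one)
  expect_equal(unname(idx["GNDVI"]), (0.5 - 0.25) / 0.75)
  # NIR = G -> GNDVI 0; R = B -> NCPI 0
  sym <- make_cloud(1, 1, 1, b = 0.2, g = 0.4, r = 0.2, nir = 0.4)
  idx2 <- compute_spectral_indices(sym)
  expect_equal(unname(idx2["GNDVI"]), 0)
  expect_equal(unname(idx2["NCPI"]), 0)
  # MCARI hand value: NIR=0.6, R=0.2, G=0.3 -> (0.4 - 0.2*0.3) * 3 = 1.02
  mc <- make_cloud(1, 1, 1, b = 0.1, g = 0.3, r = 0.2, nir = 0.6)
  expect_equal(unname(compute_spectral_indices(mc)["MCARI"]), 1.02)
  expect_error(compute_spectral_indices(make_cloud(numeric(0), numeric(0),
                                                   numeric(0))),
               class = "cropmtl_empty_input")
})

test_that("zero-denominator points are excluded with a message", {
  cl <- make_cloud(1:2, 1:2, 1:2, b = 0.2, g = c(0.25, 0), r = 0.2,
                   nir = 0.5)
  expect_message(idx <- compute_spectral_indices(cl), "zero denominators")
  expect_equal(unname(idx["GNDVI"]),
               mean(c((0.5 - 0.25) / 0.75, (0.5 - 0) / 0.5)))
  # CVI needs g > 0 at both points; one excluded
  expect_equal(unname(attr(idx, "n_excluded")["CVI"]), 1)
  expect_equal(unname(idx["CVI"]), (0.5 / 0.25) * (0.2 / 0.25))
})

test_that("structural traits match hand-computed values", {
  cl <- make_cloud(x = c(0, 11, 25, 33), y = c(0, 2, 9, 40),
                   z = c(100, 200, 300, 400))
  tr <- compute_structural_traits(cl, grid_cell = 10, voxel = 10)
  expect_equal(unname(tr["Hmean"]), 250)
  # 4 points in distinct 10 mm xy cells -> PLA = 4e-4 m^2
  expect_equal(unname(tr["PLA"]), 4 * 0.01^2)
  expect_equal(unname(tr["Volume"]), 4 * 0.01^3)
  # H99 with z = 1..100 under the linear-interpolation convention
  cl100 <- make_cloud(x = 1:100, y = 1, z = 1:100)
  expect_equal(unname(compute_structural_traits(cl100)["H99"]), 99.01)
  expect_error(compute_structural_traits(cl, grid_cell = 0),
               class = "cropmtl_invalid_argument")
})

test_that("traits satisfy invariance, equivariance and monotonicity", {
  set.seed(31)
  cl <- make_cloud(x = runif(15, 0, 100), y = runif(15, 0, 100),
                   z = runif(15, 0, 500), b = runif(15, 0.05, 0.3),
                   g = runif(15, 0.1, 0.5), r = runif(15, 0.05, 0.4),
                   nir = runif(15, 0.3, 0.9))
  base_sp <- compute_spectral_indices(cl)
  base_st <- compute_structural_traits(cl)
  # order invariance
  perm <- cl[sample(nrow(cl)), ]
  expect_equal(compute_spectral_indices(perm), base_sp)
  expect_equal(compute_structural_traits(perm), base_st)
  # duplication invariance of spectral means
  expect_equal(compute_spectral_indices(rbind(cl, cl)), base_sp)
  # z scale equivariance of heights
  cl2 <- cl
  cl2$z <- cl2$z * 3
  st2 <- compute_structural_traits(cl2)
  expect_equal(unname(st2["Hmean"]), unname(base_st["Hmean"]) * 3)
  expect_equal(unname(st2["H99"]), unname(base_st["H99"]) * 3)
  # adding a point never decreases PLA or Volume
  plus <- rbind(cl, make_cloud(500, 500, 900))
  stp <- compute_structural_traits(plus)
  expect_gte(unname(stp["PLA"]), unname(base_st["PLA"]))
  expect_gte(unname(stp["Volume"]), unname(base_st["Volume"]))
  # Hmean <= H99 on any cloud
  expect_lte(unname(base_st["Hmean"]), unname(base_st["H99"]))
})

test_that("extract_plot_traits returns all eight traits in order", {
  cl <- make_cloud(x = 1:5, y = 5:1, z = c(10, 40, 20, 80, 60))
  tr <- extract_plot_traits(cl)
  expect_identical(names(tr), trait_names())
  expect_equal(tr[trait_names("spectral")],
               compute_spectral_indices(cl)[trait_names("spectral")])
})
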