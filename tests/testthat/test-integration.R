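test_that("TIC normalization divides each pixel by its total ion count", {
  r <- msi_raster(c(0, 1), c(0, 0), c(100, 200, 300),
                  rbind(c(2, 2, 4), c(1, 1, 2)))
  n <- tic_normalize(r)
  expect_equal(unname(n$intensity[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(rowSums(n$intensity)), c(1, 1), tolerance = 1e-9)
  # idempotent on already-normalized data
  n2 <- tic_normalize(n)
  expect_equal(n2$intensity, n$intensity, tolerance = 1e-12)
})

test_that("zero-TIC pixels are excluded and counted (or fatal on demand)", {
  r <- msi_raster(c(0, 1), c(0, 0), c(100, 200),
                  rbind(c(1, 3), c(0, 0)))
  expect_warning(n <- tic_normalize(r), "zero total ion count")
  expect_equal(nrow(n$pixels), 1L)
  expect_equal(attr(n, "n_zero_tic"), 1L)
  expect_error(tic_normalize(r, on_zero = "error"), "zero total ion count")
})

test_that("pixel matching respects the radius and the barcode tie rule", {
  spots <- physical_points(c("B", "A"), c(100, 0), c(0, 0),
                           frame = "ST_unified")
  px <- structure(
    data.frame(id = c("p1", "p2", "p3"),
               x = c(0, 50, 200), y = c(0, 0, 60)),
    frame = "ST_unified", class = c("physical_points", "data.frame"))
  m <- match_pixels_to_spots(spots, px, radius = 50)
  expect_equal(m$barcode[1], "A")     # exactly at spot A
  expect_equal(m$barcode[2], "A")     # equidistant tie -> smaller barcode
  expect_true(is.na(m$barcode[3]))    # 60 um past every spot at radius 50
  expect_equal(m$distance[2], 50)
  # boundary: exactly at the radius is still assigned
  expect_false(is.na(m$barcode[2]))
  expect_error(match_pixels_to_spots(spots[0, ], px), "empty spot set")
})

test_that("matching partitions pixels and aggregation conserves mass", {
  sc <- synthetic_scenario(seed = 5, landmark_jitter = 0)
  sec <- generate_section_pair(sc)
  norm <- tic_normalize(sec$raster)
  pst <- apply_transform(msi_to_physical(norm), sec$truth$transform)
  m <- match_pixels_to_spots(hex_to_physical(sec$grid), pst)
  expect_equal(sum(!is.na(m$barcode)) + sum(is.na(m$barcode)), nrow(m))
  expect_equal(anyDuplicated(m$pixel_id), 0L)
  mat <- aggregate_spot_metabolites(m, norm)
  expect_equal(sum(!is.na(m$barcode)), nrow(mat$intensity) +
                 sum(mat$n_pixels_per_spot) - nrow(mat$intensity))
  # weighted spot means recover the assigned pixel mass exactly
  assigned <- !is.na(m$barcode)
  expect_equal(sum(mat$intensity * mat$n_pixels_per_spot),
               sum(norm$intensity[match(m$pixel_id[assigned],
                                        norm$pixels$pixel_id), ]),
               tolerance = 1e-9)
  expect_equal(mat$unassigned_pixels, sum(!assigned))
})

test_that("identity transform on coincident grids matches bijectively", {
  # square spot grid laid directly on the pixel raster positions
  px <- expand.grid(mx = 0:4, my = 0:4)
  r <- msi_raster(px$mx, px$my, 100, matrix(1, 25, 1))
  spots <- physical_points(sprintf("s%02d", 1:25),
                           px$mx * 100, px$my * 100, frame = "ST_unified")
  m <- match_pixels_to_spots(spots,
                             structure(as.data.frame(msi_to_physical(r)),
                                       frame = "ST_unified",
                                       class = c("physical_points",
                                                 "data.frame")),
                             radius = 50)
  expect_false(anyNA(m$barcode))
  expect_equal(anyDuplicated(m$barcode), 0L)
  expect_equal(m$distance, rep(0, 25))
})

test_that("aggregation means pixel values per spot", {
  r <- msi_raster(c(0, 1, 2), c(0, 0, 0), c(100),
                  matrix(c(0.2, 0.4, 0.9), 3, 1))
  m <- data.frame(pixel_id = r$pixels$pixel_id,
                  barcode = c("s1", "s1", "s2"),
                  distance = 0)
  mat <- aggregate_spot_metabolites(m, r)
  expect_equal(unname(mat$intensity["s1", ]), 0.3)
  expect_equal(unname(mat$intensity["s2", ]), 0.9)
  expect_equal(mat$n_pixels_per_spot, c(2L, 1L))
  med <- aggregate_spot_metabolites(m, r, statistic = "median")
  expect_equal(unname(med$intensity["s1", ]), 0.3)
})

test_that("cell-type designation applies the literal 70% rule", {
  props <- data.frame(barcode = c("s1", "s2", "s3"),
                      SCT = c(0.8, 0.3, 0.30),
                      VCT = c(0.2, 0.6, 0.00),
                      Fibroblast = c(0.0, 0.1, 0.70))
  ann <- assign_spot_celltype(props)
  expect_equal(ann$cell_type, c("SCT", "SCT", "SCT"))
  expect_equal(ann$rule_used,
               c("dominant_over_70", "second_most_prevalent",
                 "second_most_prevalent"))
  # 0.70 does not EXCEED the threshold, hence the second-most rule above
  two <- assign_spot_celltype(data.frame(barcode = "b", A = 0.70, B = 0.30))
  expect_equal(two$cell_type, "B")
  # conventional argmax mode
  dom <- assign_spot_celltype(props, rule = "dominant")
  expect_equal(dom$cell_type, c("SCT", "VCT", "Fibroblast"))
})

test_that("cell-type designation is invariant to column order", {
  props <- data.frame(barcode = "s1", SCT = 0.5, VCT = 0.3, EVT = 0.2)
  shuffled <- props[, c("VCT", "EVT", "barcode", "SCT")]
  expect_equal(assign_spot_celltype(props)$cell_type,
               assign_spot_celltype(shuffled)$cell_type)
})

test_that("proportion validation catches bad tables", {
  expect_error(assign_spot_celltype(
    data.frame(barcode = "b", A = 0.5, B = 0.4)), "sum to 1")
  expect_error(assign_spot_celltype(
    data.frame(barcode = "b", A = 1.0)), NA)  # dominant branch is fine
  expect_error(assign_spot_celltype(
    data.frame(barcode = "b", A = 1.0), threshold = 1.1),
    ">= 2 cell types")
})

test_that("spot matrix TSV round-trips", {
  sc <- synthetic_scenario(seed = 3)
  g <- generate_group_study(sc)
  prefix <- file.path(tempdir(), "mat_roundtrip")
  write_spot_matrix(g$matrix, prefix)
  back <- read_spot_matrix(paste0(prefix, ".tsv"))
  expect_equal(back$mz_values, g$matrix$mz_values, tolerance = 1e-9)
  expect_equal(unname(back$intensity), unname(g$matrix$intensity),
               tolerance = 1e-6)
})
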