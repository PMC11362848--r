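test_that("rigid transforms form a group under compose/invert", {
  ctr <- c(50, 40)
  t1 <- rigid_transform(12, 5, -3, ctr)
  t2 <- rigid_transform(-7, -2, 8, ctr)
  # compose then apply == apply sequentially
  pts <- cbind(c(0, 10, 33.3), c(0, -4, 21.2))
  expect_equal(transform_points(compose_transforms(t1, t2), pts),
               transform_points(t2, transform_points(t1, pts)),
               tolerance = 1e-12)
  # t composed with its inverse is the identity
  id <- compose_transforms(t1, invert_transform(t1))
  expect_lt(abs(id$rotation_deg), 1e-9)
  expect_lt(abs(id$tx_px) + abs(id$ty_px), 1e-9)
})

test_that("apply_transform: identity, integer shifts, and inverses", {
  m <- outer(1:50, 1:60, function(i, j) 2 + sin(i / 7) + cos(j / 9))
  out <- apply_transform(m, rigid_transform(0, 0, 0))
  expect_equal(unclass(out), m, ignore_attr = TRUE)

  mask <- matrix(FALSE, 40, 40); mask[10:20, 12:25] <- TRUE
  sh <- apply_transform(mask, rigid_transform(0, 3, -2))
  expect_identical(unname(sh[8:18, 15:28]), unname(mask[10:20, 12:25]))

  t1 <- rigid_transform(9, 4.5, -2.2)
  f <- apply_transform(m, t1, "bilinear")
  b <- apply_transform(f, invert_transform(rigid_transform(9, 4.5, -2.2,
                                                           c((60 - 1) / 2, (50 - 1) / 2))),
                       "bilinear")
  interior <- 10:40
  expect_lt(mean(abs(b[interior, interior] - m[interior, interior])),
            0.01 * max(m))
})

test_that("registration is exact on identical masks and recovers known transforms", {
  s <- small_slide()
  fx <- s$truth$tissue_mask
  tr0 <- rigid_register(fx, fx)
  expect_lt(abs(tr0$rotation_deg), 0.1)
  expect_lt(sqrt(tr0$tx_px^2 + tr0$ty_px^2), 0.5)
  expect_gte(attr(tr0, "overlap_after"), 0.999)

  tt <- rigid_transform(5, 10, -7, c((400 - 1) / 2, (400 - 1) / 2))
  mv <- apply_transform(fx, tt, "nearest")
  tr <- rigid_register(mv, fx)
  ti <- invert_transform(tt)
  expect_lt(abs(tr$rotation_deg - ti$rotation_deg), 0.5)
  expect_lt(sqrt((tr$tx_px - ti$tx_px)^2 + (tr$ty_px - ti$ty_px)^2), 1)
  expect_gte(attr(tr, "overlap_after"), attr(tr, "overlap_before"))
})

test_that("registration refuses nearly-empty backbones", {
  a <- matrix(FALSE, 100, 100); a[50, 50] <- TRUE
  b <- matrix(TRUE, 100, 100)
  expect_error(rigid_register(a, b), "insufficient backbone")
})

test_that("polygon rasterization obeys the pixel-center even-odd rule", {
  # rectangle spanning exactly 10 x 10 pixel centers
  ann <- annotation_set(list(list(
    label = "cortex",
    vertices = rbind(c(4.5, 2.5), c(14.5, 2.5), c(14.5, 12.5), c(4.5, 12.5))
  )))
  m <- polygon_to_mask(ann, "cortex", c(20, 20))
  expect_equal(sum(m), 100)
  expect_true(m[4, 6])    # (x=5, y=3) inside
  expect_false(m[3, 6])   # (x=5, y=2) outside

  expect_equal(sum(polygon_to_mask(annotation_set(), "cortex", c(20, 20))), 0)

  full <- annotation_set(list(list(
    label = "cortex",
    vertices = rbind(c(-1, -1), c(20, -1), c(20, 20), c(-1, 20))
  )))
  expect_true(all(polygon_to_mask(full, "cortex", c(20, 20))))

  expect_error(annotation_set(list(list(label = "cortex",
                                        vertices = rbind(c(0, 0), c(1, 1))))),
               "degenerate polygon")
})

test_that("scanner-style XML annotations parse into polygons", {
  xml <- paste0(
    "<annotations><ndpviewstate><title>cortex</title><annotation>",
    "<pointlist>",
    "<point><x>100</x><y>200</y></point>",
    "<point><x>300</x><y>200</y></point>",
    "<point><x>200</x><y>400</y></point>",
    "</pointlist></annotation></ndpviewstate></annotations>"
  )
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  ann <- read_annotation_xml(path, scale_to_map = 0.01)
  expect_equal(length(ann$polygons), 1)
  expect_equal(ann$polygons[[1]]$label, "cortex")
  expect_equal(ann$polygons[[1]]$vertices,
               cbind(c(100, 300, 200), c(200, 200, 400)))
  m <- polygon_to_mask(ann, "cortex", c(6, 6))
  expect_equal(sum(m), sum(point_in_polygon(as.vector(col(m)) - 1,
                                            as.vector(row(m)) - 1,
                                            ann$polygons[[1]]$vertices * 0.01)))
})

test_that("cortex vectors contain exactly the tissue-and-cortex pixels", {
  mk_map <- function(v) structure(list(values = v, um_per_px = 73,
                                       kernel_radius_px = 5L,
                                       kernel_pixel_count = 81, marker = "x"),
                                  class = "density_map")
  set.seed(9)
  v1 <- matrix(runif(30 * 30, 0, 500), 30, 30)
  v2 <- matrix(runif(30 * 30, 0, 100), 30, 30)
  cortex <- matrix(FALSE, 30, 30); cortex[5:25, 8:28] <- TRUE
  tissue <- matrix(FALSE, 30, 30); tissue[1:22, 1:30] <- TRUE
  tbl <- extract_cortex_vectors(list(tumor_cell = mk_map(v1), abeta = mk_map(v2)),
                                cortex, tissue)
  expect_equal(nrow(tbl), sum(cortex & tissue))
  expect_named(tbl, c("pixel_id", "x", "y", "tumor_cell_density", "abeta_density"))
  i <- 17
  expect_equal(tbl$tumor_cell_density[i], v1[tbl$pixel_id[i]])

  expect_equal(nrow(extract_cortex_vectors(list(tumor_cell = mk_map(v1)),
                                           matrix(FALSE, 30, 30), tissue)), 0)

  bad <- mk_map(v1[1:20, 1:20])
  expect_error(extract_cortex_vectors(list(tumor_cell = mk_map(v1), ptau = bad),
                                      cortex, tissue),
               "grid mismatch for marker 'ptau'")
})

test_that("cortex density averages track ground truth counts", {
  # nuclei density averaged over the cortex approximates count / area
  spec <- slide_spec(360, 360, nucleus_count = 250, seed = 21)
  s <- generate_slide(spec)
  cm <- centroid_count_map(s$truth$nucleus_centroids, dim(s$truth$tissue_mask))
  um <- 2
  dm <- density_from_centroids(cm, 25, um, marker = "tumor_cell")
  tis <- s$truth$tissue_mask
  mean_density <- mean(dm$values[tis])
  tissue_area_mm2 <- sum(tis) * (um / 1000)^2
  expect_lt(abs(mean_density * tissue_area_mm2 - 250) / 250, 0.1)
})
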