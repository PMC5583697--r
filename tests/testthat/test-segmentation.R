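test_that("max-entropy threshold equals the brute-force Kapur maximiser", {
  set.seed(31)
  for (i in 1:20) {
    v <- c(rnorm(300, 0.3, 0.05 + 0.1 * runif(1)),
           rnorm(100 + sample(300, 1), 0.75, 0.12))
    img <- matrix(v, nrow = 1)
    for (bins in c(8L, 64L, 256L))
      expect_equal(max_entropy_threshold(img, bins),
                   kapur_brute(v, bins))
  }
})

test_that("threshold separates perfect bimodality and shifts with the data", {
  img <- matrix(rep(c(10, 200), each = 50), 10, 10)
  thr <- max_entropy_threshold(img, 256)
  expect_gt(thr, 10)
  expect_lte(thr, 200)

  set.seed(8)
  img2 <- matrix(c(rnorm(60, 0.3, 0.05), rnorm(40, 0.8, 0.05)), 10, 10)
  t1 <- max_entropy_threshold(img2, 128)
  t2 <- max_entropy_threshold(img2 + 5, 128)
  expect_equal(sum(img2 < t1), sum(img2 + 5 < t2))  # same pixel partition
  expect_equal(t2 - t1, 5, tolerance = 1e-9)

  expect_error(max_entropy_threshold(matrix(1, 5, 5)), "constant")
})

test_that("watershed splits touching discs and reduces to components otherwise", {
  one <- disc_image(c(40, 40), rbind(c(20, 20, 10)))
  w1 <- watershed_split(one, 5)
  expect_equal(max(w1$labels), 1L)
  expect_equal(sum(w1$labels == 1L), sum(one))

  merged <- disc_image(c(40, 60), rbind(c(20, 20, 10), c(20, 34, 10)))
  w2 <- watershed_split(merged, 5)
  expect_equal(max(w2$labels), 2L)
  expect_true(w2$labels[21, 21] > 0 && w2$labels[21, 35] > 0)
  expect_true(w2$labels[21, 21] != w2$labels[21, 35])
  expect_true(all((w2$labels > 0) == merged))  # every fg pixel labelled once

  disjoint <- disc_image(c(40, 60), rbind(c(12, 12, 8), c(28, 45, 8)))
  w3 <- watershed_split(disjoint, 5)
  cc <- EBImage::bwlabel(disjoint)
  expect_equal(max(w3$labels), max(cc))
  expect_error(watershed_split(matrix(FALSE, 5, 5)), "empty")
})

test_that("a dark elliptical nucleus is recovered with IoU >= 0.8", {
  d <- c(80, 80)
  rows <- matrix(0:(d[1] - 1), d[1], d[2])
  cols <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  truth <- ((rows - 40) / 12)^2 + ((cols - 38) / 8)^2 <= 1
  set.seed(5)
  img <- 0.9 - 0.55 * truth + matrix(rnorm(prod(d), sd = 0.03), d[1], d[2])
  mask <- segment_nuclei(img, segmentation_params(min_area_um2 = 20,
                                                  max_area_um2 = 500),
                         pixel_size_um = 0.5)
  expect_equal(max(mask$labels), 1L)
  iou <- sum(truth & mask$labels == 1) / sum(truth | mask$labels == 1)
  expect_gte(iou, 0.8)
})

test_that("segmentation is deterministic and the area gate is monotone", {
  ph <- make_phantom_cube(phantom_spec(dim_px = c(96L, 96L), n_nuclei = 6L,
                                       seed = 12L),
                          small_axis(16))
  p <- segmentation_params()
  m1 <- segment_nuclei(ph$transmission, p, pixel_size_um = 0.5)
  m2 <- segment_nuclei(ph$transmission, p, pixel_size_um = 0.5)
  expect_identical(m1$labels, m2$labels)
  expect_equal(max(m1$labels), 6L)

  # raising min_area never increases the region count
  areas <- c(5, 20, 45, 80)
  counts <- vapply(areas, function(a)
    max(suppressWarnings(segment_nuclei(
      ph$transmission, segmentation_params(min_area_um2 = a), 0.5))$labels),
    integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("a blank image yields an empty mask with a warning", {
  set.seed(2)
  img <- matrix(0.9 + rnorm(400, sd = 0.01), 20, 20)
  expect_warning(m <- segment_nuclei(img, segmentation_params(),
                                     pixel_size_um = 0.5))
  expect_equal(max(m$labels), 0L)
})

test_that("region statistics reduce the L_d map per label", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L
  lab[6:9, 6:9] <- 2L
  mask <- label_mask(lab, pixel_size_um = 2)

  uni <- structure(list(values = matrix(7, 10, 10)), class = "ld_map")
  st <- region_ld_stats(uni, mask)
  expect_equal(st$mean_ld, c(7, 7))

  painted <- matrix(0, 10, 10)
  painted[lab == 1L] <- 1
  painted[lab == 2L] <- 3
  st2 <- region_ld_stats(structure(list(values = painted), class = "ld_map"),
                         mask)
  expect_equal(st2$mean_ld, c(1, 3))
  expect_equal(st2$area_px, c(9L, 16L))
  expect_equal(st2$area_um2, c(36, 64))
  expect_equal(st2$pixel_count_used, st2$area_px)
  expect_equal(st2$centroid_row, c(2, 6.5))  # 0-based centroids

  ann <- region_ld_stats(structure(list(values = painted), class = "ld_map"),
                         mask, annulus_width_px = 2)
  expect_true(all(ann$mean_cellular_ld < ann$mean_ld))  # zero background dilutes

  bad <- structure(list(values = matrix(0, 5, 5)), class = "ld_map")
  expect_error(region_ld_stats(bad, mask), "match")
})

test_that("nuclei carry higher L_d than their perinuclear annulus in phantoms", {
  ax <- small_axis(64)
  kbar <- ax$center_wavenumber
  wins <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    ph <- make_phantom_cube(phantom_spec(dim_px = c(72L, 72L), n_nuclei = 3L,
                                         nucleus_radius_um = 3.5,
                                         seed = 100L + s),
                            ax)
    sm <- compute_sigma_map(ph$cube, poly_order = 1L)
    ld <- sigma_to_ld(sm, 2, ax, "variance")
    st <- region_ld_stats(ld, ph$mask, annulus_width_px = 4)
    if (all(st$mean_ld > st$mean_cellular_ld)) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.95)
})
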