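render_one <- function(x = 8, y = 6, shape = c(120L, 160L)) {
  set <- make_set(data.frame(cell_id = 1L, frame = 0L, x_um = x, y_um = y))
  rp <- render_params(image_shape = shape, psf_sigma = 0, noise_scale = 0)
  render_frames(set, rp)$frames[[1]]
}

test_that("top-hat enhancement suppresses flat background, keeps cells", {
  flat <- matrix(37, 50, 50)
  expect_true(all(enhance_contrast(flat, 11) == 0))

  img <- render_one()
  enh <- enhance_contrast(img, 12)
  inside <- img > 100
  expect_true(all(enh[inside] > 0))
  expect_lt(mean(enh[!inside]), 1)
  # additive offsets are removed entirely
  expect_equal(enhance_contrast(img + 50, 12), enh, tolerance = 1e-9)
  expect_error(enhance_contrast(img, 1000), "dimension")
})

test_that("Otsu thresholding separates a bimodal image and is affine invariant", {
  img <- matrix(10, 40, 40); img[10:20, 10:30] <- 200
  mask <- otsu_binarize(img)
  expect_identical(mask, img == 200)
  expect_identical(otsu_binarize(img * 3.7 + 12), mask)
  expect_error(otsu_binarize(matrix(5, 10, 10)), "constant")
})

test_that("Otsu foreground area tracks the drawn capsule area", {
  set <- make_separated_cohort(n_cells = 8, n_frames = 2, arena_um = 32)
  set <- make_set(set[set$frame == 0, ])
  rp <- render_params(image_shape = c(320L, 320L))
  img <- render_frames(set, rp, seed = 1)$frames[[1]]
  mask <- otsu_binarize(enhance_contrast(img, 12))
  # analytic capsule area: (L - w) * w + pi (w/2)^2, in px
  cell_px <- ((4 - 1) * 1 + pi * 0.25) / 0.1^2
  expect_lt(abs(sum(mask) - 8 * cell_px) / (8 * cell_px), 0.15)
})

test_that("watershed splits touching capsules and conserves foreground", {
  img1 <- render_one()
  mask1 <- img1 > 100
  lbl1 <- watershed_split(mask1, min_area = 20)
  expect_equal(max(lbl1), 1)
  expect_identical(lbl1 > 0, mask1)

  # two collinear capsules overlapping by 20% of their width
  set <- make_set(data.frame(cell_id = 1:2, frame = 0L,
                             x_um = c(8, 11.8), y_um = c(6, 6)))
  rp <- render_params(image_shape = c(120L, 200L), psf_sigma = 0,
                      noise_scale = 0)
  mask2 <- render_frames(set, rp)$frames[[1]] > 100
  lbl2 <- watershed_split(mask2, min_area = 20, min_seed_separation = 3)
  m <- measure_objects(lbl2, 0.1, drop_border = FALSE)
  expect_equal(nrow(m), 2)
  err <- sort(abs(sort(m$x_um) - c(8, 11.8)))
  expect_true(all(err < 0.1))          # within 1 px of the true centroids
  expect_identical(lbl2 > 0, mask2)    # splitting moved no pixels

  empty <- watershed_split(matrix(FALSE, 20, 20))
  expect_equal(max(empty), 0)
})

test_that("equivalent-ellipse measurements match brute-force moments", {
  lbl <- matrix(0L, 60, 80)
  lbl[25:34, 21:60] <- 1L             # 40 px long, 10 px wide, axis = x
  m <- measure_objects(lbl, 0.1, drop_border = FALSE)
  ora <- moments_oracle(lbl, 1, 0.1)
  expect_equal(m$area_um2, 4.0)
  expect_equal(m$orientation_rad, 0)
  expect_equal(m$major_um, ora$major_um, tolerance = 1e-12)
  expect_equal(m$minor_um, ora$minor_um, tolerance = 1e-12)
  expect_equal(m$x_um, ora$x_um)

  # same rectangle rotated 90 degrees: same axes, orientation folded
  lblT <- t(lbl)
  mT <- measure_objects(lblT, 0.1, drop_border = FALSE)
  expect_equal(mT$major_um, m$major_um)
  expect_equal(mT$minor_um, m$minor_um)
  expect_equal(mT$orientation_rad, pi / 2)
})

test_that("orientation is equivariant under image rotation", {
  set.seed(5)
  for (rep in 1:4) {
    ang <- stats::runif(1, -1.2, 1.2)
    set <- make_set(data.frame(cell_id = 1L, frame = 0:1,
                               x_um = c(8, 8 + cos(ang)),
                               y_um = c(6, 6 + sin(ang))))
    rp <- render_params(image_shape = c(120L, 160L), psf_sigma = 0,
                        noise_scale = 0)
    img <- render_frames(set, rp)$frames[[1]]
    lbl <- watershed_split(img > 100)
    th <- measure_objects(lbl, 0.1, drop_border = FALSE)$orientation_rad
    # rotate the image 90 degrees: (r, c) -> (c, nr - 1 - r)
    rot <- t(lbl[nrow(lbl):1, ])
    th_rot <- measure_objects(rot, 0.1, drop_border = FALSE)$orientation_rad
    delta <- (th_rot - th - pi / 2) %% pi
    expect_lt(min(delta, pi - delta), 1e-6)
  }
})

test_that("border-touching objects are flagged and dropped by default", {
  lbl <- matrix(0L, 30, 30)
  lbl[1:5, 10:20] <- 1L      # touches the top border
  lbl[15:20, 10:20] <- 2L
  kept <- measure_objects(lbl, 0.1)
  expect_equal(kept$label, 2L)
  all_objs <- measure_objects(lbl, 0.1, drop_border = FALSE)
  expect_identical(all_objs$border, c(TRUE, FALSE))
  expect_equal(nrow(measure_objects(matrix(0L, 5, 5), 0.1)), 0)
})
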