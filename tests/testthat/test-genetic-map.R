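test_that("rate interpolation is linear with end clamping", {
  m <- genetic_map(c(1, 1001), c(1, 3), c(0, 0.002))
  expect_equal(interpolate_rate(m, 501), 2)
  expect_equal(interpolate_rate(m, 1), 1)      # exact map point
  expect_equal(interpolate_rate(m, 1001), 3)
  expect_equal(interpolate_rate(m, 5000), 3)   # clamp beyond last point
  expect_equal(interpolate_rate(m, -10), 1)    # clamp before first point
})

test_that("window mean rate is delta-cM over delta-bp", {
  # uniform 1 cM/Mb -> 1.0 for any window inside the map
  u <- genetic_map(c(1, 2000001), c(1, 1), c(0, 2))
  expect_equal(mean_window_rate(u, 100000, 100300, flank_bp = 50000), 1,
               tolerance = 1e-9)
  # cumulative 0 -> 0.5 cM over 250 kb spans the window exactly
  m <- genetic_map(c(1, 250001), c(2, 2), c(0, 0.5))
  expect_equal(mean_window_rate(m, 50000, 200001, flank_bp = 50000), 2,
               tolerance = 1e-5)
  expect_error(mean_window_rate(m, 100, 100, flank_bp = 0), "zero width")

  # piecewise map, window covering two rate segments 50/50
  pw <- genetic_map(c(1, 100001, 200001), c(1, 3, 3), c(0, 0.1, 0.4))
  got <- mean_window_rate(pw, 50000, 150000, flank_bp = 0)
  # closed-form segment integration: 50 kb at 1 + 50 kb at 3
  expect_equal(got, (0.05 * 1 + 0.05 * 3) / 0.1, tolerance = 1e-4)
})

test_that("tissue null parameters follow the mean-length / rate rules", {
  omap <- toy_organ_map("brain")
  rs <- region_set("chr1", c(100000, 500000), c(100200, 500400), c("a", "b"),
                   list("brain", "brain"), omap)
  p <- tissue_null_params(rs, for_nsl = FALSE)
  expect_equal(p$length_bp, 300)
  expect_equal(p$recomb_rate, 1e-8)

  u <- genetic_map(c(1, 2000001), c(2, 2), c(0, 4))
  pn <- tissue_null_params(rs, map = u, flank_bp = 50000, for_nsl = TRUE)
  expect_equal(pn$length_bp, 100300)
  expect_equal(pn$recomb_rate, 2e-8, tolerance = 1e-9)

  single <- region_set("chr1", 10, 270, "c", list("brain"), omap)
  expect_equal(tissue_null_params(single)$length_bp, 260)
  expect_error(tissue_null_params(rs[0, ]), "empty")
})
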