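test_that("empty and single-void masks give the documented metrics", {
  empty <- binary_mask(matrix(FALSE, 300, 300), 10, "flow_void")
  m0 <- extract_flow_voids(empty)
  expect_equal(m0$n_voids, 0L)
  expect_equal(m0$total_area_mm2, 0)
  expect_equal(m0$mean_size_um2, 0)

  v <- matrix(FALSE, 300, 300)
  v[100:101, 50:53] <- TRUE               # one 8-pixel void
  m1 <- extract_flow_voids(binary_mask(v, 10, "flow_void"))
  expect_equal(m1$n_voids, 1L)
  expect_equal(m1$total_area_mm2, 8e-4)
  expect_equal(m1$mean_size_um2, 800)
})

test_that("component metrics match a flood-fill oracle on random masks", {
  for (s in 1:20) {
    set.seed(2000 + s)
    v <- matrix(stats::runif(64 * 64) < stats::runif(1, 0.2, 0.6), 64, 64)
    for (conn in c(8, 4)) {
      got <- extract_flow_voids(binary_mask(v, 10, "flow_void"), conn)
      oracle <- floodfill_label_oracle(v, conn)
      expect_equal(got$n_voids, max(oracle))
      expect_equal(sum(got$labels > 0), sum(oracle > 0))
      # identical partition: labels agree up to renumbering
      expect_true(all((got$labels > 0) == (oracle > 0)))
      tab <- table(got$labels[oracle > 0], oracle[oracle > 0])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
      # conservation: n * mean size == total area
      expect_equal(got$n_voids * got$mean_size_um2 * 1e-6,
                   got$total_area_mm2)
    }
  }
})

test_that("minimum-size filtering drops only sub-threshold components", {
  v <- matrix(FALSE, 40, 40)
  v[2:3, 2:3] <- TRUE        # 4 px
  v[20, 20] <- TRUE          # 1 px
  v[30:34, 30:31] <- TRUE    # 10 px
  m_all <- extract_flow_voids(binary_mask(v, 10, "flow_void"))
  expect_equal(m_all$n_voids, 3L)
  m_min <- extract_flow_voids(binary_mask(v, 10, "flow_void"), min_void_px = 4)
  expect_equal(m_min$n_voids, 2L)
  expect_equal(sum(m_min$labels > 0), 14)
})

test_that("overlap percentages match hand-enumerated cases", {
  pitch <- 10
  v <- matrix(FALSE, 4, 4); v[1, 1:3] <- TRUE; v[3, 4] <- TRUE  # 4 void px
  # 6 vessel px; exactly one void pixel (1,1) lies inside the vessel region
  p <- matrix(FALSE, 4, 4); p[1:3, 1] <- TRUE; p[2:4, 3] <- TRUE
  ov <- composite_overlap(binary_mask(v, pitch, "flow_void"),
                          binary_mask(p, pitch, "pachyvessel"))
  expect_equal(ov$pachyvessel_portion_pct, 100 * 6 / 16)  # 37.5
  expect_equal(ov$void_over_vessel_pct, 25)               # 1 of 4 void px

  p_disj <- matrix(FALSE, 4, 4); p_disj[2, 1:2] <- TRUE
  disjoint <- composite_overlap(binary_mask(v, pitch, "flow_void"),
                                binary_mask(p_disj, pitch, "pachyvessel"))
  expect_equal(disjoint$void_over_vessel_pct, 0)

  full <- composite_overlap(binary_mask(v, pitch, "flow_void"),
                            binary_mask(matrix(TRUE, 4, 4), pitch,
                                        "pachyvessel"))
  expect_equal(full$pachyvessel_portion_pct, 100)
  expect_equal(full$void_over_vessel_pct, 100)
})

test_that("the composite image encodes void red, vessel green, overlap yellow", {
  v <- matrix(FALSE, 3, 3); v[1, ] <- TRUE
  p <- matrix(FALSE, 3, 3); p[, 1] <- TRUE
  ov <- composite_overlap(binary_mask(v, 10, "flow_void"),
                          binary_mask(p, 10, "pachyvessel"))
  expect_equal(ov$composite[1, 1, ], c(1, 1, 0))  # overlap -> yellow
  expect_equal(ov$composite[1, 2, ], c(1, 0, 0))  # void only -> red
  expect_equal(ov$composite[2, 1, ], c(0, 1, 0))  # vessel only -> green
  expect_equal(ov$composite[3, 3, ], c(0, 0, 0))
})

test_that("dilating the vessel mask never decreases the void-over-vessel share", {
  set.seed(31)
  v <- matrix(stats::runif(64 * 64) < 0.15, 64, 64)
  p <- matrix(stats::runif(64 * 64) < 0.2, 64, 64)
  dilate <- function(m) {
    out <- m
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      sh <- matrix(FALSE, nrow(m), ncol(m))
      rs <- max(1, 1 + o[1]):min(nrow(m), nrow(m) + o[1])
      cs <- max(1, 1 + o[2]):min(ncol(m), ncol(m) + o[2])
      sh[rs, cs] <- m[rs - o[1], cs - o[2]]
      out <- out | sh
    }
    out
  }
  vm <- binary_mask(v, 10, "flow_void")
  prev <- composite_overlap(vm, binary_mask(p, 10, "pachyvessel"))
  for (i in 1:4) {
    p <- dilate(p)
    cur <- composite_overlap(vm, binary_mask(p, 10, "pachyvessel"))
    expect_gte(cur$void_over_vessel_pct, prev$void_over_vessel_pct)
    prev <- cur
  }
})

test_that("mis-tagged or degenerate masks are rejected", {
  v <- binary_mask(matrix(TRUE, 4, 4), 10, "bright_signal")
  expect_error(extract_flow_voids(v), "flow_void")
  novoid <- binary_mask(matrix(FALSE, 4, 4), 10, "flow_void")
  vessel <- binary_mask(matrix(TRUE, 4, 4), 10, "pachyvessel")
  expect_error(composite_overlap(novoid, vessel), "undefined")
  small <- binary_mask(matrix(TRUE, 3, 3), 10, "pachyvessel")
  expect_error(
    composite_overlap(binary_mask(matrix(TRUE, 4, 4), 10, "flow_void"), small),
    "shape")
})
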