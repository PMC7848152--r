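test_that("worked 1x3 strip reproduces the enumerated weighted costs", {
  p <- make_por(matrix(c(1, 0.5, 0.25), 1), pixel_size = 1)
  m <- weighted_geodesic_map(p, c(1, 1))
  expect_equal(as.numeric(m$cost), c(0, 2, 6))
  expect_equal(as.numeric(oracle_costs(p$porosity, 1, 0.01, c(1, 1))),
               c(0, 2, 6))
  expect_equal(as.integer(m$band), c(1L, 3L, 7L))
})

test_that("weighted cost equals exhaustive path enumeration on small grids", {
  withr::with_seed(101, {
    sizes <- rbind(c(2, 2), c(2, 3), c(3, 3), c(3, 4), c(4, 4))
    for (rep in 1:100) {
      dims <- sizes[sample.int(nrow(sizes), 1), ]
      por <- random_porosity_grid(dims[1], dims[2])
      p <- make_por(por, pixel_size = 0.7)
      m <- weighted_geodesic_map(p, c(1, 1))
      expect_equal(m$cost, oracle_costs(por, 0.7, 0.01, c(1, 1)),
                   tolerance = 1e-12)
    }
  })
})

test_that("weighted cost matches an independent graph shortest-path solver", {
  skip_if_not_installed("igraph")
  withr::with_seed(102, {
    nr <- 12; nc <- 10
    por <- random_porosity_grid(nr, nc, p_blocked = 0.1)
    p <- make_por(por, pixel_size = 0.5)
    m <- weighted_geodesic_map(p, c(1, 1))
    open <- which(por >= 0.01)
    id <- match(seq_len(nr * nc), open)
    edges <- c(); w <- c()
    for (idx in open) {
      i <- (idx - 1) %% nr + 1; j <- (idx - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        ii <- i + dr; jj <- j + dc
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        jdx <- (jj - 1) * nr + ii
        if (por[jdx] < 0.01) next
        len <- if (dr != 0 && dc != 0) sqrt(2) * 0.5 else 0.5
        edges <- c(edges, id[idx], id[jdx])
        w <- c(w, len / por[jdx])
      }
    }
    g <- igraph::make_graph(edges, n = length(open), directed = TRUE)
    d <- igraph::distances(g, v = id[1], weights = w, mode = "out")
    expect_equal(m$cost[open], as.numeric(d), tolerance = 1e-10)
  })
})

test_that("unit porosity reduces the weighted map to the depth contour map", {
  withr::with_seed(103, {
    por <- matrix(1, 32, 32)
    por[runif(32 * 32) < 0.2] <- 0          # scattered blocked pixels
    por[1, 1] <- 1
    p <- make_por(por, pixel_size = 0.0492)
    w <- weighted_geodesic_map(p, c(1, 1))
    d <- depth_contour_map(p, c(1, 1))
    expect_identical(w$cost, d$cost)
    expect_identical(w$band, d$band)
  })
})

test_that("inlet pixel has cost zero and band one; blocked inlets error", {
  p <- make_por(matrix(c(0.5, 0.5, 0.001, 0.5), 2))
  m <- weighted_geodesic_map(p, c(1, 1))
  expect_identical(m$cost[1, 1], 0)
  expect_identical(m$band[1, 1], 1L)
  expect_error(weighted_geodesic_map(p, c(1, 2)), "blocked")
  expect_error(depth_contour_map(p, c(1, 2)), "blocked")
})

test_that("a pixel enclosed by a blocked ring is unreachable", {
  por <- matrix(1, 7, 7)
  por[3:5, 3] <- 0; por[3:5, 5] <- 0; por[3, 3:5] <- 0; por[5, 3:5] <- 0
  m <- weighted_geodesic_map(make_por(por), c(1, 1))
  expect_false(m$reachable[4, 4])
  expect_identical(m$cost[4, 4], Inf)
  expect_true(is.na(m$band[4, 4]))
  open <- por == 1; open[4, 4] <- FALSE     # everything else stays reachable
  expect_true(all(m$reachable[open]))
})

test_that("cost is a metric under edge relaxation and monotone in porosity", {
  withr::with_seed(104, {
    for (rep in 1:10) {
      por <- random_porosity_grid(8, 8)
      p <- make_por(por, pixel_size = 0.3)
      m <- weighted_geodesic_map(p, c(1, 1))
      # triangle property: no adjacent edge can relax any cost further
      for (i in 1:8) for (j in 1:8) {
        if (!m$reachable[i, j]) next
        for (dr in -1:1) for (dc in -1:1) {
          ii <- i + dr; jj <- j + dc
          if ((dr == 0 && dc == 0) || ii < 1 || ii > 8 || jj < 1 || jj > 8) next
          if (por[ii, jj] < 0.01) next
          len <- if (dr != 0 && dc != 0) sqrt(2) * 0.3 else 0.3
          expect_lte(m$cost[ii, jj], m$cost[i, j] + len / por[ii, jj] + 1e-12)
        }
      }
      # raising porosity anywhere never increases any cost
      k <- sample(which(por >= 0.01), 1)
      por2 <- por; por2[k] <- min(1, por2[k] + 0.4)
      m2 <- weighted_geodesic_map(make_por(por2, 0.3), c(1, 1))
      expect_true(all(m2$cost <= m$cost + 1e-12))
    }
  })
})

test_that("contour bands are nested and recomputed on combination", {
  withr::with_seed(105, {
    por <- random_porosity_grid(16, 16, p_blocked = 0.05)
    p <- make_por(por, pixel_size = 0.2)
    m1 <- weighted_geodesic_map(p, c(1, 1))
    m2 <- weighted_geodesic_map(p, c(16, 16))
    for (k in 1:5) {
      inner <- m1$band <= k & m1$reachable
      outer <- m1$band <= k + 1 & m1$reachable
      expect_true(all(outer[inner]))
    }
    cmb <- combine_inlet_maps(list(m1, m2))
    expect_equal(cmb$cost, pmin(m1$cost, m2$cost))
    expect_true(all(cmb$band[cmb$reachable] ==
                      floor(cmb$cost[cmb$reachable] / cmb$band_width) + 1))
    expect_identical(combine_inlet_maps(list(m1))$cost, m1$cost)
  })
})

test_that("mirror-symmetric medium with mirrored inlets yields a mirror-symmetric map", {
  withr::with_seed(106, {
    half <- random_porosity_grid(12, 6, p_blocked = 0.1)
    por <- cbind(half, half[, 6:1])
    p <- make_por(por, pixel_size = 0.4)
    m <- combine_inlet_maps(list(weighted_geodesic_map(p, c(3, 2)),
                                 weighted_geodesic_map(p, c(3, 11))))
    expect_equal(m$cost, m$cost[, 12:1], tolerance = 1e-12)
  })
})

test_that("combination rejects empty and mismatched inputs", {
  p <- make_por(matrix(1, 4, 4))
  m <- weighted_geodesic_map(p, c(1, 1))
  q <- weighted_geodesic_map(make_por(matrix(1, 5, 5)), c(1, 1))
  expect_error(combine_inlet_maps(list()), "non-empty")
  expect_error(combine_inlet_maps(list(m, q)), "mismatched")
})

test_that("slow-region mask flags the strict upper cost quantile", {
  p <- make_por(matrix(1, 1, 11), pixel_size = 1)
  m <- depth_contour_map(p, c(1, 1))        # costs 0..10 mm
  mask <- slow_region_mask(m, 0.9)
  expect_identical(sum(mask), 1L)           # only the 10 mm pixel
  expect_true(mask[1, 11])
  m0 <- slow_region_mask(m, 0)
  expect_identical(sum(m0), 10L)            # everything above the minimum
  # uniform cost field: nothing strictly exceeds the quantile
  u <- m; u$cost[] <- 1; u$reachable[] <- TRUE
  expect_identical(sum(slow_region_mask(u, 0.5)), 0L)
})

test_that("map rendering is deterministic with one colour per band", {
  withr::with_seed(107, {
    por <- matrix(1, 20, 20); por[10, 3:18] <- 0
    p <- make_por(por, pixel_size = 0.25)   # max cost ~ just under 5 bands
    m <- depth_contour_map(p, c(1, 1))
    f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
    r1 <- render_map(m, f1); r2 <- render_map(m, f2)
    expect_identical(length(r1$palette), max(m$band, na.rm = TRUE))
    expect_identical(length(unique(r1$palette)), length(r1$palette))
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    img <- png::readPNG(f1)
    sent <- as.numeric(col2rgb(r1$sentinel)) / 255
    blocked <- which(!m$reachable, arr.ind = TRUE)[1, ]
    expect_equal(as.numeric(img[blocked[1], blocked[2], 1:3]), sent,
                 tolerance = 1e-2)
  })
})
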