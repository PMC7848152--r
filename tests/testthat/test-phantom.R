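test_that("phantom generation is deterministic given the seed", {
  a <- make_phantom(phantom_params(seed = 9))
  b <- make_phantom(phantom_params(seed = 9))
  expect_identical(a$slice$intensities, b$slice$intensities)
  expect_identical(a$labels, b$labels)
  expect_identical(a$inlets, b$inlets)
  c <- make_phantom(phantom_params(seed = 10))
  expect_false(identical(a$slice$intensities, c$slice$intensities))
})

test_that("labels partition the grid and inlets sit on permeable soft tissue", {
  ph <- make_phantom(phantom_params())
  cls <- sort(unique(as.integer(ph$labels)))
  expect_true(all(cls %in% 1:7))
  expect_identical(sum(table(ph$labels)), length(ph$labels))
  classes <- attr(ph$labels, "classes")
  at_inlets <- classes[as.character(ph$labels[cbind(ph$inlets$row, ph$inlets$col)])]
  expect_false(any(at_inlets %in% c("cortical", "air", "tooth")))
  expect_identical(sum(ph$inlets$label == "junctional-epithelium"), 2L)
  expect_identical(sum(ph$inlets$label == "inferior-alveolar-canal"), 1L)
})

test_that("the permeable interior is sealed against air by the cortical shell", {
  ph <- make_phantom(phantom_params(noise_sd = 0))
  classes <- attr(ph$labels, "classes")
  lab <- matrix(classes[as.character(ph$labels)], nrow(ph$labels))
  air <- lab == "air"
  # 4-neighbour dilation of the air region
  near_air <- air
  near_air[-1, ] <- near_air[-1, ] | air[-nrow(air), ]
  near_air[-nrow(air), ] <- near_air[-nrow(air), ] | air[-1, ]
  near_air[, -1] <- near_air[, -1] | air[, -ncol(air)]
  near_air[, -ncol(air)] <- near_air[, -ncol(air)] | air[, -1]
  exposed <- lab[near_air & !air]
  expect_false(any(exposed %in% c("trabecular", "pdl", "canal")))
})

test_that("outer ring of the mineralised body carries the cortical level before noise", {
  params <- phantom_params(noise_sd = 0)
  ph <- make_phantom(params)
  classes <- attr(ph$labels, "classes")
  lab <- matrix(classes[as.character(ph$labels)], nrow(ph$labels))
  bone <- lab %in% c("cortical", "trabecular", "canal")
  dim(bone) <- dim(lab)
  outside <- lab %in% c("air", "gingiva")
  dim(outside) <- dim(lab)
  near_out <- matrix(FALSE, nrow(lab), ncol(lab))
  near_out[-1, ] <- outside[-nrow(lab), ]
  near_out[-nrow(lab), ] <- near_out[-nrow(lab), ] | outside[-1, ]
  near_out[, -1] <- near_out[, -1] | outside[, -ncol(lab)]
  near_out[, -ncol(lab)] <- near_out[, -ncol(lab)] | outside[, -1]
  ring <- bone & near_out   # bone surface facing air or the gingival cover
  expect_gt(sum(ring), 0)
  expect_true(all(lab[ring] == "cortical"))
  expect_true(all(ph$slice$intensities[ring] == params$levels["cortical"]))
})

test_that("impossible geometry raises a configuration error", {
  expect_error(phantom_params(grid_height = 32, grid_width = 32),
               "configuration error")
  expect_error(phantom_params(shell_thickness = -1), "positive")
  expect_error(phantom_params(levels = c(air = 0, gingiva = 70, pdl = 80,
                                         canal = 70, trabecular = 220,
                                         cortical = 230, tooth = 230)),
               "ordered")
})

test_that("ground-truth porosity and calibration agree at class representatives", {
  params <- phantom_params(noise_sd = 0)
  ph <- make_phantom(params)
  p <- calibrate_porosity(ph$slice, params$levels[["air"]],
                          params$levels[["cortical"]])
  lv <- params$levels
  expected <- function(level) (lv[["cortical"]] - level) / lv[["cortical"]]
  for (cl in c("gingiva", "pdl", "canal"))
    expect_equal(unique(p$porosity[phantom_mask(ph, cl)]),
                 expected(lv[[cl]]))
  expect_identical(unique(p$porosity[phantom_mask(ph, "cortical")]), 0)
  expect_identical(unique(p$porosity[phantom_mask(ph, "tooth")]), 0)
  expect_identical(unique(p$porosity[phantom_mask(ph, "air")]), 1)
})
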