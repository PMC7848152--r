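test_that("XTT index reproduces hand-computed values and flags negatives", {
  expect_equal(xtt_score(0.75, 0.05, 0.5, 1.5), 0.7 / 0.75,
               ignore_attr = TRUE)
  expect_equal(xtt_score(0.4, 0.4, 1, 1), 0, ignore_attr = TRUE)
  expect_error(xtt_score(0.5, 0.1, 0, 1), "positive")
  expect_error(xtt_score(0.5, 0.1, 1, -2), "positive")
  expect_warning(s <- xtt_score(0.1, 0.3, 1, 1), "negative")
  expect_equal(as.numeric(s), -0.2)
  expect_true(attr(s, "negative"))
})

test_that("glucose consumption reproduces hand-computed values", {
  expect_equal(glucose_consumption(100, 80, 50, 2, 4), 1.25,
               ignore_attr = TRUE)
  expect_equal(glucose_consumption(120, 120, 50, 2, 4), 0,
               ignore_attr = TRUE)
  expect_error(glucose_consumption(100, 80, 50, 0, 4), "positive")
  expect_error(glucose_consumption(100, 80, 50, 2, 0), "positive")
  expect_warning(g <- glucose_consumption(80, 100, 50, 2, 4), "negative")
  expect_equal(as.numeric(g), -1.25)
})

test_that("both indices are homogeneous of degree -1 in tissue weight", {
  withr::with_seed(301, {
    a450 <- runif(20, 0.2, 1); a690 <- runif(20, 0, 0.15)
    w <- runif(20, 0.1, 3)
    expect_equal(as.numeric(xtt_score(a450, a690, 2 * w, 1.5)),
                 as.numeric(xtt_score(a450, a690, w, 1.5)) / 2)
    expect_equal(as.numeric(glucose_consumption(450, 300, 50, 2 * w, 4)),
                 as.numeric(glucose_consumption(450, 300, 50, w, 4)) / 2)
  })
})

test_that("field summaries give sample mean and n-1 SD per criterion and group", {
  tb <- data.frame(group = rep(c("a", "b"), each = 4),
                   criterion = "cells_per_mm2_pdl",
                   value = c(1, 2, 3, 4, 10, 10, 10, 10))
  s <- summarize_fields(tb)
  expect_equal(s$mean[s$group == "a"], 2.5)
  expect_equal(s$sd[s$group == "a"], sd(1:4))
  expect_equal(s$sd[s$group == "b"], 0)
  one <- summarize_fields(data.frame(group = "a", criterion = "x", value = 5))
  expect_true(is.na(one$sd))
  expect_error(summarize_fields(tb[0, ]), "empty")
})

test_that("noise-free generation at a reference mean is recovered exactly", {
  ref <- histomorph_reference()
  ref$sd <- 0
  tab <- make_histomorph_table(histomorph_params(reference = ref))
  s <- summarize_fields(tab)
  target <- s[s$criterion == "cells_per_mm2_pdl" & s$group == "fresh_control", ]
  expect_equal(target$mean, 148.3)
  expect_equal(target$sd, 0)
})

test_that("group comparison: equal groups NS, separated groups significant", {
  base <- data.frame(group = rep(c("a", "b"), each = 6),
                     sample = rep(c("a1", "a2", "a3", "b1", "b2", "b3"),
                                  each = 2),
                     criterion = "x",
                     value = rep(c(3, 5, 7, 3, 5, 7), each = 2))
  eq <- compare_groups(base)                 # identical group structure
  expect_identical(eq$pairwise$verdict, "NS")
  expect_gt(eq$anova$p, 0.99)
  far <- base; far$value[far$group == "b"] <- far$value[far$group == "b"] + 200
  expect_identical(compare_groups(far)$pairwise$verdict, "significant")
})

test_that("degenerate variance is reported rather than crashing", {
  flat <- data.frame(group = rep(c("a", "b"), each = 4),
                     sample = rep(c("a1", "a2", "b1", "b2"), each = 2),
                     criterion = "x", value = 1)
  rep <- compare_groups(flat)
  expect_identical(rep$pairwise$verdict, "degenerate")
  expect_true(is.na(rep$anova$p))
})

test_that("field-level and sample-level modes differ in degrees of freedom", {
  withr::with_seed(302, {
    tab <- make_histomorph_table(histomorph_params(seed = 302))
    rs <- compare_groups(tab, level = "sample")
    rf <- compare_groups(tab, level = "field")
    expect_identical(rs$level, "sample")
    expect_identical(rf$level, "field")
    ns <- rs$summary[rs$summary$criterion == "cells_per_mm2_pdl", "n"]
    nf <- rf$summary[rf$summary$criterion == "cells_per_mm2_pdl", "n"]
    expect_identical(ns, c(3L, 3L))
    expect_identical(nf, c(27L, 27L))
  })
})
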