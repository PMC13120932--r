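test_that("rendering is deterministic and respects the identity style", {
  morph <- morphology_spec()
  set.seed(41); r1 <- render_image(morph, domain_style(), 1, side = 48)
  set.seed(41); r2 <- render_image(morph, domain_style(), 1, side = 48)
  expect_identical(r1$pixels, r2$pixels)
  expect_identical(r1$stat, r2$stat)
  # identity style leaves the render untouched bit-for-bit
  set.seed(41); r3 <- render_image(morph, domain_style(gain = c(1, 1, 1), offset = c(0, 0, 0)), 1, 48)
  expect_identical(r1$pixels, r3$pixels)
  expect_true(all(r1$pixels >= 0 & r1$pixels <= 1))
  # stat lies in the class-1 count range and determines the label
  expect_gte(r1$stat, morph$count_range_1[1])
  expect_lte(r1$stat, morph$count_range_1[2])
})

test_that("class-1 images carry more nuclei than class-0 by the generator ledger", {
  morph <- morphology_spec()
  set.seed(5)
  k0 <- replicate(15, render_image(morph, domain_style(), 0, 48)$n_placed)
  k1 <- replicate(15, render_image(morph, domain_style(), 1, 48)$n_placed)
  expect_lt(max(k0), min(k1))  # disjoint count ranges by construction
  expect_gt(mean(k1), mean(k0))
})

test_that("impossible packings and invalid specs raise explicit errors", {
  expect_error(morphology_spec(count_range_0 = c(5, 20), count_range_1 = c(10, 30)),
               "disjoint")
  crazy <- morphology_spec(count_range_0 = c(6, 12), count_range_1 = c(500, 600),
                           radius_mean = 6)
  set.seed(1)
  expect_error(render_image(crazy, domain_style(), 1, side = 32), "cannot place")
  expect_error(domain_style(gain = c(0, 1, 1)), "positive")
  expect_error(synthetic_spec(rho = 1.5), "rho")
})

test_that("stain styles invert exactly in optical-density space", {
  set.seed(43)
  img <- array(runif(16 * 16 * 3, min = 0.05, max = 1), c(16, 16, 3))
  style <- domain_style(gain = c(1.3, 0.8, 1.1), offset = c(0.05, 0.02, 0.04), id = "x")
  back <- invert_style(apply_style(img, style), style)
  expect_lt(max(abs(back - img)), 1 / 255)
})

test_that("dataset generation hits exact counts and the requested confound", {
  spec <- synthetic_spec(n_per_class = c(20, 20), side = 32, rho = 0, seed = 11,
                         morph = small_morph())
  m <- generate_dataset(spec)
  expect_equal(nrow(m), 40L)
  expect_equal(sum(m$label == 0), 20L)
  tab <- table(m$label, m$domain)
  expect_true(all(tab == 10))           # exact decorrelation
  # perfect confound
  spec1 <- synthetic_spec(n_per_class = c(10, 14), side = 32, rho = 1, seed = 12,
                          morph = small_morph())
  m1 <- generate_dataset(spec1)
  t1 <- table(m1$label, m1$domain)
  expect_equal(as.vector(t1["0", "lab_pink"]), 10)
  expect_equal(as.vector(t1["1", "lab_purple"]), 14)
  expect_equal(as.vector(t1["0", "lab_purple"]), 0)
  # published imbalance passthrough
  spec2 <- synthetic_spec(n_per_class = c(290, 934), side = 32, seed = 13,
                          morph = small_morph())
  m2 <- generate_dataset(spec2)
  expect_equal(as.vector(table(m2$label)), c(290L, 934L))
  sc <- split_counts(m2$label, m2$split)
  expect_equal(unlist(sc[1, c("train", "val", "test")], use.names = FALSE), c(203, 29, 58))
  expect_equal(unlist(sc[2, c("train", "val", "test")], use.names = FALSE), c(654, 93, 187))
})

test_that("generation writes byte-identical files for identical spec and seed", {
  spec <- synthetic_spec(n_per_class = c(3, 3), side = 32, seed = 21,
                         morph = small_morph())
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  m1 <- generate_dataset(spec, dir = d1)
  m2 <- generate_dataset(spec, dir = d2)
  expect_identical(m1$stat, m2$stat)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$path[i], "raw", 1e6), readBin(m2$path[i], "raw", 1e6))
  }
  # and the in-memory pixels equal the decoded files
  expect_equal(load_image(m1$path[1]), attr(m1, "images")[[1]], tolerance = 1e-9)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the label is a deterministic function of the recorded statistic", {
  spec <- synthetic_spec(n_per_class = c(15, 15), side = 32, seed = 31,
                         morph = small_morph())
  m <- generate_dataset(spec)
  thr <- (max(spec$morph$count_range_0) + min(spec$morph$count_range_1)) / 2
  expect_identical(m$label, as.integer(m$stat > thr))
})

test_that("shifted test sets decorrelate or hold out domains as requested", {
  spec <- synthetic_spec(n_per_class = c(40, 40), side = 32, rho = 0.9, seed = 51,
                         morph = small_morph())
  m_tr <- generate_dataset(spec)
  # rho mode: balanced label x domain contingency within rounding
  m_te <- shifted_test_set(spec, mode = "rho", rho_test = 0)
  expect_true(all(m_te$split == "test"))
  tab <- table(m_te$label, m_te$domain)
  expect_true(max(abs(tab - mean(tab))) <= 1)
  # morphology parameters pass through unchanged: stat ranges agree per class
  thr <- (max(spec$morph$count_range_0) + min(spec$morph$count_range_1)) / 2
  expect_identical(m_te$label, as.integer(m_te$stat > thr))
  # holdout mode: no overlap of domain ids with training
  held <- list(domain_style(gain = c(1.5, 0.7, 1.0), offset = c(0.06, 0, 0.02), id = "lab_new"))
  m_h <- shifted_test_set(spec, mode = "holdout", holdout_domains = held)
  expect_false(any(m_h$domain %in% m_tr$domain))
  expect_error(shifted_test_set(spec, mode = "holdout",
                                holdout_domains = list(domain_style(id = "lab_pink"))),
               "overlap")
})

test_that("confounded splits keep rho within the train split", {
  spec <- synthetic_spec(n_per_class = c(40, 40), side = 32, rho = 0.9, seed = 61,
                         morph = small_morph())
  m <- generate_dataset(spec)
  tr <- m[m$split == "train", ]
  # class-0 mostly lab_pink, class-1 mostly lab_purple ((1 + 0.9)/2 = 95%)
  frac0 <- mean(tr$domain[tr$label == 0] == "lab_pink")
  frac1 <- mean(tr$domain[tr$label == 1] == "lab_purple")
  expect_gt(frac0, 0.85)
  expect_gt(frac1, 0.85)
})
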