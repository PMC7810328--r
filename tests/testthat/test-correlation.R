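test_that("FFT cross-correlation equals the spatial-domain oracle", {
  set.seed(20)
  for (i in 1:25) {
    a <- matrix(runif(prod(da <- sample(1:12, 2))), da[1], da[2])
    b <- matrix(runif(prod(db <- sample(1:30, 2))), db[1], db[2])
    got <- xcorr2(a, b)$surface
    want <- spatial_xcorr(a, b)
    expect_equal(dim(got), dim(a) + dim(b) - 1L)
    expect_lt(max(abs(got - want)) / max(1, max(abs(want))), 1e-9)
  }
  # one larger binary instance
  a <- matrix(rbinom(64 * 64, 1, 0.2), 64)
  b <- matrix(rbinom(64 * 64, 1, 0.2), 64)
  expect_lt(max(abs(xcorr2(a, b)$surface - spatial_xcorr(a, b))), 1e-6)
  expect_error(xcorr2(matrix(1, 0, 0), b), "empty")
})

test_that("autocorrelation of an encoded image peaks at seq_len * N", {
  cs <- zeroscore_n3()
  img <- encode_sequence(random_genome(60, seed = 2), cs, columns = 10)
  cm <- xcorr2(img, img)
  expect_equal(max(round(cm$surface)), 60L * cs$N)
  pk <- which(round(cm$surface) == 60L * cs$N, arr.ind = TRUE)
  expect_equal(as.integer(pk[1, ]), dim(img$raster))  # zero-offset alignment
})

test_that("pupil band limiting converges to the ideal surface and sheds energy", {
  set.seed(21)
  a <- matrix(rbinom(100, 1, 0.3), 10)
  b <- matrix(rbinom(400, 1, 0.3), 20)
  ideal <- xcorr2(a, b)$surface
  pitch <- 1e-5
  errs <- energies <- numeric(0)
  for (D in c(0.005, 0.02, 0.08, 0.64)) {
    opt <- optical_params(z_xp = 0.04, D_xp = D, samples = 64, pitch = pitch)
    s <- xcorr2(a, b, mode = "optical", opt = opt)$surface
    errs <- c(errs, max(abs(s - ideal)))
    energies <- c(energies, sum(s^2))
  }
  expect_true(all(diff(errs) <= 1e-9))            # monotone approach
  expect_lt(errs[length(errs)], 1e-9)             # huge aperture == ideal
  expect_true(all(energies <= sum(ideal^2) + 1e-9))  # mask never adds energy
  expect_error(xcorr2(a, b, mode = "optical"), "optical_params")
})

test_that("cutoff frequency and sampling bounds follow the pupil formulas", {
  opt <- optical_params(z_xp = 0.04, D_xp = 0.08, samples = 512)
  # hand calculation: 0.08 / (2 * 632.8e-9 * 0.04) cycles per metre
  expect_equal(cutoff_frequency(opt), 1580278.132, tolerance = 1e-6)
  expect_equal(cutoff_frequency(optical_params(z_xp = 0.04, D_xp = 0.16,
                                               samples = 512)),
               2 * cutoff_frequency(opt))
  expect_equal(cutoff_frequency(optical_params(z_xp = 0.08, D_xp = 0.08,
                                               samples = 512)),
               cutoff_frequency(opt) / 2)

  sb <- sampling_bounds(opt)
  expect_equal(sb$L_side_max, 512 * sb$du_max)
  # derate scaling: 0.95 of the ideal bound, and the algebraic identity
  sb1 <- sampling_bounds(optical_params(z_xp = 0.04, D_xp = 0.08,
                                        samples = 512, derate = 1))
  expect_equal(sb$du_max / sb1$du_max, 0.95)
  set.seed(22)
  for (i in 1:5) {
    o <- optical_params(z_xp = runif(1, 1e-3, 1), D_xp = runif(1, 1e-3, 1),
                        samples = 128, derate = runif(1, 0.5, 1))
    expect_equal(sampling_bounds(o)$du_max * 2 * o$D_xp /
                   (o$wavelength * o$z_xp), o$derate)
  }
  # single-sample frame: the side bound equals the pixel bound
  o1 <- optical_params(z_xp = 0.1, D_xp = 0.05, samples = 1, derate = 1)
  expect_equal(sampling_bounds(o1)$L_side_max, sampling_bounds(o1)$du_max)
})

test_that("the peak model reproduces the reference coefficient table", {
  pm <- peak_model(N = 3, C = 1.2)
  M <- seq(0, 0.6, by = 0.1)
  real <- vapply(M, expected_peak, numeric(1), L = 1, pm = pm,
                 normalized = TRUE)
  zero <- vapply(M, expected_peak, numeric(1), L = 1, pm = pm,
                 normalized = TRUE, model = "zero")
  expect_equal(real, c(3, 2.82, 2.64, 2.46, 2.28, 2.10, 1.92))
  expect_equal(zero, c(3, 2.7, 2.4, 2.1, 1.8, 1.5, 1.2))
  # at M = 0 the models coincide; unnormalized scales by L
  expect_equal(expected_peak(200, 0, pm), expected_peak(200, 0, pm, model = "zero"))
  expect_equal(expected_peak(50, 0.3, pm), 50 * 2.46)
  expect_error(expected_peak(10, 1.5, pm), "M must")
  expect_error(peak_model(3, 3), "C must")
})

test_that("cross-talk calibration matches construction and bounds", {
  # pairwise disjoint codes: aligned cross-talk is exactly zero
  disj <- make_codeset(3, 2, 0, c("A", "B"), list(A = c(1, 2), B = c(3, 4)))
  expect_equal(calibrate_C(disj, trials = 5, L = 30, seed = 1)$C, 0)
  # calibrated C is positive and below N for the DNA fixtures; reproducible
  for (cs in list(zeroscore_n2(), zeroscore_n3())) {
    c1 <- calibrate_C(cs, trials = 10, L = 50, seed = 2)
    c2 <- calibrate_C(cs, trials = 10, L = 50, seed = 2)
    expect_identical(c1$C, c2$C)
    expect_gt(c1$C, 0)
    expect_lt(c1$C, cs$N)
  }
  expect_error(calibrate_C(make_codeset(3, 2, 0, "A", list(A = c(1, 2)))),
               "size 1")
})

test_that("queries are detected at their true positions and rejected when absent", {
  cs <- zeroscore_n3()
  pm <- peak_model(cs$N, 1.2)
  ref <- random_genome(400, seed = 30)
  img <- encode_sequence(ref, cs, columns = 40)

  # exact substring on the row grid, multi-row
  q <- substring(ref, 81, 240)
  det <- detect_query(img, encode_sequence(q, cs, columns = 40), pm, M_max = 0)
  expect_true(det$present)
  expect_equal(det$peak_value, 160 * cs$N)
  expect_equal(det$mapped_position, 81L)

  # single-row query not on the row grid still matches within its row
  q2 <- substring(ref, 13, 32)
  det2 <- detect_query(img, encode_sequence(q2, cs, columns = 40), pm, M_max = 0)
  expect_true(det2$present)
  expect_equal(det2$mapped_position, 13L)

  # absent query at the exact-match threshold
  set.seed(31)
  repeat {
    qa <- random_genome(25)
    if (count_overlapping(ref, qa) == 0) break
  }
  det3 <- detect_query(img, encode_sequence(qa, cs, columns = 40), pm, M_max = 0)
  expect_false(det3$present)

  # substituted query clears the model threshold with its tolerance
  qm <- mutate_sequence(substring(ref, 41, 200), 0.1)
  det4 <- detect_query(img, encode_sequence(qm, cs, columns = 40), pm,
                       M_max = 0.2)
  expect_true(det4$present)
  expect_error(detect_query(encode_sequence(q2, cs, columns = 40), img, pm),
               "longer")
})

test_that("k-mer counting equals string counting up to row-break cutoff", {
  cs <- zeroscore_n2()
  img <- encode_sequence("AAAA", cs, columns = 4)
  expect_equal(count_kmers(img, "A"), 4L)

  # the canonical row-break illustration: 1 of 2 found, relative error 0.5
  ref <- "TAGGAATCGGACAATCCC"
  img6 <- encode_sequence(ref, cs, columns = 6)
  expect_equal(count_kmers(img6, "AATC"), 1L)
  expect_equal(relative_error(count_overlapping(ref, "AATC"),
                              count_kmers(img6, "AATC")), 0.5)

  # zero-score sets count exactly the unbroken occurrences
  set.seed(32)
  for (i in 1:5) {
    s <- random_genome(200)
    columns <- sample(c(10, 25, 200), 1)
    im <- encode_sequence(s, cs, columns = columns)
    for (k in 1:3) {
      pat <- random_genome(k)
      expect_identical(count_kmers(im, pat),
                       as.integer(count_unbroken(s, pat, columns)))
    }
  }
  expect_error(count_kmers(img, "AX"), "not in alphabet")
  expect_error(count_kmers(img, paste(rep("A", 9), collapse = "")), "1..")
})
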