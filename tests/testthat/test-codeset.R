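test_that("code-set construction validates its invariants", {
  cs <- make_codeset(3, 3, 0, dna,
                     list(A = c(1, 5, 9), C = c(2, 6, 7),
                          G = c(3, 4, 8), T = c(1, 6, 8)))
  expect_s3_class(cs, "codeset")
  expect_length(cs$codes, 4)
  for (m in cs$codes) expect_equal(sum(m), 3)
  # row-major materialisation: index 2 is row 1, col 2
  expect_equal(cs$codes$C[1, 2], 1L)

  expect_error(make_codeset(3, 2, 0, "A", list(A = c(1, 1))), "duplicate")
  expect_error(make_codeset(3, 2, 0, "A", list(A = c(1, 10))), "out of range")
  expect_error(make_codeset(3, 2, 2, "A", list(A = c(1, 2))), "E must")
  expect_error(make_codeset(3, 2, 0, c("A", "A"),
                            list(A = c(1, 2), A = c(3, 4))), "unique")

  # the large 9x9/32-bit shape is accepted
  pos <- lapply(1:4, function(k) (seq_len(32) + 7 * k) %% 81 + 1)
  names(pos) <- dna
  big <- make_codeset(9, 32, 11, dna, pos)
  expect_equal(big$d, 9L)
  expect_equal(relative_threshold(big), 11 / 32)
})

test_that("1D code sets use 1 x d codes and 1 x 2 grids", {
  cs <- make_codeset(4, 2, 0, c("A", "B"),
                     list(A = c(1, 3), B = c(2, 4)), mode = "1D")
  expect_equal(dim(cs$codes$A), c(1L, 4L))
  g <- make_cgrid(cs, c(1, 2))
  expect_equal(dim(g$raster), c(1L, 8L))
  expect_equal(sum(g$raster), 2 * cs$N)
  expect_equal(overlap_cost(cs)$n_states, 2^3)
})

test_that("correlating a code with a c-grid matches the sliding-window definition", {
  # delta-function code: unit peaks exactly at the four alignment offsets
  cs <- make_codeset(3, 1, 0, "A", list(A = 1))
  g <- make_cgrid(cs, c(1, 1, 1, 1))
  m <- correlate_code_with_grid(cs$codes$A, g)
  expect_equal(dim(m), c(8L, 8L))
  expect_equal(sum(m), 4L)
  expect_equal(m[3, 3] + m[3, 6] + m[6, 3] + m[6, 6], 4L)

  # all-zero raster correlates to zero everywhere
  g0 <- g
  g0$raster[] <- 0L
  expect_true(all(correlate_code_with_grid(cs$codes$A, g0) == 0))

  # diagonal code tiled four times: every alignment offset scores N = 3
  csd <- make_codeset(3, 3, 0, "A", list(A = c(1, 5, 9)))
  gd <- make_cgrid(csd, c(1, 1, 1, 1))
  md <- correlate_code_with_grid(csd$codes$A, gd)
  expect_equal(c(md[3, 3], md[3, 6], md[6, 3], md[6, 6]), rep(3L, 4))
  expect_true(max(md) <= 3)

  # random instances against the independent spatial oracle
  set.seed(101)
  for (i in 1:20) {
    cs <- random_codeset(sample(2:4, 1), sample(1:3, 1), 4)
    g <- make_cgrid(cs, sample(4, 4, replace = TRUE))
    m <- correlate_code_with_grid(cs$codes[[1]], g)
    expect_identical(m + 0, spatial_xcorr(cs$codes[[1]] + 0, g$raster + 0))
  }
})

test_that("overlap cost equals the exhaustive state enumeration oracle", {
  # a single corner-pixel code: only full-match alignments are nonzero
  cs1 <- make_codeset(2, 1, 0, "A", list(A = 1))
  expect_equal(overlap_cost(cs1)$total_invalid, 0L)
  expect_true(is_zero_score(cs1))

  # two identical codes: aligned cross-symbol full peaks are counted
  cs2 <- make_codeset(2, 1, 0, c("A", "B"), list(A = 1, B = 1))
  expect_gt(overlap_cost(cs2)$total_invalid, 0)
  expect_false(is_zero_score(cs2))

  set.seed(202)
  shapes <- list(c(2, 1, 2), c(2, 2, 2), c(3, 2, 3), c(3, 2, 4), c(3, 3, 2))
  for (sh in shapes) {
    for (rep in 1:2) {
      cs <- random_codeset(sh[1], sh[2], sh[3])
      got <- overlap_cost(cs)
      want <- naive_overlap_cost(cs)
      expect_identical(got$total_invalid, as.integer(want$total_invalid))
      expect_identical(got$max_noise, as.integer(want$max_noise))
      expect_identical(got$n_states, want$n_states)
      expect_lte(got$max_noise, cs$N)
    }
  }
  # 1D reduction obeys the same oracle
  cs1d <- random_codeset(4, 2, 3, mode = "1D")
  expect_identical(overlap_cost(cs1d)$total_invalid,
                   as.integer(naive_overlap_cost(cs1d)$total_invalid))
})

test_that("overlap cost is invariant under alphabet relabeling", {
  set.seed(33)
  for (rep in 1:5) {
    cs <- random_codeset(3, 2, 4)
    perm <- sample(4)
    cs2 <- make_codeset(3, 2, 0, cs$alphabet,
                        stats::setNames(cs$positions[perm], cs$alphabet))
    expect_identical(overlap_cost(cs)$total_invalid,
                     overlap_cost(cs2)$total_invalid)
  }
})

test_that("per-state breakdown sums to the total and covers K^5 states", {
  set.seed(44)
  cs <- random_codeset(3, 2, 4)
  rep <- overlap_cost(cs, per_state = TRUE)
  expect_equal(dim(rep$per_state), c(4^4, 4))
  expect_equal(sum(rep$per_state), rep$total_invalid)
  expect_equal(rep$n_states, 4^5)
})

test_that("zero-score fixtures verify and noise stays under the margin", {
  for (cs in list(zeroscore_n2(), zeroscore_n3())) {
    rep <- overlap_cost(cs)
    expect_identical(rep$total_invalid, 0L)
    expect_lte(rep$max_noise, cs$N - cs$E - 1)
    expect_true(is_zero_score(cs))
  }
  expect_gt(overlap_cost(noisy_n2())$total_invalid, 800)
})

test_that("relative threshold is E/N", {
  expect_equal(relative_threshold(list(N = 3, E = 0)), 0)
  expect_equal(relative_threshold(list(N = 32, E = 11)), 0.34375)
  expect_error(relative_threshold(list(N = 0, E = 0)), "positive")
})

test_that("code sets round-trip through the JSON sidecar", {
  set.seed(55)
  cs <- random_codeset(3, 2, 4)
  cs$score <- overlap_cost(cs)$total_invalid
  path <- withr::local_tempfile(fileext = ".json")
  write_codeset(cs, path)
  back <- read_codeset(path)
  expect_identical(back$positions, cs$positions)
  expect_identical(back$codes, cs$codes)
  expect_identical(back$score, cs$score)
  expect_identical(back[c("d", "N", "E", "K", "mode", "alphabet")],
                   cs[c("d", "N", "E", "K", "mode", "alphabet")])
})
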