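# Independent oracles used across the suite.

# O(n^4) spatial-domain full cross-correlation: a slides over b.
spatial_xcorr <- function(a, b) {
  Ha <- nrow(a); Wa <- ncol(a); Hb <- nrow(b); Wb <- ncol(b)
  out <- matrix(0, Ha + Hb - 1L, Wa + Wb - 1L)
  for (s in seq_len(nrow(out))) {
    ri <- seq_len(Ha) + s - Ha
    kr <- ri >= 1L & ri <= Hb
    if (!any(kr)) next
    for (t in seq_len(ncol(out))) {
      ci <- seq_len(Wa) + t - Wa
      kc <- ci >= 1L & ci <= Wb
      if (!any(kc)) next
      out[s, t] <- sum(a[kr, kc, drop = FALSE] *
                         b[ri[kr], ci[kc], drop = FALSE])
    }
  }
  out
}

# Naive K^5 (or K^3) enumeration of the overlap-noise cost via
# correlate_code_with_grid, with the same-symbol alignment exclusions.
naive_overlap_cost <- function(cs) {
  d <- cs$d
  nq <- if (cs$mode == "2D") 4L else 2L
  grids <- as.matrix(expand.grid(rep(list(seq_len(cs$K)), nq)))
  total <- 0L
  mx <- 0L
  for (g in seq_len(nrow(grids))) {
    grid <- make_cgrid(cs, grids[g, ])
    for (cc in seq_len(cs$K)) {
      m <- correlate_code_with_grid(cs$codes[[cc]], grid)
      align <- if (cs$mode == "2D")
        list(c(d, d), c(d, 2L * d), c(2L * d, d), c(2L * d, 2L * d))
      else list(c(1L, d), c(1L, 2L * d))
      keep <- matrix(TRUE, nrow(m), ncol(m))
      for (q in seq_len(nq))
        if (grids[g, q] == cc) keep[align[[q]][1], align[[q]][2]] <- FALSE
      total <- total + sum(m[keep] >= cs$N - cs$E)
      mx <- max(mx, max(m[keep]))
    }
  }
  list(total_invalid = total, max_noise = mx,
       n_states = nrow(grids) * cs$K)
}

random_codeset <- function(d, N, K, E = 0, mode = "2D") {
  ncell <- if (mode == "2D") d * d else d
  pos <- lapply(seq_len(K), function(k) sample.int(ncell, N))
  names(pos) <- LETTERS[seq_len(K)]
  make_codeset(d, N, E, LETTERS[seq_len(K)], pos, mode = mode)
}

# exact overlapping substring count, and the count of occurrences that do
# not span a row wrap of a raster with the given number of columns
count_overlapping <- function(seq, pat) {
  h <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (h[1] == -1L) 0L else length(h)
}
count_unbroken <- function(seq, pat, columns) {
  h <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (h[1] == -1L) return(0L)
  k <- nchar(pat)
  sum((h - 1L) %% columns <= columns - k)
}

fixture_codeset <- function(name) {
  read_codeset(system.file("extdata", name, package = "gacodes"))
}
zeroscore_n2 <- function() fixture_codeset("codeset-d3-N2-E0-zeroscore.json")
zeroscore_n3 <- function() fixture_codeset("codeset-d3-N3-E0-zeroscore.json")
noisy_n2 <- function() fixture_codeset("codeset-d3-N2-E0-random.json")

dna <- c("A", "C", "G", "T")
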