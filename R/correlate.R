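#' Optical parameters for the band-limited correlator mode
#'
#' The coherent optical system transmits no spatial frequency beyond the
#' cutoff `f0 = D_xp / (2 lambda z_xp)` set by its exit pupil. Sampling on
#' the simulated detector uses a pixel pitch at (or below) the bound
#' `lambda z_xp / (2 D_xp)`, derated by a safety fraction.
#'
#' @param wavelength Laser wavelength in metres (default: HeNe, 632.8 nm).
#' @param z_xp Exit-pupil distance (focal length of the transform lens), m.
#' @param D_xp Exit-pupil diameter, m.
#' @param samples Pixels per side of the simulated frame.
#' @param derate Fraction applied to the sampling upper bounds (default 0.95,
#'   i.e. 5% below the theoretical limit).
#' @param pitch Physical sample interval in metres; defaults to the derated
#'   upper bound `derate * wavelength * z_xp / (2 D_xp)`.
#' @return An object of class `optical_params`.
#' @export
optical_params <- function(wavelength = 632.8e-9, z_xp, D_xp, samples = 512,
                           derate = 0.95, pitch = NULL) {
  if (wavelength <= 0 || z_xp <= 0 || D_xp <= 0 || samples <= 0)
    stop("wavelength, z_xp, D_xp and samples must be positive")
  if (derate <= 0 || derate > 1) stop("derate must be in (0, 1]")
  if (is.null(pitch)) pitch <- derate * wavelength * z_xp / (2 * D_xp)
  if (pitch <= 0) stop("pitch must be positive")
  structure(list(wavelength = wavelength, z_xp = z_xp, D_xp = D_xp,
                 samples = as.integer(samples), derate = derate,
                 pitch = pitch),
            class = "optical_params")
}

#' Coherent cutoff frequency
#'
#' `f0 = D_xp / (2 lambda z_xp)`, in cycles per metre: the diffraction limit
#' beyond which the coherent transfer function of the simulated system is
#' zero.
#'
#' @param opt An [optical_params()] object.
#' @return Cutoff frequency in cycles/m.
#' @export
cutoff_frequency <- function(opt) {
  stopifnot(inherits(opt, "optical_params"))
  opt$D_xp / (2 * opt$wavelength * opt$z_xp)
}

#' Sampling upper bounds of the simulated optical system
#'
#' The physical sample interval is bounded by
#' `du <= lambda z_xp / (2 D_xp)` and the frame side length by
#' `L <= S lambda z_xp / (2 D_xp)` (with `L = S du`); both are returned
#' derated by `opt$derate`.
#'
#' @param opt An [optical_params()] object.
#' @return List with `du_max` (m) and `L_side_max` (m).
#' @export
sampling_bounds <- function(opt) {
  stopifnot(inherits(opt, "optical_params"))
  du <- opt$derate * opt$wavelength * opt$z_xp / (2 * opt$D_xp)
  list(du_max = du, L_side_max = opt$samples * du)
}

as_raster <- function(x) {
  if (inherits(x, "encoded_image")) x$raster
  else if (is.matrix(x)) x
  else stop("expected a matrix or encoded_image")
}

# padded FFT sizes for a full linear correlation of an Ha x Wa kernel with an
# Hb x Wb image; highly composite lengths keep R's mixed-radix FFT fast
corr_pad_dims <- function(Ha, Wa, Hb, Wb) {
  c(stats::nextn(Ha + Hb - 1L, c(2, 3, 5)),
    stats::nextn(Wa + Wb - 1L, c(2, 3, 5)))
}

# hard circular low-pass pupil mask on the P1 x P2 discrete frequency grid
pupil_mask <- function(P1, P2, opt) {
  f0 <- cutoff_frequency(opt)
  fr <- fft_freqs(P1, opt$pitch)
  fc <- fft_freqs(P2, opt$pitch)
  outer(fr^2, fc^2, `+`) <= f0^2
}

fft_freqs <- function(n, pitch) {
  k <- seq_len(n) - 1L
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / (n * pitch)
}

#' Full linear 2D cross-correlation of two images
#'
#' Computes the full (zero-padded, never circular) linear cross-correlation
#' surface of `a` slid over `b`: entry `(s, t)` is the dot product of `a`
#' with `b` when `a`'s top-left pixel sits over `b`'s pixel
#' `(s - nrow(a) + 1, t - ncol(a) + 1)`, so exact alignment of `a` at `b`'s
#' position `(r, c)` peaks at `(r + nrow(a) - 1, c + ncol(a) - 1)`. The
#' surface has shape `(Ha + Hb - 1) x (Wa + Wb - 1)`.
#'
#' In `"optical"` mode each forward spectrum is multiplied by a hard-edged
#' centred circular low-pass mask at the pupil cutoff frequency
#' [cutoff_frequency()] before the spectra are multiplied, emulating the
#' diffraction limit of a coherent correlator; as the cutoff grows the
#' surface converges to the ideal one.
#'
#' @param a Query image: matrix or [encode_sequence()] result.
#' @param b Reference image: matrix or `encoded_image`.
#' @param mode `"ideal"` (exact) or `"optical"` (pupil band-limited).
#' @param opt An [optical_params()] object; required in optical mode.
#' @return An object of class `correlation_map`: `surface`, `dim_a`,
#'   `dim_b`, `mode`.
#' @export
xcorr2 <- function(a, b, mode = c("ideal", "optical"), opt = NULL) {
  mode <- match.arg(mode)
  a <- as_raster(a); b <- as_raster(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty input matrix")
  if (mode == "optical" && is.null(opt))
    stop("optical mode requires an optical_params object")
  Ha <- nrow(a); Wa <- ncol(a); Hb <- nrow(b); Wb <- ncol(b)
  P <- corr_pad_dims(Ha, Wa, Hb, Wb)
  FA <- padded_fft(a[Ha:1, Wa:1, drop = FALSE], P)
  FB <- padded_fft(b, P)
  if (mode == "optical") {
    mask <- pupil_mask(P[1], P[2], opt)
    FA <- FA * mask
    FB <- FB * mask
  }
  S <- Re(stats::fft(FA * FB, inverse = TRUE)) / prod(P)
  surface <- S[seq_len(Ha + Hb - 1L), seq_len(Wa + Wb - 1L), drop = FALSE]
  structure(list(surface = surface, dim_a = c(Ha, Wa), dim_b = c(Hb, Wb),
                 mode = mode),
            class = "correlation_map")
}

padded_fft <- function(m, P) {
  z <- matrix(0, P[1], P[2])
  z[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  stats::fft(z)
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("correlation map (%s): %d x %d, max %.3f\n", x$mode,
              nrow(x$surface), ncol(x$surface), max(x$surface)))
  invisible(x)
}

#' Peak-value model of a code set
#'
#' For a query of `L` symbols with substitution rate `M`, codes with `N` ones
#' produce an expected true-alignment peak of `L N (1 - M)` if mismatched
#' symbols contributed nothing; in practice each mismatch contributes the
#' set-specific cross-talk constant `C` on average, giving
#' `L (N (1 - M) + C M)`.
#'
#' @param N Ones per code.
#' @param C Cross-talk constant (expected per-mismatch contribution at the
#'   true alignment), `0 <= C < N`; see [calibrate_C()].
#' @param E Acceptance margin of the code set (used for threshold slack).
#' @return An object of class `peak_model`.
#' @export
peak_model <- function(N, C, E = 0) {
  if (C < 0 || C >= N) stop("C must satisfy 0 <= C < N")
  structure(list(N = N, C = C, E = E), class = "peak_model")
}

#' Expected correlation peak under the mutation model
#'
#' @param L Query length in symbols (`>= 1`).
#' @param M Substitution rate in `[0, 1]`.
#' @param pm A [peak_model()] object.
#' @param normalized If `TRUE`, return the per-symbol coefficient (the peak
#'   divided by `L`).
#' @param model `"real"` (includes the mismatch cross-talk term `C M`) or
#'   `"zero"` (mutation-free model `N (1 - M)` with no cross-talk).
#' @return Expected peak value (or coefficient).
#' @examples
#' pm <- peak_model(N = 3, C = 1.2)
#' expected_peak(1, 0.1, pm, normalized = TRUE)  # 2.82
#' @export
expected_peak <- function(L, M, pm, normalized = FALSE,
                          model = c("real", "zero")) {
  model <- match.arg(model)
  stopifnot(inherits(pm, "peak_model"))
  if (any(M < 0 | M > 1)) stop("M must be in [0, 1]")
  if (any(L < 1)) stop("L must be >= 1")
  coef <- pm$N * (1 - M) + if (model == "real") pm$C * M else 0
  if (normalized) coef else L * coef
}

#' Calibrate the cross-talk constant C of a code set
#'
#' Monte-Carlo estimate: for each trial a random sequence of length `L` is
#' paired with a fully substituted copy (every symbol replaced by a
#' different, uniformly chosen symbol); the two encodings are
#' cross-correlated and the value at the exact-alignment offset, divided by
#' `L`, estimates the mean per-mismatch contribution. `C` is calibrated
#' empirically per code set because it depends on the set's bit patterns.
#'
#' @param cs A [make_codeset()] object (alphabet size must exceed 1).
#' @param trials Number of Monte-Carlo trials.
#' @param L Sequence length per trial.
#' @param seed Optional RNG seed.
#' @return List with `C` (mean estimate), `se` (standard error) and
#'   `trials`.
#' @export
calibrate_C <- function(cs, trials = 30, L = 100, seed = NULL) {
  stopifnot(inherits(cs, "codeset"))
  if (cs$K < 2L) stop("alphabet of size 1: no substitution possible")
  if (trials < 1L) stop("trials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(trials)
  for (t in seq_len(trials)) {
    s <- sample(cs$alphabet, L, replace = TRUE)
    sub <- mutate_sequence(paste(s, collapse = ""), 1, alphabet = cs$alphabet)
    if (cs$mode == "2D") {
      ia <- encode_sequence(paste(s, collapse = ""), cs, columns = L)
      ib <- encode_sequence(sub, cs, columns = L)
    } else {
      ia <- encode_sequence_1d(paste(s, collapse = ""), cs)
      ib <- encode_sequence_1d(sub, cs)
    }
    cm <- xcorr2(ib, ia)
    # images share a shape, so exact alignment sits at (Ha, Wa)
    vals[t] <- cm$surface[nrow(ib$raster), ncol(ib$raster)] / L
  }
  list(C = mean(vals), se = stats::sd(vals) / sqrt(trials), trials = trials)
}

#' Detect a query in an encoded reference
#'
#' Correlates the query image against the reference image, finds the peak
#' (restricted to the code lattice by default), and declares the query
#' present when the peak reaches the model threshold
#' `L (N (1 - M_max) + C M_max) - slack`, where `M_max` is the largest
#' substitution rate the detector should tolerate. When the peak lies on the
#' code lattice it is back-mapped to a 1-based reference sequence position.
#'
#' @param ref_img,query_img [encode_sequence()] results sharing the same
#'   code set, columns and pad.
#' @param pm A [peak_model()] for the code set.
#' @param M_max Largest tolerated substitution rate.
#' @param mode `"ideal"` or `"optical"`.
#' @param opt [optical_params()] for optical mode.
#' @param lattice If `TRUE`, search peaks only at code-lattice offsets
#'   (query fully inside the reference, aligned to cell boundaries);
#'   `FALSE` scans the whole surface (diagnostics).
#' @param slack Threshold slack; default `E * L / 2`.
#' @return A list of class `detection`: `present`, `peak_value`,
#'   `peak_offset` (surface row/col), `threshold_used`, `mapped_position`
#'   (sequence index or `NA`).
#' @export
detect_query <- function(ref_img, query_img, pm, M_max = 0,
                         mode = c("ideal", "optical"), opt = NULL,
                         lattice = TRUE, slack = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pm, "peak_model"))
  if (query_img$seq_len > ref_img$seq_len)
    stop("query is longer than the reference")
  if (query_img$cell != ref_img$cell || query_img$codeset$d != ref_img$codeset$d)
    stop("query and reference must share code set geometry")
  L <- query_img$seq_len
  if (is.null(slack)) slack <- pm$E * L / 2
  cm <- xcorr2(query_img, ref_img, mode = mode, opt = opt)
  S <- cm$surface
  if (mode == "ideal") S <- round(S)
  Hq <- nrow(query_img$raster); Wq <- ncol(query_img$raster)
  cell <- ref_img$cell
  if (lattice) {
    sr <- seq.int(Hq, nrow(ref_img$raster), by = cell)
    st <- seq.int(Wq, ncol(ref_img$raster), by = cell)
    sub <- S[sr, st, drop = FALSE]
    pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    peak_offset <- c(sr[pk[1]], st[pk[2]])
    peak_value <- sub[pk[1], pk[2]]
  } else {
    pk <- which(S == max(S), arr.ind = TRUE)[1, ]
    peak_offset <- as.integer(pk)
    peak_value <- S[pk[1], pk[2]]
  }
  threshold <- expected_peak(L, M_max, pm) - slack
  ar <- peak_offset[1] - Hq; ac <- peak_offset[2] - Wq  # 0-based raster pos
  mapped <- NA_integer_
  if (ar >= 0 && ac >= 0 && ar %% cell == 0 && ac %% cell == 0) {
    pos <- (ar %/% cell) * ref_img$columns + (ac %/% cell) + 1L
    if (pos <= ref_img$seq_len) mapped <- as.integer(pos)
  }
  structure(list(present = peak_value >= threshold, peak_value = peak_value,
                 peak_offset = as.integer(peak_offset),
                 threshold_used = threshold, mapped_position = mapped),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("detection: %s (peak %.2f vs threshold %.2f, position %s)\n",
              if (x$present) "present" else "absent", x$peak_value,
              x$threshold_used,
              if (is.na(x$mapped_position)) "off-lattice"
              else x$mapped_position))
  invisible(x)
}

#' Count k-mer occurrences by correlation
#'
#' Encodes the k-mer as a single code row and counts the offsets of the
#' correlation surface whose value reaches the full-peak threshold
#' `k N - slack`. For a zero-score code set only genuine, unbroken
#' occurrences reach the threshold (every junk offset stays below `N - E`
#' per symbol), so the count equals the true overlapping count minus
#' occurrences broken across a row wrap of the reference raster — the cutoff
#' error that the relative-error benchmark quantifies. Noisy code sets also
#' produce above-threshold junk peaks and over-count; `lattice = TRUE`
#' restricts counting to exact code-lattice alignments (diagnostics: it
#' hides the junk peaks a noisy set produces).
#'
#' @param ref_img An [encode_sequence()] result.
#' @param kmer Character string over the code set's alphabet
#'   (`1 <= k <=` reference length).
#' @param slack Threshold slack; default `E * k / 2`.
#' @param mode `"ideal"` or `"optical"`.
#' @param opt [optical_params()] for optical mode.
#' @param lattice Count only code-lattice alignment offsets (default
#'   `FALSE`: the whole surface, which is what a detector sees).
#' @return Integer count of detected occurrences.
#' @export
count_kmers <- function(ref_img, kmer, slack = NULL,
                        mode = c("ideal", "optical"), opt = NULL,
                        lattice = FALSE) {
  mode <- match.arg(mode)
  cs <- ref_img$codeset
  k <- nchar(kmer)
  if (k < 1L || k > ref_img$seq_len)
    stop("k must be in 1..reference length")
  if (k > ref_img$columns)
    stop("k exceeds the raster width in codes; no unbroken occurrence fits")
  syms <- check_symbols(kmer, cs$alphabet)  # errors on foreign symbols
  q <- if (cs$mode == "2D")
    encode_sequence(kmer, cs, columns = k, pad = ref_img$pad)
  else encode_sequence_1d(kmer, cs, pad = ref_img$pad)
  if (is.null(slack)) slack <- cs$E * k / 2
  cm <- xcorr2(q, ref_img, mode = mode, opt = opt)
  S <- cm$surface
  if (mode == "ideal") S <- round(S)
  thr <- k * cs$N - slack
  if (lattice) {
    Hq <- nrow(q$raster); Wq <- ncol(q$raster)
    cell <- ref_img$cell
    # start cells (r, c) with the whole k-window inside one row
    ecols <- min(ref_img$seq_len, ref_img$columns)
    sr <- seq.int(Hq, by = cell, length.out = ref_img$rows)
    st <- seq.int(Wq, by = cell, length.out = ecols - k + 1L)
    sum(S[sr, st, drop = FALSE] >= thr)
  } else {
    sum(S >= thr)
  }
}
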