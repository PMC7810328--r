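#' Random synthetic genome
#'
#' Uniform i.i.d. symbols — the null model the benchmark queries are drawn
#' from. Real genomes have composition bias and repeats that this generator
#' does not emulate; see the methods vignette for what that implies.
#'
#' @param n Length in symbols.
#' @param alphabet Symbols to draw from.
#' @param seed Optional RNG seed.
#' @return A character string of length `n`.
#' @export
random_genome <- function(n, alphabet = c("A", "C", "G", "T"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Substitute a fixed fraction of a sequence
#'
#' Exactly `round(rate * nchar(seq))` distinct positions, chosen uniformly
#' without replacement, are each replaced by a uniformly chosen *different*
#' symbol; length is preserved (substitutions only, no indels).
#'
#' @param seq Character string.
#' @param rate Substitution rate in `[0, 1]`.
#' @param alphabet Symbols to substitute from (size must exceed 1).
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, rate, alphabet = c("A", "C", "G", "T")) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (length(alphabet) < 2L) stop("alphabet size 1: no substitution possible")
  ch <- strsplit(seq, "")[[1]]
  m <- round(rate * length(ch))
  if (m == 0L) return(seq)
  pos <- sample.int(length(ch), m)
  for (p in pos) {
    ch[p] <- sample(setdiff(alphabet, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Benchmark configuration
#'
#' Reduced-scale defaults (100 kb reference, 30 queries of 50–1500 bp,
#' substitution rates 0–60% in steps of 10%) keep a full sweep in the
#' minutes range; the protocol itself mirrors a whole-genome evaluation with
#' 10 kb scenes of 100 x 100 symbols.
#'
#' @param n_queries Number of base queries (each is mutated at every rate).
#' @param length_range Min/max query length in symbols.
#' @param mutation_rates Substitution rates swept.
#' @param scene_bp Symbols per scene.
#' @param columns Codes per raster row.
#' @param pad Free-boundary width around each code cell.
#' @param seed RNG seed.
#' @param mode `"ideal"` or `"optical"`.
#' @param align_rows If `TRUE` (default) query start positions are drawn on
#'   the raster row grid, so an unmutated contained query is an exact
#'   sub-image of its scene; row-break handling is deferred and its cost is
#'   quantified separately by the k-mer cutoff error.
#' @param m_tolerance Detection tolerance `M_max`; default is the largest
#'   swept rate plus a 0.05 margin for the binomial fluctuation of the
#'   per-mismatch cross-talk sum.
#' @param noise_z Specificity guard: the detection threshold is never below
#'   `L mu + noise_z * sqrt(L sigma^2)`, where `mu` and `sigma^2` are the
#'   exact per-symbol mean and variance of the absent-query alignment null
#'   ([alignment_null()]). Default 5 (one-sided, with headroom for the
#'   ~10^4 lattice offsets scanned per pair).
#' @return A list of class `bench_config`.
#' @export
bench_config <- function(n_queries = 30, length_range = c(50, 1500),
                         mutation_rates = seq(0, 0.6, by = 0.1),
                         scene_bp = 10000, columns = 100, pad = 0,
                         seed = 1, mode = "ideal", align_rows = TRUE,
                         m_tolerance = NULL, noise_z = 5) {
  if (any(mutation_rates < 0 | mutation_rates > 1))
    stop("mutation rates must lie in [0, 1]")
  if (length_range[1] > length_range[2]) stop("length_range must be min <= max")
  if (is.null(m_tolerance))
    m_tolerance <- min(1, max(mutation_rates) + 0.05)
  structure(list(n_queries = n_queries, length_range = length_range,
                 mutation_rates = mutation_rates, scene_bp = scene_bp,
                 columns = columns, pad = pad, seed = seed, mode = mode,
                 align_rows = align_rows, m_tolerance = m_tolerance,
                 noise_z = noise_z),
            class = "bench_config")
}

#' Alignment null model of a code set
#'
#' Exact per-symbol mean and variance of the correlation contribution when a
#' random query symbol is laid over a random, unrelated reference symbol at
#' a code-lattice offset: the value is the aligned overlap
#' `<code_a, code_b>` of a uniform ordered symbol pair. This is the null
#' distribution that spurious (absent-query) lattice peaks are drawn from,
#' and the basis of the benchmark's specificity guard.
#'
#' @param cs A [make_codeset()] object.
#' @return List with `mu` and `sigma2` (per symbol).
#' @export
alignment_null <- function(cs) {
  vals <- outer(seq_len(cs$K), seq_len(cs$K),
                Vectorize(function(a, b) sum(cs$codes[[a]] * cs$codes[[b]])))
  mu <- mean(vals)
  list(mu = mu, sigma2 = mean((vals - mu)^2))
}

#' Build the benchmark query table
#'
#' Samples `n_queries` substrings of the reference with uniform lengths in
#' `length_range`, then produces one mutated copy per substitution rate.
#' Mutated copies of one query are *coupled* across rates: a single random
#' position order and a single replacement draw per position are shared, so
#' the positions mutated at a lower rate are a subset of those at a higher
#' rate. Marginally each copy still carries exactly `round(rate * length)`
#' uniform substitutions, but the coupling makes each query's true-alignment
#' peak exactly non-increasing in the rate (a standard coupling design that
#' removes spurious non-monotonicity from the sensitivity sweep).
#' Ground truth (the scene containing each query's start, and whether the
#' query straddles a scene boundary) comes from the sampled coordinates and
#' is verified against the reference by direct substring extraction.
#'
#' @param ref Reference sequence (character string).
#' @param cfg A [bench_config()].
#' @return A data frame with one row per (query, rate): `query_id`, `start`,
#'   `length`, `rate`, `scene` (1-based scene of the start), `straddle`
#'   (query crosses a scene boundary), `seq` (mutated sequence).
#' @export
build_benchmark <- function(ref, cfg) {
  stopifnot(inherits(cfg, "bench_config"))
  L <- nchar(ref)
  if (L <= cfg$length_range[2]) stop("reference shorter than the longest query")
  set.seed(cfg$seed)
  lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]),
                 cfg$n_queries, replace = TRUE)
  starts <- integer(cfg$n_queries)
  for (i in seq_len(cfg$n_queries)) {
    hi <- L - lens[i] + 1L
    if (cfg$align_rows) {
      grid <- seq.int(1L, hi, by = cfg$columns)
      starts[i] <- grid[sample.int(length(grid), 1L)]
    } else starts[i] <- sample.int(hi, 1L)
  }
  alpha <- c("A", "C", "G", "T")
  rows <- vector("list", cfg$n_queries * length(cfg$mutation_rates))
  j <- 0L
  for (i in seq_len(cfg$n_queries)) {
    orig <- substring(ref, starts[i], starts[i] + lens[i] - 1L)
    stopifnot(nchar(orig) == lens[i])
    scene <- (starts[i] - 1L) %/% cfg$scene_bp + 1L
    straddle <- (starts[i] + lens[i] - 1L - 1L) %/% cfg$scene_bp + 1L != scene
    # coupled mutations: one position order and one replacement per position
    ch <- strsplit(orig, "")[[1]]
    ord <- sample.int(lens[i])
    repl <- vapply(ch, function(s) sample(setdiff(alpha, s), 1L), character(1))
    for (r in cfg$mutation_rates) {
      j <- j + 1L
      m <- round(r * lens[i])
      mut <- ch
      if (m > 0L) mut[ord[seq_len(m)]] <- repl[ord[seq_len(m)]]
      rows[[j]] <- data.frame(
        query_id = i, start = starts[i], length = lens[i], rate = r,
        scene = scene, straddle = straddle,
        seq = paste(mut, collapse = ""))
    }
  }
  do.call(rbind, rows)
}

#' Confusion counts
#'
#' @param TP,TN,FP,FN Non-negative tallies; `n = TP + TN + FP + FN` is the
#'   search-space size.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP, TN, FP, FN)
  if (any(v < 0)) stop("counts must be non-negative")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, n = sum(v)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, exactitude and error
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Ex = (TP+TN)/n`,
#' `Er = (FP+FN)/n`; `Ex + Er = 1`. A ratio with a zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param cc A [confusion_counts()] object.
#' @return Named list with `Se`, `Sp`, `Ex`, `Er`, all in `[0, 1]` (or `NA`).
#' @export
quadruple_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$TP + cc$TN + cc$FP + cc$FN != cc$n)
    stop("inconsistent counts: TP+TN+FP+FN != n")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(Se = safe_div(cc$TP, cc$TP + cc$FN),
       Sp = safe_div(cc$TN, cc$TN + cc$FP),
       Ex = safe_div(cc$TP + cc$TN, cc$n),
       Er = safe_div(cc$FP + cc$FN, cc$n))
}

#' Relative counting error
#'
#' `|n_real - n_found| / n_real`; undefined (`NA`) when `n_real` is 0.
#'
#' @param n_real True occurrence count.
#' @param n_found Count reported by the detector.
#' @return Non-negative ratio, or `NA` when undefined.
#' @export
relative_error <- function(n_real, n_found) {
  if (n_real == 0) return(NA_real_)
  abs(n_real - n_found) / n_real
}

#' Throughput specification of the optical setup
#'
#' @param scene_width,scene_height Scene size in pixels (e.g. 4K:
#'   `4096 x 2160`).
#' @param d Code side length in pixels.
#' @param switching_speed Display switching speed, Hz.
#' @return A list of class `throughput_spec`.
#' @export
throughput_spec <- function(scene_width = 4096, scene_height = 2160, d = 3,
                            switching_speed = 2.44e6) {
  if (any(c(scene_width, scene_height, d, switching_speed) <= 0))
    stop("all throughput parameters must be positive")
  structure(list(scene_width = scene_width, scene_height = scene_height,
                 d = d, switching_speed = switching_speed),
            class = "throughput_spec")
}

#' Nucleotides fitting on one scene
#'
#' `floor(scene_width / d) * floor(scene_height / d)`: a code cannot
#' straddle the scene edge, so whole codes are counted per dimension
#' (4096 x 2160 pixels with 3 x 3 codes hold 1365 x 720 = 982800 codes).
#'
#' @param ts A [throughput_spec()].
#' @return Integer count.
#' @export
nucleotides_per_scene <- function(ts) {
  stopifnot(inherits(ts, "throughput_spec"))
  (ts$scene_width %/% ts$d) * (ts$scene_height %/% ts$d)
}

#' Scenes needed for a sequence or a query batch
#'
#' `ceiling(total bp / nucleotides per scene)`; for a query batch the worst
#' case `n_queries * max_length` total is used.
#'
#' @param ts A [throughput_spec()].
#' @param total_bp Total symbols to display (for a batch:
#'   `n_queries * max_length`).
#' @return Integer scene count.
#' @export
scene_count <- function(ts, total_bp) {
  ceiling(total_bp / nucleotides_per_scene(ts))
}

#' Predicted optical search time
#'
#' `query_scenes * ref_scenes / switching_speed` seconds — a model
#' prediction for the display-bound correlator, not a measurement.
#'
#' @param ts A [throughput_spec()].
#' @param ref_scenes,query_scenes Scene counts from [scene_count()].
#' @return Seconds.
#' @export
search_time <- function(ts, ref_scenes, query_scenes) {
  stopifnot(inherits(ts, "throughput_spec"))
  query_scenes * ref_scenes / ts$switching_speed
}

#' Number of pairwise scene comparisons
#'
#' `n (n - 1) / 2` for `n >= 2` scenes.
#'
#' @param n_scenes Scene count.
#' @return Integer.
#' @export
pairwise_comparisons <- function(n_scenes) {
  if (n_scenes < 2) stop("need at least 2 scenes")
  n_scenes * (n_scenes - 1) / 2
}

#' Run the detection benchmark
#'
#' Splits the reference into scenes, encodes them once, and runs
#' [detect_query()] for every (query, scene) pair of [build_benchmark()]'s
#' table, tallying confusion counts per substitution rate against the
#' coordinate ground truth (a query is present in the scene containing its
#' start; scene-straddling queries are tallied separately, not in the
#' confusion counts). Also accumulates the normalized true-alignment peak
#' (peak / L) of every present pair for the peak-model table.
#'
#' @param ref Reference sequence (character string).
#' @param cfg A [bench_config()].
#' @param cs Code set used for encoding (2D).
#' @param pm Optional [peak_model()]; defaults to `N` of `cs` with `C`
#'   calibrated by [calibrate_C()].
#' @param opt [optical_params()] when `cfg$mode == "optical"`.
#' @return A list of class `bench_result`: `metrics` (per-rate data frame
#'   with Se/Sp/Ex/Er and the confusion counts), `peaks` (per-rate mean and
#'   variance of the normalized true-alignment peak), `C` used,
#'   `n_straddle`, and the query table.
#' @export
run_bench <- function(ref, cfg, cs, pm = NULL, opt = NULL) {
  stopifnot(inherits(cfg, "bench_config"), inherits(cs, "codeset"))
  if (is.null(pm)) {
    cal <- calibrate_C(cs, trials = 30, L = 100, seed = cfg$seed)
    pm <- peak_model(cs$N, cal$C, cs$E)
  }
  qtab <- build_benchmark(ref, cfg)
  sc <- split_scenes(ref, cfg$scene_bp)
  scene_imgs <- lapply(sc$scenes, encode_sequence, cs = cs,
                       columns = cfg$columns, pad = cfg$pad)
  n_scenes <- length(scene_imgs)

  # shared padded FFT grid so each scene spectrum is computed once
  max_q_rows <- ceiling(max(qtab$length) / cfg$columns)
  cell <- cs$d + 2L * cfg$pad
  Hb <- max(vapply(scene_imgs, function(im) nrow(im$raster), integer(1)))
  Wb <- cfg$columns * cell
  P <- corr_pad_dims(max_q_rows * cell, Wb, Hb, Wb)
  mask <- if (cfg$mode == "optical") {
    if (is.null(opt)) stop("optical mode requires optical_params")
    pupil_mask(P[1], P[2], opt)
  } else NULL
  FBs <- lapply(scene_imgs, function(im) {
    FB <- padded_fft(im$raster, P)
    if (!is.null(mask)) FB * mask else FB
  })

  null <- alignment_null(cs)
  rates <- cfg$mutation_rates
  tal <- data.frame(rate = rates, TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  peaks <- stats::setNames(vector("list", length(rates)), as.character(rates))
  n_straddle <- sum(qtab$straddle[qtab$rate == rates[1]])
  for (qi in seq_len(nrow(qtab))) {
    qrow <- qtab[qi, ]
    if (qrow$straddle) next
    qimg <- encode_sequence(qrow$seq, cs, columns = cfg$columns, pad = cfg$pad)
    Hq <- nrow(qimg$raster); Wq <- ncol(qimg$raster)
    FA <- padded_fft(qimg$raster[Hq:1, Wq:1, drop = FALSE], P)
    if (!is.null(mask)) FA <- FA * mask
    L <- qrow$length
    thr <- max(expected_peak(L, cfg$m_tolerance, pm) - pm$E * L / 2,
               L * null$mu + cfg$noise_z * sqrt(L * null$sigma2))
    ri <- which(rates == qrow$rate)
    for (si in seq_len(n_scenes)) {
      Sfull <- Re(stats::fft(FA * FBs[[si]], inverse = TRUE)) / prod(P)
      S <- Sfull[seq_len(Hq + nrow(scene_imgs[[si]]$raster) - 1L),
                 seq_len(Wq + Wb - 1L), drop = FALSE]
      if (cfg$mode == "ideal") S <- round(S)
      sr <- seq.int(Hq, nrow(scene_imgs[[si]]$raster), by = cell)
      st <- seq.int(Wq, Wb, by = cell)
      pk <- max(S[sr, st])
      present <- pk >= thr
      truth <- si == qrow$scene
      if (truth) {
        if (present) tal$TP[ri] <- tal$TP[ri] + 1L
        else tal$FN[ri] <- tal$FN[ri] + 1L
        # normalized peak at the true alignment offset
        off <- qrow$start - sc$starts[si]  # 0-based symbol offset in scene
        s0 <- Hq + (off %/% cfg$columns) * cell
        t0 <- Wq + (off %% cfg$columns) * cell
        peaks[[ri]] <- c(peaks[[ri]], S[s0, t0] / L)
      } else {
        if (present) tal$FP[ri] <- tal$FP[ri] + 1L
        else tal$TN[ri] <- tal$TN[ri] + 1L
      }
    }
  }
  met <- lapply(seq_along(rates), function(i) {
    m <- quadruple_metrics(confusion_counts(tal$TP[i], tal$TN[i],
                                            tal$FP[i], tal$FN[i]))
    data.frame(rate = rates[i], Se = m$Se, Sp = m$Sp, Ex = m$Ex, Er = m$Er,
               TP = tal$TP[i], TN = tal$TN[i], FP = tal$FP[i], FN = tal$FN[i])
  })
  pk_tab <- data.frame(
    rate = rates,
    mean_norm_peak = vapply(peaks, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1)),
    var_norm_peak = vapply(peaks, function(v)
      if (length(v) > 1) stats::var(v) else NA_real_, numeric(1)),
    n = vapply(peaks, length, integer(1)))
  structure(list(metrics = do.call(rbind, met), peaks = pk_tab, C = pm$C,
                 n_straddle = n_straddle, queries = qtab,
                 n_scenes = n_scenes),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat("benchmark over", x$n_scenes, "scenes (C =", round(x$C, 3), "):\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Relative error of correlation-based k-mer counting
#'
#' Counts every k-mer of the given lengths in `seq` twice — by
#' [count_kmers()] on the encoded raster and by exact overlapping string
#' search — and reports the per-motif relative error. Zero-score code sets
#' err only through the row-wrap cutoff; noisy sets also over-count.
#'
#' @param seq Reference sequence (character string).
#' @param cs Code set to encode with.
#' @param kmax Count all motifs of length `1..kmax` over the alphabet.
#' @param columns,pad Raster layout (defaults 42 columns, no padding).
#' @param mode,opt Correlator mode, see [xcorr2()].
#' @return A data frame with one row per motif occurring at least once:
#'   `kmer`, `n_real`, `n_found`, `rel_error`.
#' @export
kmer_count_errors <- function(seq, cs, kmax = 4, columns = 42, pad = 0,
                              mode = "ideal", opt = NULL) {
  img <- encode_sequence(seq, cs, columns = columns, pad = pad)
  rows <- list()
  for (k in seq_len(kmax)) {
    motifs <- apply(expand.grid(rep(list(cs$alphabet), k)), 1, paste,
                    collapse = "")
    for (m in motifs) {
      real <- count_substring(seq, m)
      if (real == 0L) next
      found <- count_kmers(img, m, mode = mode, opt = opt)
      rows[[length(rows) + 1L]] <- data.frame(
        kmer = m, n_real = real, n_found = found,
        rel_error = relative_error(real, found))
    }
  }
  do.call(rbind, rows)
}

# exact overlapping substring count (ground truth)
count_substring <- function(seq, pat) {
  hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}
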