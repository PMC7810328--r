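#' Construct a validated code set
#'
#' A code set assigns to each symbol of an alphabet (e.g. A, C, G, T) a binary
#' code matrix of side `d` (2D mode) or a single row of length `d` (1D mode)
#' containing exactly `N` ones. `E` is the peak-acceptance margin: the gap, in
#' correlation counts, required between the full-peak height `N` and the
#' tallest tolerated overlap-noise peak. Cell indices are 1-based and
#' row-major within a code.
#'
#' @param d Code side length in cells (1D codes are `1 x d`).
#' @param N Number of ones per code; `1 <= N <= d^2` (2D) or `<= d` (1D).
#' @param E Peak-acceptance margin, `0 <= E <= N - 1`.
#' @param alphabet Character vector of symbols, one per code (e.g.
#'   `c("A","C","G","T")`).
#' @param positions Named list (one entry per symbol) of `N` unique cell
#'   indices in `1..d^2` (2D) or `1..d` (1D).
#' @param mode `"2D"` (square codes) or `"1D"` (row codes).
#' @param score Optional cached overlap-noise cost (see [overlap_cost()]).
#' @return An object of class `codeset` with fields `d`, `N`, `E`, `K`,
#'   `mode`, `alphabet`, `positions`, `codes` (list of binary matrices) and
#'   `score`.
#' @examples
#' cs <- make_codeset(3, 2, 0, c("A", "C", "G", "T"),
#'                    list(A = c(1, 5), C = c(2, 7), G = c(4, 9), T = c(3, 8)))
#' cs$codes$A
#' @export
make_codeset <- function(d, N, E, alphabet, positions, mode = c("2D", "1D"),
                         score = NULL) {
  mode <- match.arg(mode)
  d <- as.integer(d); N <- as.integer(N); E <- as.integer(E)
  ncell <- if (mode == "2D") d * d else d
  if (d < 1L) stop("d must be >= 1")
  if (N < 1L || N > ncell)
    stop("N must be in 1..", ncell, " for mode ", mode)
  if (E < 0L || E >= N) stop("E must satisfy 0 <= E <= N-1")
  alphabet <- as.character(alphabet)
  K <- length(alphabet)
  if (K < 1L) stop("alphabet must be non-empty")
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be unique")
  if (!is.list(positions) || length(positions) != K)
    stop("positions must be a list with one entry per alphabet symbol")
  if (is.null(names(positions))) names(positions) <- alphabet
  if (!setequal(names(positions), alphabet))
    stop("names(positions) must match the alphabet")
  positions <- positions[alphabet]
  codes <- vector("list", K)
  names(codes) <- alphabet
  for (s in alphabet) {
    idx <- as.integer(positions[[s]])
    if (length(idx) != N)
      stop("positions for symbol '", s, "' must contain exactly N = ", N,
           " indices")
    if (anyDuplicated(idx))
      stop("duplicate cell index within the chunk for symbol '", s, "'")
    if (any(idx < 1L | idx > ncell))
      stop("cell index out of range 1..", ncell, " for symbol '", s, "'")
    positions[[s]] <- idx
    codes[[s]] <- code_from_indices(idx, d, mode)
  }
  structure(
    list(d = d, N = N, E = E, K = K, mode = mode, alphabet = alphabet,
         positions = positions, codes = codes,
         score = if (is.null(score)) NULL else as.integer(score)),
    class = "codeset")
}

# row-major materialisation of a code from its 1-based cell indices
code_from_indices <- function(idx, d, mode) {
  if (mode == "2D") {
    m <- matrix(0L, d, d)
    m[cbind((idx - 1L) %/% d + 1L, (idx - 1L) %% d + 1L)] <- 1L
  } else {
    m <- matrix(0L, 1L, d)
    m[1L, idx] <- 1L
  }
  m
}

#' @export
print.codeset <- function(x, ...) {
  cat(sprintf("codeset: %s, d=%d, N=%d, E=%d, K=%d (%s)\n",
              x$mode, x$d, x$N, x$E, x$K,
              paste(x$alphabet, collapse = "")))
  if (!is.null(x$score)) cat("  cached score:", x$score, "\n")
  invisible(x)
}

#' Build a c-grid from a code set
#'
#' A c-grid is the minimal tiling over which overlap noise must be checked:
#' a 2 x 2 array of codes in 2D mode (raster `2d x 2d`), or a 1 x 2 array in
#' 1D mode (raster `1 x 2d`). `cells` are 1-based indices into the code set's
#' alphabet.
#'
#' @param cs A [make_codeset()] object.
#' @param cells Integer vector of code indices: length 4 (2D, row-major
#'   `[c1 c2; c3 c4]`) or length 2 (1D).
#' @return A list with `cells` and the tiled binary `raster`
#'   (exactly `4N` or `2N` ones).
#' @export
make_cgrid <- function(cs, cells) {
  stopifnot(inherits(cs, "codeset"))
  cells <- as.integer(cells)
  d <- cs$d
  if (cs$mode == "2D") {
    if (length(cells) != 4L) stop("2D c-grid needs 4 code indices")
    raster <- matrix(0L, 2L * d, 2L * d)
    org <- list(c(0L, 0L), c(0L, d), c(d, 0L), c(d, d))
    for (q in 1:4) {
      o <- org[[q]]
      raster[o[1] + seq_len(d), o[2] + seq_len(d)] <- cs$codes[[cells[q]]]
    }
  } else {
    if (length(cells) != 2L) stop("1D c-grid needs 2 code indices")
    raster <- cbind(cs$codes[[cells[1]]], cs$codes[[cells[2]]])
  }
  if (any(cells < 1L | cells > cs$K)) stop("code index out of range")
  list(cells = cells, raster = raster)
}

#' Full linear cross-correlation of a code with a c-grid raster
#'
#' Direct sliding-window implementation (the definitional form): surface
#' entry `(s, t)` is the dot product of the code with the raster when the
#' code's top-left cell sits over raster coordinate `(s - d + 1, t - d + 1)`.
#' The surface covers every offset with non-empty overlap, so its size is
#' `(3d - 1) x (3d - 1)` in 2D mode and `1 x (3d - 1)` in 1D mode; entries
#' are non-negative integers bounded by `N`.
#'
#' @param code A binary `d x d` (or `1 x d`) matrix.
#' @param grid A c-grid from [make_cgrid()] (or any list with a `raster`
#'   matrix of matching shape).
#' @return Integer matrix of correlation values.
#' @export
correlate_code_with_grid <- function(code, grid) {
  raster <- grid$raster
  dh <- nrow(code); dw <- ncol(code)
  if (nrow(raster) != 2L * dh && !(dh == 1L && nrow(raster) == 1L))
    stop("shape mismatch between code and grid raster")
  if (ncol(raster) != 2L * dw) stop("shape mismatch between code and grid raster")
  H <- nrow(raster); W <- ncol(raster)
  out <- matrix(0L, H + dh - 1L, W + dw - 1L)
  for (s in seq_len(nrow(out))) {
    r0 <- s - dh  # raster row of code row 1, 0-based
    ri <- seq_len(dh) + r0
    ok_r <- ri >= 1L & ri <= H
    if (!any(ok_r)) next
    for (t in seq_len(ncol(out))) {
      c0 <- t - dw
      ci <- seq_len(dw) + c0
      ok_c <- ci >= 1L & ci <= W
      if (!any(ok_c)) next
      out[s, t] <- sum(code[ok_r, ok_c, drop = FALSE] *
                         raster[ri[ok_r], ci[ok_c], drop = FALSE])
    }
  }
  out
}

# pairwise full cross-correlation map of two codes (small, direct);
# entry (u, v), u,v in 1..(2d-1), is the overlap when code a's top-left is at
# (u - d + 1, v - d + 1) relative to code b's top-left.
code_pair_corr <- function(a, b) {
  dh <- nrow(a); dw <- ncol(a)
  out <- matrix(0L, 2L * dh - 1L, 2L * dw - 1L)
  for (u in seq_len(nrow(out))) {
    r0 <- u - dh
    ra <- which(seq_len(dh) + r0 >= 1L & seq_len(dh) + r0 <= dh)
    for (v in seq_len(ncol(out))) {
      c0 <- v - dw
      ca <- which(seq_len(dw) + c0 >= 1L & seq_len(dw) + c0 <= dw)
      out[u, v] <- sum(a[ra, ca, drop = FALSE] *
                         b[ra + r0, ca + c0, drop = FALSE])
    }
  }
  out
}

#' Overlap-noise cost of a code set
#'
#' Enumerates every c-grid that the alphabet can tile (`K^4` grids in 2D,
#' `K^2` in 1D) and slides every code over each (`K^5` resp. `K^3` states).
#' An offset is counted as an invalid peak when its correlation value reaches
#' `N - E` or more, except at exact-alignment offsets where the sliding code
#' overlays a grid cell holding the *same* symbol — those are the full
#' (informative) peaks. Exact alignment with a *different* symbol's code does
#' count, which penalises duplicate or near-duplicate codes. The genetic
#' algorithm minimises this count; a set with cost 0 is a "zero-score"
#' coding.
#'
#' @param cs A [make_codeset()] object.
#' @param per_state If `TRUE`, also return the invalid-peak count for every
#'   (grid, sliding code) state.
#' @return A list of class `cost_report`: `total_invalid`, `max_noise`
#'   (largest correlation value at any counted offset), `n_states`, and
#'   optionally `per_state` (a `K^4 x K` or `K^2 x K` matrix).
#' @export
overlap_cost <- function(cs, per_state = FALSE) {
  stopifnot(inherits(cs, "codeset"))
  d <- cs$d; K <- cs$K; N <- cs$N; E <- cs$E
  two_d <- cs$mode == "2D"
  # surface of sliding a code over the grid raster
  SH <- if (two_d) 3L * d - 1L else 1L
  SW <- 3L * d - 1L
  PH <- if (two_d) 2L * d - 1L else 1L
  PW <- 2L * d - 1L
  # quadrant origins of grid cells within the raster (0-based row, col)
  org <- if (two_d) list(c(0L, 0L), c(0L, d), c(d, 0L), c(d, d))
         else list(c(0L, 0L), c(0L, d))
  nq <- length(org)
  # scatter index: pairwise-map entry (u, v) lands at surface entry
  # (u + org_r, v + org_c); as linear indices into the SH x SW surface
  pu <- rep(seq_len(PH), times = PW)
  pv <- rep(seq_len(PW), each = PH)
  scatter <- lapply(org, function(o) (pv + o[2] - 1L) * SH + (pu + o[1]))
  # full-peak (exact alignment) surface position for each quadrant
  align_row <- if (two_d) d else 1L
  align_pos <- vapply(org, function(o) (d + o[2] - 1L) * SH + (align_row + o[1]),
                      integer(1))
  # all grids as rows of a (K^nq) x nq index matrix
  grids <- as.matrix(expand.grid(rep(list(seq_len(K)), nq),
                                 KEEP.OUT.ATTRS = FALSE))
  ng <- nrow(grids)
  # pairwise correlation maps, flattened
  pair <- array(0, dim = c(PH * PW, K, K))
  for (a in seq_len(K)) for (b in seq_len(K))
    pair[, a, b] <- as.vector(code_pair_corr(cs$codes[[a]], cs$codes[[b]]))
  thr <- N - E
  total <- 0
  max_noise <- 0L
  if (per_state) ps <- matrix(0L, ng, K)
  for (cc in seq_len(K)) {
    # per-quadrant scatter of pair maps of sliding code cc vs each symbol
    A <- lapply(seq_len(nq), function(q) {
      m <- matrix(0, SH * SW, K)
      m[scatter[[q]], ] <- pair[, cc, ]
      m
    })
    V <- A[[1]][, grids[, 1], drop = FALSE]
    for (q in 2:nq) V <- V + A[[q]][, grids[, q], drop = FALSE]
    # mask out same-symbol exact alignments (full peaks)
    for (q in seq_len(nq)) {
      same <- which(grids[, q] == cc)
      if (length(same)) V[align_pos[q], same] <- -Inf
    }
    fin <- V > -Inf
    max_noise <- max(max_noise, max(V[fin]))
    inv <- V >= thr & fin
    total <- total + sum(inv)
    if (per_state) ps[, cc] <- colSums(inv)
  }
  rep <- list(total_invalid = as.integer(total),
              max_noise = as.integer(max_noise),
              n_states = ng * K)
  if (per_state) rep$per_state <- ps
  structure(rep, class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("overlap cost: %d invalid peaks over %d states (max noise %d)\n",
              x$total_invalid, x$n_states, x$max_noise))
  invisible(x)
}

#' Is a code set zero-score?
#'
#' `TRUE` iff the overlap-noise cost is zero, i.e. every counted off-match
#' correlation value is at most `N - E - 1`.
#'
#' @param cs A [make_codeset()] object.
#' @return Logical scalar.
#' @export
is_zero_score <- function(cs) {
  overlap_cost(cs)$total_invalid == 0L
}

#' Relative threshold of a code set
#'
#' The dimensionless ratio `E / N`, which makes the acceptance margin
#' comparable across code sets of different size and weight.
#'
#' @param cs A [make_codeset()] object (or any list with `N` and `E`).
#' @return A number in `[0, 1)`.
#' @export
relative_threshold <- function(cs) {
  if (cs$N <= 0) stop("N must be positive")
  cs$E / cs$N
}

#' Write a code set to its JSON sidecar format
#'
#' The sidecar stores `d`, `N`, `E`, `mode`, the alphabet, the per-symbol
#' cell indices and the cached score (if any); [read_codeset()] round-trips
#' it losslessly.
#'
#' @param cs A [make_codeset()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codeset <- function(cs, path) {
  stopifnot(inherits(cs, "codeset"))
  obj <- list(d = cs$d, N = cs$N, E = cs$E, mode = cs$mode,
              alphabet = cs$alphabet,
              positions = cs$positions,
              score = if (is.null(cs$score)) NULL else cs$score)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a code set from its JSON sidecar format
#'
#' @param path Path to a file written by [write_codeset()].
#' @return A [make_codeset()] object.
#' @export
read_codeset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_codeset(obj$d, obj$N, obj$E, obj$alphabet,
               as.list(obj$positions), mode = obj$mode,
               score = obj$score)
}
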