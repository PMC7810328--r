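#' Random valid individual
#'
#' An individual is the genetic algorithm's flat chromosome: `K * N` cell
#' indices, where chunk `k` (genes `[(k-1)N + 1, kN]`) holds the `N` unique
#' one-positions of symbol `k`'s code.
#'
#' @param d,N,K Code side length, ones per code, alphabet size.
#' @param mode `"2D"` or `"1D"`.
#' @return Integer vector of length `K * N`.
#' @export
random_individual <- function(d, N, K, mode = c("2D", "1D")) {
  mode <- match.arg(mode)
  ncell <- if (mode == "2D") d * d else d
  if (N > ncell) stop("N exceeds the number of cells")
  unlist(lapply(seq_len(K), function(k) sample.int(ncell, N)))
}

#' Decode an individual into a code set
#'
#' @param genes Integer vector of length `K * N` (see [random_individual()]).
#' @param d,N,E Code-set parameters.
#' @param alphabet Alphabet symbols (length `K`).
#' @param mode `"2D"` or `"1D"`.
#' @return A [make_codeset()] object.
#' @export
decode_individual <- function(genes, d, N, E, alphabet, mode = c("2D", "1D")) {
  mode <- match.arg(mode)
  K <- length(alphabet)
  if (length(genes) != K * N) stop("genes must have length K * N")
  pos <- split(as.integer(genes), rep(seq_len(K), each = N))
  names(pos) <- alphabet
  make_codeset(d, N, E, alphabet, pos, mode = mode)
}

#' Fitness of an individual
#'
#' Minus the overlap-noise cost of the decoded code set; 0 is optimal.
#'
#' @inheritParams decode_individual
#' @return Integer `<= 0`.
#' @export
individual_fitness <- function(genes, d, N, E, alphabet, mode = c("2D", "1D")) {
  -overlap_cost(decode_individual(genes, d, N, E, alphabet, mode))$total_invalid
}

#' Mutate an individual
#'
#' Picks a random chunk, a random entry within it, and replaces that entry
#' with a cell index not already present in the chunk, so chunk uniqueness is
#' preserved. Exactly one gene changes; the input is not modified.
#'
#' @param genes Integer vector of length `K * N`.
#' @param d,N Code parameters; the number of cells must exceed `N` so a free
#'   index exists.
#' @param mode `"2D"` or `"1D"`.
#' @return The mutated gene vector.
#' @export
mutate_individual <- function(genes, d, N, mode = c("2D", "1D")) {
  mode <- match.arg(mode)
  ncell <- if (mode == "2D") d * d else d
  if (ncell <= N) stop("no free cell index: d^2 (or d) must exceed N")
  K <- length(genes) %/% N
  k <- sample.int(K, 1L)
  i <- sample.int(N, 1L)
  chunk <- genes[((k - 1L) * N + 1L):(k * N)]
  free <- setdiff(seq_len(ncell), chunk)
  genes[(k - 1L) * N + i] <- free[sample.int(length(free), 1L)]
  genes
}

#' Chunk-boundary crossover of two individuals
#'
#' Recombination cuts only at chunk boundaries, so every offspring chunk is
#' copied intact from one parent and chunk validity is inherited.
#'
#' @param p1,p2 Parent gene vectors of equal length `K * N`.
#' @param N Ones per code (chunk length).
#' @return List of two offspring gene vectors.
#' @export
crossover_individuals <- function(p1, p2, N) {
  if (length(p1) != length(p2)) stop("parents must have the same shape")
  K <- length(p1) %/% N
  if (K < 2L) return(list(p1, p2))
  cut <- sample.int(K - 1L, 1L)  # after chunk `cut`
  i <- seq_len(cut * N)
  list(c(p1[i], p2[-i]), c(p2[i], p1[-i]))
}

#' Evolve a code set with the genetic algorithm
#'
#' Searches for a zero-score (or minimum-cost) code set for the given
#' `(d, N, E)` and alphabet. Each cycle selects the two fittest members,
#' recombines them at a chunk boundary, mutates each offspring with
#' probability `mutation_prob`, and accepts the offspring — replacing the two
#' worst members — only if both beat the current worst fitness. Evolution
#' stops when an individual reaches fitness 0 or after `max_cycles` cycles;
#' non-convergence is reported, not raised.
#'
#' @param d,N,E Code-set parameters.
#' @param alphabet Alphabet symbols (default DNA).
#' @param mode `"2D"` or `"1D"`.
#' @param pop_size Population size (constant across cycles).
#' @param mutation_prob Per-offspring mutation probability.
#' @param max_cycles Cycle budget.
#' @param seed RNG seed; runs are bit-reproducible given the same seed and
#'   parameters.
#' @param init Optional starting individual (e.g. a highly fitted seed); the
#'   initial population is `pop_size - 1` repeated mutations of it, plus
#'   itself.
#' @param history_every Record best/mean fitness every this many cycles.
#' @return A list of class `evolve_result`: `best` (a [make_codeset()] object
#'   with its score cached), `best_fitness`, `cycles` run, `converged`,
#'   `history` (data frame), and `seed`.
#' @examples
#' \donttest{
#' res <- gac_evolve(3, 2, 0, seed = 1, max_cycles = 5000)
#' res$best_fitness
#' }
#' @export
gac_evolve <- function(d, N, E, alphabet = c("A", "C", "G", "T"),
                       mode = c("2D", "1D"), pop_size = 50,
                       mutation_prob = 0.3, max_cycles = 200000,
                       seed = NULL, init = NULL, history_every = 50) {
  mode <- match.arg(mode)
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (max_cycles < 1) stop("max_cycles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  K <- length(alphabet)
  fit_of <- function(g) individual_fitness(g, d, N, E, alphabet, mode)

  if (is.null(init)) init <- random_individual(d, N, K, mode)
  pop <- vector("list", pop_size)
  pop[[1]] <- init
  for (i in seq_len(pop_size - 1L))
    pop[[i + 1L]] <- mutate_individual(init, d, N, mode)
  fits <- vapply(pop, fit_of, numeric(1))

  hist_cyc <- integer(0); hist_best <- numeric(0); hist_mean <- numeric(0)
  record <- function(cycle) {
    hist_cyc <<- c(hist_cyc, cycle)
    hist_best <<- c(hist_best, max(fits))
    hist_mean <<- c(hist_mean, mean(fits))
  }
  record(0L)
  cycle <- 0L
  while (max(fits) < 0 && cycle < max_cycles) {
    cycle <- cycle + 1L
    ord <- order(-fits, seq_along(fits))  # ties broken by lower member index
    parents <- ord[1:2]
    off <- crossover_individuals(pop[[parents[1]]], pop[[parents[2]]], N)
    for (j in 1:2)
      if (stats::runif(1) < mutation_prob)
        off[[j]] <- mutate_individual(off[[j]], d, N, mode)
    worst_fit <- min(fits)
    of <- vapply(off, fit_of, numeric(1))
    if (all(of > worst_fit)) {
      worst_idx <- order(fits, -seq_along(fits))[1:2]
      pop[worst_idx] <- off
      fits[worst_idx] <- of
    }
    if (cycle %% history_every == 0L || max(fits) == 0) record(cycle)
  }
  best_i <- which.max(fits)
  best_cs <- decode_individual(pop[[best_i]], d, N, E, alphabet, mode)
  best_cs$score <- as.integer(-fits[best_i])
  structure(
    list(best = best_cs, best_fitness = as.integer(fits[best_i]),
         cycles = cycle, converged = fits[best_i] == 0,
         history = data.frame(cycle = hist_cyc, best = hist_best,
                              mean = hist_mean),
         seed = seed),
    class = "evolve_result")
}

#' @export
print.evolve_result <- function(x, ...) {
  cat(sprintf("GA result: best fitness %d after %d cycles (%s)\n",
              x$best_fitness, x$cycles,
              if (x$converged) "zero-score found" else "budget exhausted"))
  invisible(x)
}
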