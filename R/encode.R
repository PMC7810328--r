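#' Read sequences from a FASTA file
#'
#' Thin wrapper around `Biostrings::readBStringSet()` (with a plain-text
#' fallback parser when Biostrings is not installed). Sequences are
#' upper-cased. Symbols outside `alphabet` are rejected (`policy = "strict"`)
#' or dropped with a message (`policy = "skip"`); ambiguity codes such as
#' `N` fall under the same policy.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Allowed symbols; `NULL` disables the check.
#' @param policy `"strict"` (error on foreign symbols) or `"skip"` (drop
#'   them, reporting the count).
#' @return A data frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path, alphabet = c("A", "C", "G", "T"),
                       policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    ids <- names(set)
    seqs <- as.character(set)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (length(lines) && !hdr[1]) stop("malformed FASTA: no header line")
    grp <- cumsum(hdr)
    ids <- sub("^>", "", lines[hdr])
    seqs <- vapply(seq_along(ids), function(i)
      paste(lines[grp == i & !hdr], collapse = ""), character(1))
  }
  if (length(ids) == 0L)
    return(data.frame(id = character(0), sequence = character(0)))
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(seqs)
  if (!is.null(alphabet)) {
    dropped <- 0L
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[i], "")[[1]]
      bad <- !(ch %in% alphabet)
      if (any(bad)) {
        if (policy == "strict")
          stop("record '", ids[i], "' contains ", sum(bad),
               " symbol(s) outside the alphabet")
        dropped <- dropped + sum(bad)
        seqs[i] <- paste(ch[!bad], collapse = "")
      }
    }
    if (dropped > 0L)
      message("read_fasta: dropped ", dropped, " out-of-alphabet symbol(s)")
  }
  data.frame(id = ids, sequence = unname(seqs))
}

#' Encode a sequence as a simulated-SLM binary raster
#'
#' Symbols are laid left-to-right, wrapping to a new row every `columns`
#' symbols; each symbol's `d x d` code is centred in its
#' `(d + 2 pad) x (d + 2 pad)` cell, so `pad` zero pixels surround every code
#' on all four sides (a "free boundary" that suppresses halo cross-talk in
#' the band-limited optical mode). The tail of the last row is zero-filled.
#'
#' @param seq A character string over the code set's alphabet.
#' @param cs A 2D [make_codeset()] object.
#' @param columns Codes per raster row (default 42).
#' @param pad Free-boundary width in pixels around each code cell.
#' @return An object of class `encoded_image`: `raster` (binary matrix with
#'   exactly `seq_len * N` ones, `min(seq_len, columns) * (d + 2 pad)` pixels
#'   wide and `ceil(seq_len / columns) * (d + 2 pad)` high), `codeset`,
#'   `columns`, `pad`, `cell` (`d + 2 pad`), `seq_len`, `rows`.
#' @export
encode_sequence <- function(seq, cs, columns = 42, pad = 0) {
  stopifnot(inherits(cs, "codeset"))
  if (cs$mode != "2D") stop("encode_sequence needs a 2D code set")
  syms <- check_symbols(seq, cs$alphabet)
  L <- length(syms)
  columns <- as.integer(columns); pad <- as.integer(pad)
  if (columns < 1L) stop("columns must be >= 1")
  if (pad < 0L) stop("pad must be >= 0")
  d <- cs$d; cell <- d + 2L * pad
  rows <- ceiling(L / columns)
  # a sequence shorter than one row only occupies L cells; trimming the
  # raster to the occupied width keeps sliding-offset ranges meaningful
  width <- min(L, columns) * cell
  raster <- matrix(0L, rows * cell, width)
  ci <- match(syms, cs$alphabet)
  for (i in seq_len(L)) {
    r <- (i - 1L) %/% columns
    cc <- (i - 1L) %% columns
    raster[r * cell + pad + seq_len(d), cc * cell + pad + seq_len(d)] <-
      cs$codes[[ci[i]]]
  }
  structure(list(raster = raster, codeset = cs, columns = columns, pad = pad,
                 cell = cell, seq_len = L, rows = rows, mode = "2D"),
            class = "encoded_image")
}

#' Encode a sequence as a single-row raster of 1D codes
#'
#' @param seq A character string over the code set's alphabet.
#' @param cs A 1D [make_codeset()] object.
#' @param pad Free-boundary width in pixels around each code cell.
#' @return An `encoded_image` with a `1 x (seq_len * (d + 2 pad))` raster
#'   (row height 1: 1D codes have no vertical extent, so `pad` widens cells
#'   horizontally only).
#' @export
encode_sequence_1d <- function(seq, cs, pad = 0) {
  stopifnot(inherits(cs, "codeset"))
  if (cs$mode != "1D") stop("encode_sequence_1d needs a 1D code set")
  syms <- check_symbols(seq, cs$alphabet)
  L <- length(syms)
  pad <- as.integer(pad)
  d <- cs$d; cell <- d + 2L * pad
  raster <- matrix(0L, 1L, L * cell)
  ci <- match(syms, cs$alphabet)
  for (i in seq_len(L))
    raster[1L, (i - 1L) * cell + pad + seq_len(d)] <- cs$codes[[ci[i]]]
  structure(list(raster = raster, codeset = cs, columns = L, pad = pad,
                 cell = cell, seq_len = L, rows = 1L, mode = "1D"),
            class = "encoded_image")
}

check_symbols <- function(seq, alphabet) {
  if (length(seq) == 1L && is.character(seq)) syms <- strsplit(seq, "")[[1]]
  else syms <- as.character(seq)
  if (length(syms) == 0L) stop("sequence is empty")
  syms <- toupper(syms)
  bad <- !(syms %in% alphabet)
  if (any(bad))
    stop("symbol(s) not in alphabet: ",
         paste(unique(syms[bad]), collapse = ", "))
  syms
}

#' @export
print.encoded_image <- function(x, ...) {
  cat(sprintf("encoded image: %d symbols, %d x %d raster (%d columns, pad %d)\n",
              x$seq_len, nrow(x$raster), ncol(x$raster), x$columns, x$pad))
  invisible(x)
}

#' Recover the sequence from an encoded image
#'
#' Reads each cell of the raster back through the code set's layout; used to
#' verify that encoding is lossless.
#'
#' @param img An [encode_sequence()] result.
#' @return The decoded character string.
#' @export
decode_image <- function(img) {
  cs <- img$codeset
  d <- cs$d; pad <- img$pad; cell <- img$cell
  out <- character(img$seq_len)
  for (i in seq_len(img$seq_len)) {
    r <- (i - 1L) %/% img$columns
    cc <- (i - 1L) %% img$columns
    if (img$mode == "1D") {
      block <- img$raster[1L, (i - 1L) * cell + pad + seq_len(d), drop = FALSE]
    } else {
      block <- img$raster[r * cell + pad + seq_len(d),
                          cc * cell + pad + seq_len(d), drop = FALSE]
    }
    hit <- which(vapply(cs$codes, function(m) all(m == block), logical(1)))
    if (length(hit) != 1L) stop("cell ", i, " does not match a unique code")
    out[i] <- cs$alphabet[hit]
  }
  paste(out, collapse = "")
}

#' Raster origin of an encoded symbol
#'
#' Maps a 1-based symbol index to the top-left pixel (1-based row, col) of
#' its code within the raster — the layout map used to back-map correlation
#' peaks to sequence positions.
#'
#' @param img An `encoded_image`.
#' @param i Symbol index (vectorised).
#' @return A two-column matrix of (row, col) origins.
#' @export
symbol_origin <- function(img, i) {
  i <- as.integer(i)
  if (any(i < 1L | i > img$seq_len)) stop("symbol index out of range")
  r <- (i - 1L) %/% img$columns
  cc <- (i - 1L) %% img$columns
  cbind(row = r * img$cell + img$pad + 1L, col = cc * img$cell + img$pad + 1L)
}

#' Split a sequence into consecutive scenes
#'
#' A scene is the block of symbols that fits on one display frame of the
#' simulated input device. Chunks are non-overlapping and consecutive; the
#' final scene may be shorter.
#'
#' @param seq A character string.
#' @param scene_bp Symbols per scene.
#' @return A list of class `scene_set`: `scenes` (character vector),
#'   `starts` (1-based start of each scene), `scene_bp`.
#' @export
split_scenes <- function(seq, scene_bp) {
  scene_bp <- as.integer(scene_bp)
  if (scene_bp < 1L) stop("scene_bp must be >= 1")
  L <- nchar(seq)
  starts <- seq.int(1L, L, by = scene_bp)
  scenes <- substring(seq, starts, pmin(starts + scene_bp - 1L, L))
  structure(list(scenes = scenes, starts = starts, scene_bp = scene_bp),
            class = "scene_set")
}
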