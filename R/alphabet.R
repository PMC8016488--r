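#' Extended IUPAC amino-acid alphabet
#'
#' The 26-letter residue alphabet used by the embedding network: the 20
#' standard amino acids plus the ambiguity and rare codes B, J, O, U, X and Z
#' (which together cover all letters A--Z). Symbols are indexed 1..26 in
#' alphabetical order; index 0 is reserved for padding and is never a residue.
#'
#' @return An object of class `og_alphabet` with fields `symbols`, `index_of`,
#'   `padding_index` and `ambiguity_table` (empty for this alphabet: the
#'   embedding learns its own representation for ambiguous codes).
#' @examples
#' ab <- extended_alphabet()
#' length(ab$symbols)  # 26
#' ab$index_of[["A"]]  # 1
#' @export
extended_alphabet <- function() {
  symbols <- LETTERS
  structure(
    list(
      symbols = symbols,
      index_of = stats::setNames(seq_along(symbols), symbols),
      padding_index = 0L,
      ambiguity_table = list()
    ),
    class = "og_alphabet"
  )
}

#' Baseline 21-letter amino-acid alphabet with ambiguity interpolation
#'
#' The alphabet of the fixed-length one-hot baseline encoding: the 20 standard
#' amino acids plus 'X' (unknown). Ambiguous codes interpolate between their
#' manifestations (B = 1/2 D + 1/2 N, J = 1/2 I + 1/2 L, Z = 1/2 E + 1/2 Q);
#' the rare codes O and U map to 'X'.
#'
#' @return An `og_alphabet` whose `ambiguity_table` maps each non-member
#'   symbol to a data frame of (symbol, weight) rows summing to 1.
#' @export
baseline_alphabet <- function() {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  symbols <- c(std, "X")
  half <- function(a, b) data.frame(symbol = c(a, b), weight = c(0.5, 0.5))
  to_x <- data.frame(symbol = "X", weight = 1)
  structure(
    list(
      symbols = symbols,
      index_of = stats::setNames(seq_along(symbols), symbols),
      padding_index = 0L,
      ambiguity_table = list(
        B = half("D", "N"),
        J = half("I", "L"),
        Z = half("E", "Q"),
        O = to_x,
        U = to_x
      )
    ),
    class = "og_alphabet"
  )
}

std_residues <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Uppercase, strip one trailing '*', map anything outside the extended
# alphabet (including internal '*') to 'X'. Returns the cleaned string;
# errors if nothing is left.
sanitize_sequence <- function(sequence, id = "<sequence>") {
  s <- toupper(sequence)
  if (nchar(s) > 0 && substr(s, nchar(s), nchar(s)) == "*") {
    warning(sprintf("record '%s': stripped trailing stop symbol '*'", id),
            call. = FALSE)
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% LETTERS)
  if (any(bad)) {
    warning(sprintf(
      "record '%s': replaced %d character(s) outside the amino-acid alphabet by 'X'",
      id, sum(bad)), call. = FALSE)
    chars[bad] <- "X"
  }
  if (length(chars) == 0L) {
    stop(sprintf("record '%s': sequence is empty after sanitation", id),
         call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Encode a protein sequence as integer residue indices
#'
#' Sanitizes the sequence (uppercasing, stripping a single trailing stop
#' symbol `*`, replacing characters outside the alphabet by `X`, each with a
#' warning) and maps each residue to its 1-based alphabet index.
#'
#' @param record A sequence string, or a list/one-row data frame with fields
#'   `id` and `sequence` (as returned by [read_fasta()]).
#' @param alphabet An `og_alphabet`; defaults to [extended_alphabet()].
#' @return An object of class `og_encoded`: list with integer `indices` and
#'   `length` (number of real residues).
#' @examples
#' enc <- encode_sequence("ACD")
#' enc$indices  # 1 2 3
#' @export
encode_sequence <- function(record, alphabet = extended_alphabet()) {
  if (is.character(record)) record <- list(id = "<sequence>", sequence = record)
  s <- sanitize_sequence(record$sequence, record$id)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- unname(alphabet$index_of[chars])
  if (anyNA(idx)) {
    # symbol not in this alphabet (e.g. ambiguity code under the baseline
    # 21-letter alphabet): fall back to 'X'
    idx[is.na(idx)] <- alphabet$index_of[["X"]]
  }
  structure(list(indices = as.integer(idx), length = length(idx)),
            class = "og_encoded")
}

#' Decode integer residue indices back to a sequence string
#'
#' @param encoded An `og_encoded` object.
#' @param alphabet The alphabet used for encoding.
#' @return Character scalar.
#' @export
decode_sequence <- function(encoded, alphabet = extended_alphabet()) {
  paste(alphabet$symbols[encoded$indices], collapse = "")
}

#' Pad encoded sequences into a rectangular batch
#'
#' Right-pads every sequence with the padding index 0 up to the longest
#' sequence in the batch, but never below `min_length` so that the largest
#' convolution filter (size 36 by default) always has at least one window.
#'
#' @param seqs List of `og_encoded` objects.
#' @param min_length Minimum batch width; default 36, the largest default
#'   filter size.
#' @return An `og_batch`: list with integer `matrix` (batch x width) and
#'   `lengths`.
#' @export
pad_and_batch <- function(seqs, min_length = 36L) {
  if (inherits(seqs, "og_encoded")) seqs <- list(seqs)
  if (length(seqs) == 0L) stop("cannot batch an empty list of sequences")
  lens <- vapply(seqs, function(e) e$length, integer(1))
  width <- max(max(lens), as.integer(min_length))
  m <- matrix(0L, nrow = length(seqs), ncol = width)
  for (b in seq_along(seqs)) {
    m[b, seq_len(lens[b])] <- seqs[[b]]$indices
  }
  structure(list(matrix = m, lengths = lens), class = "og_batch")
}

#' Fixed-length pseudo one-hot encoding (baseline network input)
#'
#' Encodes a sequence as a `fixed_length` x 21 real matrix over the baseline
#' alphabet (20 standard residues + X). Each residue row sums to 1; ambiguous
#' codes split weight over their manifestations (B = 1/2 D + 1/2 N,
#' J = 1/2 I + 1/2 L, Z = 1/2 E + 1/2 Q); O and U map to X. Rows beyond the
#' sequence are all zero (zero padding). Sequences longer than `fixed_length`
#' are rejected (the baseline discards them), returning `NULL` with a warning.
#'
#' @param record Sequence string or record with `id`/`sequence`.
#' @param fixed_length Input length the baseline network expects; default 1000.
#' @return Numeric matrix `fixed_length` x 21 with residue symbols as column
#'   names, or `NULL` if the sequence is too long.
#' @export
encode_pseudo_onehot <- function(record, fixed_length = 1000L) {
  if (is.character(record)) record <- list(id = "<sequence>", sequence = record)
  s <- sanitize_sequence(record$sequence, record$id)
  L <- nchar(s)
  if (L > fixed_length) {
    warning(sprintf(
      "record '%s': length %d exceeds the fixed input length %d; discarded",
      record$id, L, fixed_length), call. = FALSE)
    return(NULL)
  }
  ab <- baseline_alphabet()
  m <- matrix(0, nrow = fixed_length, ncol = length(ab$symbols),
              dimnames = list(NULL, ab$symbols))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (t in seq_len(L)) {
    ch <- chars[t]
    if (!is.null(ab$ambiguity_table[[ch]])) {
      tab <- ab$ambiguity_table[[ch]]
      m[t, tab$symbol] <- tab$weight
    } else if (ch %in% ab$symbols) {
      m[t, ch] <- 1
    } else {
      m[t, "X"] <- 1
    }
  }
  m
}

# Lookup tables mapping extended-alphabet indices (1..26) to baseline one-hot
# columns: col1/w1 always set; col2/w2 used for the two-way ambiguity codes.
onehot_tables <- function() {
  ext <- extended_alphabet()
  base <- baseline_alphabet()
  n <- length(ext$symbols)
  col1 <- integer(n); w1 <- numeric(n)
  col2 <- rep(NA_integer_, n); w2 <- numeric(n)
  for (i in seq_len(n)) {
    sym <- ext$symbols[i]
    amb <- base$ambiguity_table[[sym]]
    if (!is.null(amb)) {
      col1[i] <- base$index_of[[amb$symbol[1]]]
      w1[i] <- amb$weight[1]
      if (nrow(amb) > 1) {
        col2[i] <- base$index_of[[amb$symbol[2]]]
        w2[i] <- amb$weight[2]
      }
    } else if (sym %in% base$symbols) {
      col1[i] <- base$index_of[[sym]]
      w1[i] <- 1
    } else {
      col1[i] <- base$index_of[["X"]]
      w1[i] <- 1
    }
  }
  list(col1 = col1, w1 = w1, col2 = col2, w2 = w2)
}

# Batch of pseudo one-hot encodings as a fixed_length x 21 x B array, built
# from extended-alphabet integer encodings. Internal fast path for the
# baseline network.
onehot_batch <- function(seqs, fixed_length) {
  tabs <- onehot_tables()
  B <- length(seqs)
  arr <- array(0, dim = c(fixed_length, 21L, B))
  for (b in seq_len(B)) {
    idx <- seqs[[b]]$indices
    L <- length(idx)
    if (L > fixed_length) {
      stop(sprintf("sequence of length %d exceeds fixed input length %d",
                   L, fixed_length))
    }
    pos <- seq_len(L)
    arr[cbind(pos, tabs$col1[idx], b)] <- tabs$w1[idx]
    two <- !is.na(tabs$col2[idx])
    if (any(two)) {
      arr[cbind(pos[two], tabs$col2[idx[two]], b)] <- tabs$w2[idx[two]]
    }
  }
  arr
}
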