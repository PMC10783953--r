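#' Tokenizer configuration
#'
#' Amino-acid sequences are padded at the beginning with `pad_char` until the
#' length is divisible by `word_size`, then split into non-overlapping words
#' of exactly `word_size` characters. Each word is further decomposed into
#' the multiset of all its contiguous substrings ("sub-words"): at the
#' default word size of 3 every word has exactly 6 sub-words.
#'
#' @param word_size residues per word (default 3).
#' @param pad_char single padding character, outside the amino-acid alphabet.
#' @param alphabet allowed residue characters (default: 20 standard amino acids).
#' @param gap_char optional gap character (e.g. `"-"` for aligned allele
#'   sequences) admitted into the alphabet as an ordinary symbol.
#' @return an object of class `tokenizer_config`.
#' @examples
#' cfg <- tokenizer_config()
#' pad_sequence("ABCD", cfg)       # "^^ABCD"
#' split_into_words("^^ABCD", cfg) # "^^A" "BCD"
#' enumerate_subwords("BCD")       # B C D BC CD BCD
#' @export
tokenizer_config <- function(word_size = 3L, pad_char = "^",
                             alphabet = AA_STANDARD, gap_char = NULL) {
  word_size <- as.integer(word_size)
  stopifnot(length(word_size) == 1L, word_size >= 1L,
            is.character(pad_char), nchar(pad_char) == 1L)
  if (!is.null(gap_char)) {
    stopifnot(nchar(gap_char) == 1L)
    alphabet <- union(alphabet, gap_char)
  }
  if (pad_char %in% alphabet)
    stop("pad_char must not be part of the alphabet")
  structure(list(word_size = word_size, pad_char = pad_char,
                 alphabet = alphabet, gap_char = gap_char),
            class = "tokenizer_config")
}

check_alphabet <- function(chars, cfg, what = "sequence") {
  bad <- which(!(chars %in% cfg$alphabet))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d of %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Pad a sequence at the beginning to a multiple of the word size
#'
#' @param seq single amino-acid string (case-insensitive).
#' @param cfg a [tokenizer_config()].
#' @return the padded string; padding is prepended only.
#' @export
pad_sequence <- function(seq, cfg = tokenizer_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty input", call. = FALSE)
  check_alphabet(strsplit(seq, "", fixed = TRUE)[[1L]], cfg)
  k <- (cfg$word_size - nchar(seq) %% cfg$word_size) %% cfg$word_size
  paste0(strrep(cfg$pad_char, k), seq)
}

#' Split a padded sequence into non-overlapping words
#'
#' @param padded string whose length is divisible by the word size.
#' @param cfg a [tokenizer_config()].
#' @return character vector of words, in order.
#' @export
split_into_words <- function(padded, cfg = tokenizer_config()) {
  stopifnot(is.character(padded), length(padded) == 1L)
  n <- nchar(padded)
  w <- cfg$word_size
  if (n == 0L || n %% w != 0L)
    stop("length not divisible by word_size; pad the sequence first",
         call. = FALSE)
  substring(padded, seq(1L, n, by = w), seq(w, n, by = w))
}

#' Enumerate the sub-word multiset of a word
#'
#' All contiguous substrings, enumerated by position: repeated substrings of
#' a word such as `"AAA"` appear once per position, so every word of size 3
#' yields exactly 6 sub-words.
#'
#' @param word a string of exactly `word_size` characters.
#' @param cfg a [tokenizer_config()].
#' @return character vector of `word_size * (word_size + 1) / 2` sub-words,
#'   ordered by length then start position.
#' @export
enumerate_subwords <- function(word, cfg = tokenizer_config()) {
  k <- nchar(word)
  if (k != cfg$word_size)
    stop(sprintf("word '%s' does not have word_size = %d characters",
                 word, cfg$word_size), call. = FALSE)
  out <- character(0)
  for (len in seq_len(k)) {
    starts <- seq_len(k - len + 1L)
    out <- c(out, substring(word, starts, starts + len - 1L))
  }
  out
}

#' Tokenize an amino-acid sequence into padded words
#'
#' Composes [pad_sequence()] and [split_into_words()], recording how many
#' padding characters were prepended.
#'
#' @inheritParams pad_sequence
#' @return an object of class `pmhc_tokens`: list with `source` (uppercased
#'   input), `words`, and `pad_count`.
#' @export
tokenize <- function(seq, cfg = tokenizer_config()) {
  padded <- pad_sequence(seq, cfg)
  words <- split_into_words(padded, cfg)
  structure(list(source = toupper(seq), words = words,
                 pad_count = nchar(padded) - nchar(seq)),
            class = "pmhc_tokens")
}

#' @export
print.pmhc_tokens <- function(x, ...) {
  cat(sprintf("Tokenized sequence: %s\n  %d word(s): %s\n  pad_count: %d\n",
              x$source, length(x$words), paste(x$words, collapse = " "),
              x$pad_count))
  invisible(x)
}
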