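# Byte-pair-encoding SMILES tokenizer.
#
# The base alphabet is the set of single characters observed in the training
# corpus; multi-character atoms such as "Cl" and "Br" are learned as merges
# like any other frequent pair. Merges are appended greedily by pair
# frequency; frequency ties are broken by lexicographic order of the merged
# string so that retraining on the same corpus is bit-identical.

.SPECIAL_TOKENS <- c("[PAD]", "[CLS_S]", "[SEP]", "[UNK]")

#' Train a BPE subword vocabulary on a SMILES corpus
#'
#' @param corpus Character vector of SMILES strings.
#' @param vocab_size Target total vocabulary size (specials + alphabet +
#'   merges). Training stops early if no adjacent pair occurs at least twice.
#' @return A `bpe_vocab`: `$tokens` (id order; ids are row positions),
#'   `$merges` (list of character pairs in learned order), `$specials`
#'   (named integer ids), `$alphabet`.
#' @export
train_bpe <- function(corpus, vocab_size = 300) {
  if (length(corpus) == 0L) stop("corpus is empty")
  seqs <- strsplit(corpus, "", fixed = TRUE)
  alphabet <- sort(unique(unlist(seqs)))
  base_n <- length(alphabet) + length(.SPECIAL_TOKENS)
  if (vocab_size < base_n) {
    stop("vocab_size ", vocab_size, " is smaller than specials + observed ",
         "character set (", base_n, ")")
  }
  merges <- list()
  n_merges <- vocab_size - base_n
  while (length(merges) < n_merges) {
    pair_strings <- unlist(lapply(seqs, function(s) {
      n <- length(s)
      if (n < 2L) return(character())
      paste(s[-n], s[-1L], sep = "\x1f")
    }))
    if (length(pair_strings) == 0L) break
    tab <- table(pair_strings)  # keys carry a \x1f separator between the two tokens
    best_freq <- max(tab)
    if (best_freq < 2L) break
    cands <- names(tab)[tab == best_freq]
    merged_strings <- gsub("\x1f", "", cands, fixed = TRUE)
    best <- cands[order(merged_strings)][1L]
    pair <- strsplit(best, "\x1f", fixed = TRUE)[[1]]
    merges[[length(merges) + 1L]] <- pair
    seqs <- lapply(seqs, .bpe_apply_merge, a = pair[1], b = pair[2])
  }
  tokens <- c(.SPECIAL_TOKENS, alphabet,
              vapply(merges, function(p) paste0(p[1], p[2]), character(1)))
  structure(list(tokens = tokens,
                 merges = merges,
                 specials = stats::setNames(seq_along(.SPECIAL_TOKENS),
                                            .SPECIAL_TOKENS),
                 alphabet = alphabet),
            class = "bpe_vocab")
}

# Replace every (left-to-right, non-overlapping) adjacent occurrence of the
# pair (a, b) in a token vector with the merged token.
.bpe_apply_merge <- function(s, a, b) {
  n <- length(s)
  if (n < 2L) return(s)
  hits <- which(s[-n] == a & s[-1L] == b)
  if (length(hits) == 0L) return(s)
  keep <- rep(TRUE, n)
  last <- -1L
  for (h in hits) {
    if (h > last) {
      s[h] <- paste0(a, b)
      keep[h + 1L] <- FALSE
      last <- h + 1L
    }
  }
  s[keep]
}

#' @export
print.bpe_vocab <- function(x, ...) {
  cat("<bpe_vocab>", length(x$tokens), "tokens (",
      length(x$alphabet), "chars,", length(x$merges), "merges )\n")
  invisible(x)
}

#' Tokenize a SMILES string
#'
#' Applies the learned merges in training order and frames the result with
#' `[CLS_S]` ... `[SEP]`.
#'
#' @param smiles A single SMILES string (may be empty).
#' @param vocab A `bpe_vocab`.
#' @param max_len Maximum framed sequence length; longer sequences error.
#' @return Integer vector of token ids.
#' @export
tokenize <- function(smiles, vocab, max_len = 100L) {
  stopifnot(inherits(vocab, "bpe_vocab"), length(smiles) == 1L)
  s <- strsplit(smiles, "", fixed = TRUE)[[1]]
  bad <- setdiff(s, vocab$alphabet)
  if (length(bad) > 0) {
    stop("character(s) not in tokenizer alphabet: ",
         paste(unique(bad), collapse = " "))
  }
  for (p in vocab$merges) {
    if (length(s) < 2L) break
    s <- .bpe_apply_merge(s, p[1], p[2])
  }
  ids <- c(vocab$specials[["[CLS_S]"]],
           match(s, vocab$tokens),
           vocab$specials[["[SEP]"]])
  if (length(ids) > max_len) {
    stop("tokenized length ", length(ids), " exceeds max_len ", max_len)
  }
  as.integer(ids)
}

#' Tokenize many SMILES strings
#'
#' @param smiles Character vector.
#' @inheritParams tokenize
#' @return List of integer id vectors.
#' @export
tokenize_batch <- function(smiles, vocab, max_len = 100L) {
  lapply(smiles, tokenize, vocab = vocab, max_len = max_len)
}

#' Invert tokenization
#'
#' @param ids Integer vector framed by `[CLS_S]` and `[SEP]`.
#' @param vocab A `bpe_vocab`.
#' @return The SMILES string spelled by the subwords between the frame.
#' @export
detokenize <- function(ids, vocab) {
  stopifnot(inherits(vocab, "bpe_vocab"))
  if (any(ids < 1L | ids > length(vocab$tokens))) {
    stop("unknown token id(s): ",
         paste(ids[ids < 1L | ids > length(vocab$tokens)], collapse = ", "))
  }
  if (ids[1L] != vocab$specials[["[CLS_S]"]] ||
      ids[length(ids)] != vocab$specials[["[SEP]"]]) {
    stop("token sequence is not framed by [CLS_S] ... [SEP]")
  }
  inner <- ids[-c(1L, length(ids))]
  paste(vocab$tokens[inner], collapse = "")
}

#' Save a BPE vocabulary as JSON
#'
#' @param vocab A `bpe_vocab`.
#' @param path File path.
#' @export
vocab_save <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab$tokens,
                            merges = vocab$merges,
                            specials = as.list(vocab$specials),
                            alphabet = vocab$alphabet),
                       path, auto_unbox = FALSE, digits = NA)
}

#' Load a BPE vocabulary from JSON
#'
#' @param path File path written by [vocab_save()].
#' @return A `bpe_vocab`.
#' @export
vocab_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  merges <- if (is.matrix(obj$merges)) {
    lapply(seq_len(nrow(obj$merges)), function(i) obj$merges[i, ])
  } else if (is.list(obj$merges)) {
    lapply(obj$merges, unlist)
  } else {
    list()
  }
  structure(list(tokens = obj$tokens,
                 merges = merges,
                 specials = stats::setNames(as.integer(obj$specials),
                                            names(obj$specials)),
                 alphabet = obj$alphabet),
            class = "bpe_vocab")
}
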