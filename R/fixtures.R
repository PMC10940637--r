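# Deterministic toy data generators.
#
# Molecules are assembled by concatenating chemically composable SMILES
# fragments and validated with the parser before emission, so every emitted
# string is a valid molecule; generation is reproducible from the seed and
# needs no network or external files. The fragments are short so that a
# small BPE vocabulary is learnable from modest corpora. No chemical
# plausibility is claimed for the toy reactions; they exercise the seq2seq
# machinery.

.DEFAULT_FRAGMENTS <- c("C", "CC", "CCC", "N", "O", "CO", "CN", "S",
                        "C(C)", "C(=O)", "C(=O)O", "C(F)", "C(Cl)",
                        "C(Br)", "C(N)", "c1ccccc1", "C1CCCCC1",
                        "c1ccncc1", "C(=O)N")

#' Specification for a toy SMILES corpus
#'
#' @param n Number of molecules.
#' @param seed RNG seed.
#' @param max_fragments Maximum fragments concatenated per molecule.
#' @param fragments Fragment alphabet (each must itself be a valid SMILES
#'   piece that can be concatenated at both ends).
#' @return A `toy_corpus_spec`.
#' @export
toy_corpus_spec <- function(n, seed = 7L, max_fragments = 4L,
                            fragments = .DEFAULT_FRAGMENTS) {
  stopifnot(n >= 1)
  if (length(fragments) == 0L) stop("fragment alphabet is empty")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 max_fragments = as.integer(max_fragments),
                 fragments = fragments),
            class = "toy_corpus_spec")
}

#' Generate a deterministic toy SMILES corpus
#'
#' Candidates are random fragment concatenations; each batch of candidates
#' is validated with the parser and rejected candidates are resampled, so
#' every returned string parses. Emitted strings are unique (corpora are
#' sets of molecules; duplicates would act as false negatives in the
#' contrastive objective).
#'
#' @param spec A `toy_corpus_spec`.
#' @return Character vector of `spec$n` distinct valid SMILES.
#' @export
generate_toy_corpus <- function(spec) {
  stopifnot(inherits(spec, "toy_corpus_spec"))
  set.seed(spec$seed)
  out <- character(0)
  guard <- 0L
  while (length(out) < spec$n && guard < 200L) {
    need <- spec$n - length(out)
    cand <- vapply(seq_len(need * 1.2 + 4), function(i) {
      one <- function() {
        k <- sample.int(spec$max_fragments, 1L)
        paste(sample(spec$fragments, k, replace = TRUE), collapse = "")
      }
      # ~10% multi-component molecules (salt/mixture style), so downstream
      # tokenizers see the "." separator during pre-training
      if (stats::runif(1) < 0.1) paste(one(), one(), sep = ".") else one()
    }, character(1))
    ok <- smiles_is_valid(cand)
    out <- unique(c(out, cand[ok]))
    guard <- guard + 1L
  }
  if (length(out) < spec$n) stop("could not assemble enough valid molecules")
  out[seq_len(spec$n)]
}

#' Generate deterministic toy reaction pairs
#'
#' Esterification-style templates: an acid `A-C(=O)O` and an alcohol `B-O`
#' combine into the ester `A-C(=O)O-B`. Both sides are validated; pairs
#' whose sides fail to parse are resampled.
#'
#' @param n Number of reaction pairs.
#' @param seed RNG seed.
#' @return data.frame with character columns `reactants` (dot-separated)
#'   and `product`.
#' @export
generate_toy_reactions <- function(n, seed = 7L) {
  stopifnot(n >= 1)
  set.seed(seed)
  bodies <- c("C", "CC", "CCC", "CC(C)", "CCN", "CCO", "Cc1ccccc1",
              "CC(F)", "CCS", "CCCC", "CC(Cl)", "CCc1ccncc1")
  res <- list()
  guard <- 0L
  while (length(res) < n && guard < 50L) {
    need <- n - length(res)
    a <- sample(bodies, need * 1.2 + 4, replace = TRUE)
    b <- sample(bodies, need * 1.2 + 4, replace = TRUE)
    reactants <- paste0(a, "C(=O)O", ".", b, "O")
    # the acid ester-bonds through its hydroxyl oxygen: A-C(=O)-O-B
    product <- paste0(a, "C(=O)O", b)
    ok <- smiles_is_valid(reactants) & smiles_is_valid(product)
    for (i in which(ok)) {
      if (length(res) < n) {
        res[[length(res) + 1L]] <- c(reactants[i], product[i])
      }
    }
    guard <- guard + 1L
  }
  if (length(res) < n) stop("could not assemble enough valid reactions")
  df <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  names(df) <- c("reactants", "product")
  df
}

#' Write a corpus as a .smi file (one SMILES per line)
#' @param corpus Character vector of SMILES.
#' @param path Output path.
#' @export
corpus_save <- function(corpus, path) writeLines(corpus, path)

#' Read a .smi corpus
#' @param path File with one SMILES per line.
#' @return Character vector.
#' @export
corpus_load <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
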