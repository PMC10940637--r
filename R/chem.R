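# Open Babel backed SMILES utilities.
#
# All molecule I/O goes through the `obabel` command-line tool. Batch calls
# tag every input molecule with a synthetic title so that invalid SMILES --
# which Open Babel silently drops from the output stream -- can be detected
# by absence while keeping the remaining rows aligned.

.ob_available <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- nzchar(Sys.which("obabel"))
    cached
  }
})

.ob_check <- function() {
  if (!.ob_available()) {
    stop("the 'obabel' executable is required but was not found on PATH")
  }
}

# Run obabel over a batch of SMILES. Returns a data.frame with one row per
# input (NA rows for molecules obabel rejected): columns `out` (first
# tab-field of the output line) and `extra` (whitespace-split fields after
# the title, as a list column), aligned with `smiles`.
.ob_batch <- function(smiles, out_format = "can", extra_args = character()) {
  .ob_check()
  n <- length(smiles)
  out <- rep(NA_character_, n)
  extra <- vector("list", n)
  usable <- which(!is.na(smiles) & nzchar(trimws(smiles)) &
                    !grepl("[[:space:]]", trimws(smiles)))
  if (length(usable) == 0L) {
    return(list(out = out, extra = extra))
  }
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(trimws(smiles[usable]), paste0("t", usable)), fin)
  args <- c(paste0("-ismi"), fin, paste0("-o", out_format), "-O", fout,
            "-e", extra_args)
  suppressWarnings(system2("obabel", args, stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout)) {
    return(list(out = out, extra = extra))
  }
  lines <- readLines(fout, warn = FALSE)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    tab <- regexpr("\t", ln, fixed = TRUE)
    if (tab < 0) next
    body <- substr(ln, 1L, tab - 1L)
    rest <- strsplit(trimws(substr(ln, tab + 1L, nchar(ln))), "[[:space:]]+")[[1]]
    if (length(rest) == 0L) next
    idx <- suppressWarnings(as.integer(sub("^t", "", rest[[1]])))
    if (is.na(idx) || idx < 1L || idx > n) next
    out[idx] <- body
    extra[[idx]] <- if (length(rest) > 1L) rest[-1L] else character()
  }
  list(out = out, extra = extra)
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to Open Babel's canonical form. Strings that do not
#' parse as molecules yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @export
smiles_canonical <- function(smiles) {
  if (length(smiles) == 0L) return(character())
  .ob_batch(smiles, "can")$out
}

#' Test SMILES validity
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector: does each string parse as a molecule?
#' @export
smiles_is_valid <- function(smiles) {
  !is.na(smiles_canonical(smiles))
}

# Open Babel descriptor names the backend can request via --append.
.OB_DESCRIPTORS <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
                     "atoms", "bonds", "abonds", "sbonds", "dbonds", "tbonds",
                     "rotors")

# Batch-compute Open Babel descriptors. Returns a numeric matrix
# length(smiles) x length(props) with NA rows for invalid molecules.
.ob_properties <- function(smiles, props = .OB_DESCRIPTORS) {
  stopifnot(all(props %in% .OB_DESCRIPTORS))
  res <- .ob_batch(smiles, "smi",
                   extra_args = c("--append", paste(props, collapse = " ")))
  m <- matrix(NA_real_, nrow = length(smiles), ncol = length(props),
              dimnames = list(NULL, props))
  for (i in seq_along(smiles)) {
    ex <- res$extra[[i]]
    if (!is.null(ex) && length(ex) == length(props)) {
      m[i, ] <- suppressWarnings(as.numeric(ex))
    }
  }
  m
}

# Rewrite a single SMILES starting from a given heavy-atom index (Open Babel
# SMILES writer option "f"). Returns NA on failure.
.ob_rewrite_from_atom <- function(smiles, atom_idx) {
  res <- .ob_batch(smiles, "smi", extra_args = c("-xf", as.character(atom_idx)))
  res$out[[1]]
}

# Lexical scan of a canonical SMILES: counts of atom tokens and syntactic
# features. This is token counting on a string whose grammar Open Babel has
# already validated, not a molecular parser; ring counts use the cyclomatic
# number (bonds - atoms + components), which equals the SSSR ring count.
.smiles_lexical <- function(can_smiles) {
  s <- can_smiles
  counts <- c(nC = 0, nc_arom = 0, nN = 0, nn_arom = 0, nO = 0, no_arom = 0,
              nS = 0, ns_arom = 0, nP = 0, nCl = 0, nBr = 0, nI = 0, nB = 0,
              n_bracket = 0, n_pos = 0, n_neg = 0)
  i <- 1L
  nch <- nchar(s)
  while (i <= nch) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, nch), fixed = TRUE)
      body <- substr(s, i + 1L, i + j - 2L)
      counts["n_bracket"] <- counts["n_bracket"] + 1
      counts["n_pos"] <- counts["n_pos"] + lengths(regmatches(body, gregexpr("\\+", body)))
      counts["n_neg"] <- counts["n_neg"] + lengths(regmatches(body, gregexpr("-", body)))
      elem <- regmatches(body, regexpr("^[0-9]*([A-Z][a-z]?|[a-z])", body))
      elem <- sub("^[0-9]*", "", elem)
      key <- switch(elem,
                    "C" = "nC", "c" = "nc_arom", "N" = "nN", "n" = "nn_arom",
                    "O" = "nO", "o" = "no_arom", "S" = "nS", "s" = "ns_arom",
                    "P" = "nP", "Cl" = "nCl", "Br" = "nBr", "I" = "nI",
                    "B" = "nB", NULL)
      if (!is.null(key)) counts[key] <- counts[key] + 1
      i <- i + j
    } else if (ch %in% c("C", "B")) {
      two <- substr(s, i, i + 1L)
      if (two == "Cl") {
        counts["nCl"] <- counts["nCl"] + 1; i <- i + 2L
      } else if (two == "Br") {
        counts["nBr"] <- counts["nBr"] + 1; i <- i + 2L
      } else {
        counts[if (ch == "C") "nC" else "nB"] <-
          counts[if (ch == "C") "nC" else "nB"] + 1
        i <- i + 1L
      }
    } else {
      key <- switch(ch, "c" = "nc_arom", "N" = "nN", "n" = "nn_arom",
                    "O" = "nO", "o" = "no_arom", "S" = "nS", "s" = "ns_arom",
                    "P" = "nP", "I" = "nI", NULL)
      if (!is.null(key)) counts[key] <- counts[key] + 1
      i <- i + 1L
    }
  }
  n_branch <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  ring_digits <- lengths(regmatches(s, gregexpr("%[0-9][0-9]|[0-9]", s)))
  n_components <- lengths(regmatches(s, gregexpr(".", s, fixed = TRUE))) + 1L
  c(counts,
    n_branch = as.numeric(n_branch),
    n_ring_closure = as.numeric(ring_digits) / 2,
    n_components = as.numeric(n_components),
    smiles_length = as.numeric(nch))
}

# Convert SMILES to igraph molecular graphs (heavy atoms only), via an
# obabel SDF conversion parsed with ChemmineR. Returns a list of igraph
# objects (NULL for invalid molecules), vertices carrying `element`, edges
# carrying `order`.
.smiles_to_graphs <- function(smiles) {
  .ob_check()
  n <- length(smiles)
  out <- vector("list", n)
  valid <- which(!is.na(smiles) & nzchar(trimws(smiles)) &
                   !grepl("[[:space:]]", trimws(smiles)))
  if (length(valid) == 0L) return(out)
  fin <- tempfile(fileext = ".smi")
  fsdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fsdf)), add = TRUE)
  writeLines(paste(trimws(smiles[valid]), paste0("t", valid)), fin)
  suppressWarnings(system2("obabel", c("-ismi", fin, "-osdf", "-O", fsdf, "-e"),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(fsdf) || file.size(fsdf) == 0) return(out)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(fsdf))
  ok <- ChemmineR::validSDF(sdfs)
  for (k in seq_along(sdfs@SDF)) {
    if (!ok[k]) next
    sdf <- sdfs@SDF[[k]]
    idx <- suppressWarnings(as.integer(sub("^t", "", ChemmineR::sdfid(sdfs[k]))))
    if (is.na(idx)) next
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_[0-9]+$", "", rownames(ab))
    g <- igraph::make_empty_graph(n = nrow(ab), directed = FALSE)
    igraph::V(g)$element <- elements
    if (!is.null(bb) && nrow(bb) > 0) {
      ends <- as.vector(t(bb[, 1:2, drop = FALSE]))
      g <- igraph::add_edges(g, ends)
      igraph::E(g)$order <- as.numeric(bb[, 3])
    }
    out[[idx]] <- g
  }
  out
}
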