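# Descriptor registry and property-vector construction.
#
# A property vector (PV) is a fixed-order list of scalar molecular
# descriptors, z-scored with corpus statistics, in which any position may be
# masked as [UNK] ("value unspecified"). The registry fixes the identity and
# order of the descriptors for the lifetime of a model; positional embeddings
# in the PV encoder index into this order.

# Derived descriptors computed from Open Babel properties (`ob` row) and the
# lexical scan (`lex` row) of the canonical SMILES.
.DERIVED_DESCRIPTORS <- list(
  n_aromatic_atoms = function(ob, lex) lex["nc_arom"] + lex["nn_arom"] +
    lex["no_arom"] + lex["ns_arom"],
  n_halogen        = function(ob, lex) lex["nCl"] + lex["nBr"] + lex["nI"] + ob["nF"],
  n_heteroatoms    = function(ob, lex) lex["nN"] + lex["nn_arom"] + lex["nO"] +
    lex["no_arom"] + lex["nS"] + lex["ns_arom"] + lex["nP"] +
    lex["nCl"] + lex["nBr"] + lex["nI"] + ob["nF"],
  ring_count       = function(ob, lex) ob["bonds"] - ob["atoms"] + lex["n_components"],
  frac_aromatic    = function(ob, lex) if (ob["atoms"] > 0)
    (lex["nc_arom"] + lex["nn_arom"] + lex["no_arom"] + lex["ns_arom"]) / ob["atoms"] else 0,
  frac_hetero      = function(ob, lex) if (ob["atoms"] > 0)
    .DERIVED_DESCRIPTORS$n_heteroatoms(ob, lex) / ob["atoms"] else 0,
  frac_rotors      = function(ob, lex) if (ob["bonds"] > 0) ob["rotors"] / ob["bonds"] else 0,
  mw_per_heavy_atom = function(ob, lex) if (ob["atoms"] > 0) ob["MW"] / ob["atoms"] else 0,
  tpsa_per_heavy_atom = function(ob, lex) if (ob["atoms"] > 0) ob["TPSA"] / ob["atoms"] else 0,
  mr_per_heavy_atom = function(ob, lex) if (ob["atoms"] > 0) ob["MR"] / ob["atoms"] else 0,
  unsaturation_index = function(ob, lex) ob["dbonds"] + 2 * ob["tbonds"],
  hbond_sites      = function(ob, lex) ob["HBA1"] + ob["HBD"],
  logp_per_heavy_atom = function(ob, lex) if (ob["atoms"] > 0) ob["logP"] / ob["atoms"] else 0,
  bonds_per_atom   = function(ob, lex) if (ob["atoms"] > 0) ob["bonds"] / ob["atoms"] else 0,
  frac_single_bonds = function(ob, lex) if (ob["bonds"] > 0) ob["sbonds"] / ob["bonds"] else 0,
  frac_double_bonds = function(ob, lex) if (ob["bonds"] > 0) ob["dbonds"] / ob["bonds"] else 0,
  frac_aromatic_bonds = function(ob, lex) if (ob["bonds"] > 0) ob["abonds"] / ob["bonds"] else 0,
  net_charge       = function(ob, lex) lex["n_pos"] - lex["n_neg"])

.LEXICAL_NAMES <- c("nC", "nc_arom", "nN", "nn_arom", "nO", "no_arom", "nS",
                    "ns_arom", "nP", "nCl", "nBr", "nI", "nB", "n_bracket",
                    "n_pos", "n_neg", "n_branch", "n_ring_closure",
                    "n_components", "smiles_length")

.BUILTIN_DESCRIPTORS <- c(.OB_DESCRIPTORS, .LEXICAL_NAMES,
                          names(.DERIVED_DESCRIPTORS))

# Default registry order: continuous physicochemical descriptors first, then
# counting descriptors. 53 entries, mirroring the scale of a typical
# descriptor panel; the identity of the panel is a documented, configurable
# default of this package, not a reproduction of any specific list.
.DEFAULT_53 <- c(
  "MW", "logP", "TPSA", "MR", "mw_per_heavy_atom", "tpsa_per_heavy_atom",
  "mr_per_heavy_atom", "frac_aromatic", "frac_hetero", "frac_rotors",
  "HBA1", "HBA2", "HBD", "hbond_sites", "nF", "atoms", "bonds", "abonds",
  "sbonds", "dbonds", "tbonds", "rotors", "unsaturation_index",
  "ring_count", "n_ring_closure", "n_components", "n_branch",
  "n_aromatic_atoms", "n_halogen", "n_heteroatoms",
  "nC", "nc_arom", "nN", "nn_arom", "nO", "no_arom", "nS", "ns_arom",
  "nP", "nCl", "nBr", "nI", "nB", "n_bracket", "n_pos", "n_neg",
  "net_charge", "smiles_length", "logp_per_heavy_atom", "bonds_per_atom",
  "frac_single_bonds", "frac_double_bonds", "frac_aromatic_bonds")

#' Create a descriptor registry
#'
#' A registry is an ordered list of descriptor names, each backed by a
#' compute function SMILES -> numeric. Builtin names are served by Open Babel
#' and lexical analysis of the canonical SMILES; arbitrary user descriptors
#' can be supplied as R functions.
#'
#' @param names Ordered character vector of descriptor names. Defaults to the
#'   package's 53-descriptor panel.
#' @param compute_fns Optional named list of functions `function(smiles)` ->
#'   numeric, for names that are not builtin.
#' @return An object of class `property_registry`.
#' @export
property_registry <- function(names = default_descriptor_names(),
                              compute_fns = list()) {
  if (anyDuplicated(names)) stop("registry names must be unique")
  custom <- setdiff(names, .BUILTIN_DESCRIPTORS)
  missing <- setdiff(custom, base::names(compute_fns))
  if (length(missing) > 0) {
    stop("no compute function for descriptor(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(names = names, compute_fns = compute_fns[custom]),
            class = "property_registry")
}

#' Default 53-descriptor panel
#'
#' @return Character vector of 53 descriptor names.
#' @export
default_descriptor_names <- function() {
  .DEFAULT_53
}

#' A small registry preset of 12 cheap Open Babel descriptors
#'
#' Convenient for desk-scale experiments where the full 53-descriptor panel
#' is unnecessarily wide.
#'
#' @return A `property_registry` with 12 descriptors.
#' @export
toy_registry <- function() {
  property_registry(c("MW", "logP", "TPSA", "MR", "HBA1", "HBD", "atoms",
                      "bonds", "abonds", "sbonds", "dbonds", "rotors"))
}

#' @export
print.property_registry <- function(x, ...) {
  cat("<property_registry> P =", length(x$names), "descriptors\n")
  cat(" ", paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Compute raw descriptor values for SMILES
#'
#' @param smiles Character vector of SMILES strings; every string must parse.
#' @param registry A `property_registry`.
#' @return Numeric matrix, `length(smiles)` rows by `P` columns named by
#'   descriptor.
#' @export
compute_descriptors <- function(smiles, registry = property_registry()) {
  stopifnot(inherits(registry, "property_registry"))
  can <- smiles_canonical(smiles)
  if (anyNA(can)) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[is.na(can)], 5), collapse = ", "))
  }
  nm <- registry$names
  out <- matrix(NA_real_, nrow = length(smiles), ncol = length(nm),
                dimnames = list(NULL, nm))
  need_ob <- any(nm %in% c(.OB_DESCRIPTORS, names(.DERIVED_DESCRIPTORS)))
  ob <- if (need_ob) .ob_properties(smiles) else NULL
  need_lex <- any(nm %in% c(.LEXICAL_NAMES, names(.DERIVED_DESCRIPTORS)))
  lex <- if (need_lex) t(vapply(can, .smiles_lexical, .smiles_lexical("C"))) else NULL
  for (j in seq_along(nm)) {
    d <- nm[j]
    if (d %in% .OB_DESCRIPTORS) {
      out[, j] <- ob[, d]
    } else if (d %in% .LEXICAL_NAMES) {
      out[, j] <- lex[, d]
    } else if (d %in% names(.DERIVED_DESCRIPTORS)) {
      f <- .DERIVED_DESCRIPTORS[[d]]
      out[, j] <- vapply(seq_along(smiles),
                         function(i) unname(f(ob[i, ], lex[i, ])), numeric(1))
    } else {
      out[, j] <- vapply(smiles, registry$compute_fns[[d]], numeric(1))
    }
  }
  if (anyNA(out) || any(!is.finite(out))) {
    stop("descriptor computation produced non-finite values")
  }
  out
}

#' Fit per-descriptor normalization statistics on a corpus
#'
#' Mean and population (1/n) standard deviation per descriptor, with the
#' standard deviation floored at `eps` (constant descriptors are kept but
#' flagged with a warning).  Invalid SMILES are skipped with a warning that
#' reports the count.
#'
#' @param corpus Character vector of SMILES.
#' @param registry A `property_registry`.
#' @param eps Floor for the standard deviation.
#' @return A `normalization_stats` object with `$names`, `$mean`, `$std`.
#' @export
fit_normalization <- function(corpus, registry = property_registry(),
                              eps = 1e-8) {
  if (length(corpus) == 0L) stop("corpus is empty")
  ok <- smiles_is_valid(corpus)
  if (!all(ok)) {
    warning(sum(!ok), " invalid SMILES skipped while fitting normalization")
    corpus <- corpus[ok]
  }
  if (length(corpus) == 0L) stop("no valid SMILES in corpus")
  raw <- compute_descriptors(corpus, registry)
  mu <- colMeans(raw)
  n <- nrow(raw)
  sd_pop <- sqrt(colMeans(sweep(raw, 2, mu)^2))
  if (any(sd_pop < eps)) {
    warning("constant descriptor(s) floored at eps: ",
            paste(colnames(raw)[sd_pop < eps], collapse = ", "))
  }
  structure(list(names = registry$names, mean = unname(mu),
                 std = pmax(unname(sd_pop), eps)),
            class = "normalization_stats")
}

#' Build a fully-known property vector from raw values
#'
#' @param raw Numeric vector of raw descriptor values, registry order.
#' @param stats A `normalization_stats` object.
#' @return A `property_vector`: normalized `$values` plus logical `$known`.
#' @export
normalize_pv <- function(raw, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  if (length(raw) != length(stats$mean)) {
    stop("length mismatch: ", length(raw), " values vs ",
         length(stats$mean), " descriptors")
  }
  new_property_vector((raw - stats$mean) / stats$std,
                      known = rep(TRUE, length(raw)))
}

#' Map normalized values back to the raw descriptor scale
#'
#' @param pv A `property_vector` (or numeric vector of normalized values).
#' @param stats A `normalization_stats` object.
#' @return Numeric vector on the raw scale (NA at [UNK] positions).
#' @export
denormalize_pv <- function(pv, stats) {
  v <- if (inherits(pv, "property_vector")) ifelse(pv$known, pv$values, NA_real_) else pv
  if (length(v) != length(stats$mean)) stop("length mismatch")
  v * stats$std + stats$mean
}

#' Construct a property vector
#'
#' @param values Numeric vector of normalized values (ignored where `known`
#'   is `FALSE`).
#' @param known Logical vector: `FALSE` marks an \[UNK\] position.
#' @return A `property_vector`.
#' @export
new_property_vector <- function(values, known = rep(TRUE, length(values))) {
  stopifnot(length(values) == length(known))
  if (any(known & !is.finite(values))) {
    stop("known property values must be finite")
  }
  values[!known] <- 0  # placeholder; never read by the model
  structure(list(values = as.numeric(values), known = as.logical(known)),
            class = "property_vector")
}

#' @export
print.property_vector <- function(x, ...) {
  cat("<property_vector> P =", length(x$values), "|",
      sum(!x$known), "[UNK]\n")
  invisible(x)
}

#' Randomly mask property positions as \[UNK\]
#'
#' Each currently-known position independently becomes \[UNK\] with
#' probability `rate`; positions already \[UNK\] stay \[UNK\]. Uses R's
#' global RNG stream.
#'
#' @param pv A `property_vector`.
#' @param rate Masking probability in \[0, 1\].
#' @return A `property_vector`.
#' @export
apply_unk_mask <- function(pv, rate) {
  stopifnot(inherits(pv, "property_vector"))
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop("rate must be in [0, 1]")
  }
  drop <- pv$known & (stats::runif(length(pv$known)) < rate)
  new_property_vector(ifelse(drop, 0, pv$values), pv$known & !drop)
}

#' Save normalization statistics as JSON
#'
#' @param stats A `normalization_stats` object.
#' @param path File path.
#' @export
stats_save <- function(stats, path) {
  obj <- stats::setNames(
    lapply(seq_along(stats$names),
           function(i) list(mean = stats$mean[i], std = stats$std[i])),
    stats$names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Write a property table as TSV
#'
#' Column `smiles` plus one column per registry descriptor.
#'
#' @param smiles Character vector of SMILES.
#' @param registry A `property_registry`.
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
property_table_save <- function(smiles, registry, path) {
  raw <- compute_descriptors(smiles, registry)
  df <- data.frame(smiles = smiles, raw, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a property table written by [property_table_save()]
#'
#' @param path TSV path with a `smiles` column and one column per
#'   descriptor.
#' @return data.frame with `smiles` and numeric descriptor columns.
#' @export
property_table_load <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) stop("property table has no 'smiles' column")
  df
}

#' Load normalization statistics from JSON
#'
#' @param path File path written by [stats_save()].
#' @return A `normalization_stats` object.
#' @export
stats_load <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(names = names(obj),
                 mean = vapply(obj, function(x) x$mean, numeric(1), USE.NAMES = FALSE),
                 std = vapply(obj, function(x) x$std, numeric(1), USE.NAMES = FALSE)),
            class = "normalization_stats")
}
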