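# Extended-connectivity (circular, Morgan-style) fingerprints.
#
# SMILES parsing is delegated to ChemmineR/OpenBabel; the iterative
# circular-neighborhood hashing is implemented here because no installed R
# package produces hashed circular fingerprints. Bit positions are
# implementation-defined (as in every ECFP implementation); what is
# guaranteed is structural: the same molecule gives the same fingerprint
# regardless of SMILES atom ordering, and substructure environments up to
# the chosen radius determine the set bits.

# Parse one SMILES into a connection table: element vector + bond table.
# Results are cached per SMILES string for the session.
.smiles_cache <- new.env(parent = emptyenv())

smiles_connection_table <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) stop("empty SMILES string")
  key <- paste0("s:", smiles)
  if (!is.null(.smiles_cache[[key]])) return(.smiles_cache[[key]])
  # canonicalize first so equivalent SMILES (including aromatic vs kekulized
  # forms) share one connection table, then parse the canonical form
  can <- tryCatch(
    gsub("[\t\n ]+$", "", ChemmineOB::convertFormat("SMI", "CAN", source = smiles)),
    error = function(e) "")
  if (!nzchar(can)) stop("unparsable SMILES: ", smiles, call. = FALSE)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(can)),
    error = function(e) stop("unparsable SMILES: ", smiles, call. = FALSE)
  )
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  ct <- list(elements = elements, bonds = bonds)
  .smiles_cache[[key]] <- ct
  ct
}

#' Circular (Morgan-style) fingerprint of a molecule
#'
#' Computes a hashed extended-connectivity fingerprint from a SMILES
#' string: atoms start from a structural invariant (element, heavy-atom
#' degree, bond-order sum), neighborhoods are iteratively hashed out to
#' `radius` bonds, and all environment codes are folded into `nbits` bits.
#' The result depends only on the molecular graph, not on the atom order
#' of the SMILES.
#'
#' @param smiles SMILES string; unparsable input raises an error carrying
#'   the offending string (such molecules are treated as unsequenced
#'   downstream).
#' @param radius Neighborhood radius in bonds (default 2, i.e. ECFP4-like).
#' @param nbits Fingerprint length (default 2048).
#' @return Integer 0/1 vector of length `nbits`.
#' @export
#' @examples
#' identical(compute_ecfp("CCO"), compute_ecfp("OCC"))
compute_ecfp <- function(smiles, radius = 2L, nbits = 2048L) {
  stopifnot(radius >= 0, nbits >= 1)
  ct <- smiles_connection_table(smiles)
  n <- length(ct$elements)
  fp <- integer(nbits)
  if (n == 0) return(fp)
  # neighbor lists (heavy atoms only; OpenBabel SDF output has implicit H)
  nb <- vector("list", n)
  if (nrow(ct$bonds)) {
    for (r in seq_len(nrow(ct$bonds))) {
      a <- ct$bonds$a1[r]; b <- ct$bonds$a2[r]; o <- ct$bonds$order[r]
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
  }
  degree <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bosum <- vapply(nb, function(x) if (is.null(x)) 0L else sum(x[, 2]), integer(1))
  codes <- vapply(seq_len(n), function(i)
    fnv1a(paste(ct$elements[i], degree[i], bosum[i], sep = "|")), numeric(1))
  all_codes <- codes
  if (radius > 0) for (it in seq_len(radius)) {
    new_codes <- vapply(seq_len(n), function(i) {
      if (is.null(nb[[i]])) return(fnv1a(paste("t", it, codes[i], sep = "|")))
      env <- sort(paste(nb[[i]][, 2], codes[nb[[i]][, 1]], sep = ":"))
      fnv1a(paste(c("t", it, codes[i], env), collapse = "|"))
    }, numeric(1))
    codes <- new_codes
    all_codes <- c(all_codes, codes)
  }
  fp[unique(as.integer(all_codes %% nbits)) + 1L] <- 1L
  fp
}

# Vectorized helper: fingerprint many SMILES, returning a matrix plus a
# logical vector of which parsed. Unparsable rows are all-zero and flagged.
ecfp_matrix <- function(smiles, radius = 2L, nbits = 2048L) {
  out <- matrix(0L, length(smiles), nbits)
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    fpi <- tryCatch(compute_ecfp(smiles[i], radius, nbits), error = function(e) NULL)
    if (!is.null(fpi)) { out[i, ] <- fpi; ok[i] <- TRUE }
  }
  list(fp = out, parsed = ok)
}

# TRUE where a SMILES string parses (cheaply cached).
smiles_parses <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    !is.null(tryCatch(smiles_connection_table(s), error = function(e) NULL))
  }, logical(1), USE.NAMES = FALSE)
}
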