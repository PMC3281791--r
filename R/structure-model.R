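#' Construct a structure model
#'
#' A `struct_model` is the uniform coordinate container used throughout the
#' package: a tibble of heavy-atom records (`chain`, `resno`, `insert`,
#' `resname`, `elety`, `element`, `x`, `y`, `z`, `occupancy`, `b`, `het`)
#' plus entry metadata (entry id, space group, SEQRES sequences and any
#' deposited biological-assembly transforms).
#'
#' @param atoms Tibble of atom records. Required columns: `chain`, `resno`,
#'   `resname`, `elety`, `element`, `x`, `y`, `z`. Optional: `insert`
#'   (default `""`), `occupancy` (default 1), `b` (default 0), `het`
#'   (default `FALSE`).
#' @param entry_id Entry identifier (e.g. a PDB code).
#' @param seqres Named list mapping chain id to a character vector of
#'   three-letter residue codes (the deposited full sequence), or `NULL`.
#' @param transforms List of assembly transforms as returned by
#'   [assembly_transform()], or `NULL`.
#' @param space_group Space-group symbol, or `NA`.
#'
#' @return An object of class `struct_model`.
#' @seealso [read_structure()], [build_assembly()], [model_chain()]
#' @export
struct_model <- function(atoms, entry_id = "XXXX", seqres = NULL,
                         transforms = NULL, space_group = NA_character_) {
  atoms <- as_tibble(atoms)
  req <- c("chain", "resno", "resname", "elety", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    abort(paste0("atoms is missing column(s): ", paste(miss, collapse = ", ")))
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$het[is.na(atoms$het)] <- FALSE
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && !all(is.finite(xyz)))
    abort("atom coordinates must be finite")
  if (nrow(atoms) > 0 && any(!nzchar(atoms$element)))
    abort("element symbols must be non-empty")
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1)))
    abort("occupancy must lie in [0, 1]")
  atoms <- arrange(atoms, .data$chain, .data$het, .data$resno, .data$insert)
  structure(
    list(entry_id = entry_id, atoms = atoms, seqres = seqres,
         transforms = transforms, space_group = space_group),
    class = "struct_model"
  )
}

#' @export
print.struct_model <- function(x, ...) {
  pol <- filter(x$atoms, !.data$het)
  cat("<struct_model> ", x$entry_id, "\n", sep = "")
  cat("  chains:  ", paste(chain_ids(x), collapse = " "), "\n", sep = "")
  cat("  atoms:   ", nrow(pol), " polymer, ",
      sum(x$atoms$het), " hetero\n", sep = "")
  if (!is.na(x$space_group))
    cat("  space group: ", x$space_group, "\n", sep = "")
  if (length(x$transforms) > 0)
    cat("  assembly transforms: ", length(x$transforms), "\n", sep = "")
  invisible(x)
}

#' Accessors for structure models
#'
#' `chain_ids()` lists polymer chain identifiers; `model_chain()` extracts
#' one chain's polymer atoms as a tibble; `polymer_atoms()` returns all
#' polymer (non-hetero, non-water) atoms; `model_xyz()` returns an N x 3
#' coordinate matrix.
#'
#' @param model A [struct_model()].
#' @param chain Chain identifier.
#' @param atoms An atom tibble.
#' @return A character vector, tibble, or numeric matrix respectively.
#' @export
chain_ids <- function(model) {
  unique(filter(model$atoms, !.data$het)$chain)
}

#' @rdname chain_ids
#' @export
model_chain <- function(model, chain) {
  stopifnot(inherits(model, "struct_model"))
  out <- filter(model$atoms, .data$chain == !!chain, !.data$het)
  if (nrow(out) == 0)
    abort(paste0("no polymer atoms for chain '", chain, "'"))
  out
}

#' @rdname chain_ids
#' @export
polymer_atoms <- function(model) {
  filter(model$atoms, !.data$het)
}

#' @rdname chain_ids
#' @export
model_xyz <- function(atoms) {
  if (inherits(atoms, "struct_model")) atoms <- atoms$atoms
  unname(as.matrix(atoms[, c("x", "y", "z")]))
}

# three-letter -> one-letter amino acid codes
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Extract a one-letter sequence from a chain
#'
#' @param model A [struct_model()].
#' @param chain Chain identifier.
#' @param source `"coords"` uses the residues resolved in the coordinates
#'   (unobserved residues are skipped); `"seqres"` returns the full
#'   deposited sequence from the SEQRES records.
#' @return A one-letter character string; unknown residue codes map to "X".
#' @export
extract_sequence <- function(model, chain, source = c("coords", "seqres")) {
  source <- match.arg(source)
  if (source == "seqres") {
    if (is.null(model$seqres) || !chain %in% names(model$seqres))
      abort(paste0("no SEQRES record for chain '", chain, "'"))
    codes <- model$seqres[[chain]]
  } else {
    at <- model_chain(model, chain)
    res <- distinct(at, .data$resno, .data$insert, .data$resname)
    res <- arrange(res, .data$resno, .data$insert)
    codes <- res$resname
  }
  if (length(codes) == 0) abort("chain has no residues")
  letters1 <- unname(AA_3TO1[toupper(codes)])
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}
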