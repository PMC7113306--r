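#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   across left_join bind_rows distinct row_number n slice pull rename
#' @importFrom tibble tibble as_tibble
NULL

# Standard 3-letter -> 1-letter residue code table. Nonstandard residues map
# to "X": excluded from conservation but retained for SASA and contacts.
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")
MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

aa_three_to_one <- function(resid) {
  out <- unname(AA_3TO1[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

guess_element <- function(atom_name, resid) {
  nm <- gsub("[0-9'\"]", "", toupper(atom_name))
  two <- substr(nm, 1, 2)
  known2 <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "CA", "SE", "BR", "NI", "CO")
  # CA is calcium only outside polymer residues; in amino acids it is C-alpha
  ifelse(two %in% known2 & !(toupper(resid) %in% names(AA_3TO1)),
         two, substr(nm, 1, 1))
}

new_structure_model <- function(atoms, id = "model", metadata = list()) {
  stopifnot(is.data.frame(atoms))
  structure(list(id = id, atoms = as_tibble(atoms), metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  pol <- x$atoms[x$atoms$is_polymer, ]
  cat("<structure_model> ", x$id, "\n", sep = "")
  cat("  chains: ", paste(unique(x$atoms$chain), collapse = ", "), "\n", sep = "")
  cat("  polymer residues: ",
      nrow(dplyr::distinct(pol, .data$chain, .data$resno, .data$ins)),
      "; atoms: ", nrow(x$atoms), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble structure_model
#' @export
as_tibble.structure_model <- function(x, ...) x$atoms

is_structure_model <- function(x) inherits(x, "structure_model")

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses a coordinate file into a flat atom table. Waters are discarded,
#' non-polymer heteroatoms are retained but flagged (`is_polymer = FALSE`),
#' and for residues with alternate locations only the highest-occupancy
#' conformer is kept (ties broken alphabetically by altloc tag). Hydrogens
#' are dropped: all downstream geometric criteria are heavy-atom based.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format One of `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param id Label for the model; defaults to the file stem.
#' @return A `structure_model`: a list with `id`, `metadata` and an `atoms`
#'   tibble with columns `chain`, `resno` (author numbering), `ins`,
#'   `orf` (open-reading-frame numbering, `NA` until assigned with
#'   [assign_orf()]), `resid`, `resid1`, `atom`, `element`, `x`, `y`, `z`,
#'   `occ`, `is_mainchain`, `is_polymer`.
#' @seealso [write_structure()], [assign_orf()], [select_atoms()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) abort(paste0("could not parse ", format, " file '",
                                     path, "': ", conditionMessage(e)))
  )
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) abort(paste0("no atom records in ", path))
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- toupper(trimws(elem))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- guess_element(at$elety[miss], at$resid[miss])

  atoms <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    ins = as.character(at$insert),
    resid = toupper(as.character(at$resid)),
    atom = toupper(as.character(at$elety)),
    altloc = as.character(at$alt),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occ = at$o,
    record = as.character(at$type)
  )
  atoms <- filter(atoms, !.data$resid %in% WATER_NAMES, .data$element != "H",
                  .data$element != "D")
  if (nrow(atoms) == 0) abort("no polymer residues: file contains only water/hydrogen")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    abort(paste0("non-finite coordinates in ", path))

  # altloc resolution: within each (chain, residue, atom) keep the conformer
  # with highest occupancy; ties -> first altloc tag alphabetically
  atoms <- atoms |>
    arrange(.data$chain, .data$resno, .data$ins, .data$atom,
            dplyr::desc(.data$occ), .data$altloc) |>
    distinct(.data$chain, .data$resno, .data$ins, .data$atom, .keep_all = TRUE)

  atoms <- atoms |>
    mutate(
      is_polymer = .data$record == "ATOM" | .data$resid %in% names(AA_3TO1),
      resid1 = ifelse(.data$is_polymer, aa_three_to_one(.data$resid), NA_character_),
      is_mainchain = .data$is_polymer & .data$atom %in% MAINCHAIN_ATOMS,
      orf = NA_integer_
    ) |>
    arrange(.data$chain, .data$resno, .data$ins,
            match(.data$atom, MAINCHAIN_ATOMS, nomatch = 99L), .data$atom) |>
    select("chain", "resno", "ins", "orf", "resid", "resid1", "atom",
           "element", "x", "y", "z", "occ", "is_mainchain", "is_polymer")

  if (!any(atoms$is_polymer)) abort("no polymer residues")
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  new_structure_model(atoms, id = id,
                      metadata = list(source = path, format = format))
}

#' Write a structure model to PDB format
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(is_structure_model(model))
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_polymer, "ATOM", "HETATM"),
    resno = a$resno, resid = a$resid, chain = a$chain,
    insert = ifelse(a$ins == "", NA, a$ins),
    elety = a$atom, o = a$occ, b = rep(0, nrow(a)),
    elesy = a$element
  )
  invisible(path)
}

# one-letter sequence of a chain's polymer residues, with residue keys
chain_sequence <- function(model, chain_id) {
  res <- model$atoms |>
    filter(.data$chain == chain_id, .data$is_polymer) |>
    distinct(.data$chain, .data$resno, .data$ins, .data$resid1)
  if (nrow(res) == 0) abort(paste0("chain '", chain_id, "' has no polymer residues"))
  res
}

identity_submat <- function(match = 2, mismatch = -1) {
  letters <- c(Biostrings::AA_STANDARD, "X", "U", "O")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m["X", ] <- 0; m[, "X"] <- 0  # unknown residues: neutral
  m
}

#' Map author residue numbering to ORF numbering
#'
#' Aligns the observed one-letter sequence of a chain to a full-length
#' reference sequence (numbered from Met1 of the open reading frame, i.e.
#' the start of the signal peptide) by Needleman-Wunsch global alignment
#' with identity scoring and affine gaps, and assigns each observed residue
#' the reference position it aligns to.
#'
#' @param model A `structure_model`.
#' @param chain_id Chain to map.
#' @param reference_sequence One-letter reference sequence (character scalar).
#' @param reference_id Optional identifier of the reference sequence.
#' @param min_identity Minimum identity over aligned (non-gap) positions;
#'   below this the reference is considered mismatched and an error is raised.
#' @return A tibble (`numbering_map`) with columns `chain`, `resno`, `ins`,
#'   `orf`, `obs`, `ref` — one row per observed polymer residue.
#' @export
map_numbering <- function(model, chain_id, reference_sequence,
                          reference_id = NULL, min_identity = 0.95) {
  res <- chain_sequence(model, chain_id)
  obs <- paste(res$resid1, collapse = "")
  ref <- toupper(gsub("\\s", "", reference_sequence))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(obs), subject = Biostrings::AAString(ref),
    type = "global-local",
    substitutionMatrix = identity_submat(match = 2, mismatch = -4),
    gapOpening = 4, gapExtension = 0.5
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- Biostrings::start(Biostrings::subject(pa))
  orf <- integer(0); aligned_match <- logical(0)
  i_obs <- 0L
  for (k in seq_along(pat)) {
    if (sub[k] != "-" && pat[k] != "-") {
      i_obs <- i_obs + 1L
      orf[i_obs] <- ref_pos
      aligned_match[i_obs] <- pat[k] == sub[k]
      ref_pos <- ref_pos + 1L
    } else if (sub[k] == "-" && pat[k] != "-") {
      abort(paste0("unaligned observed residue at alignment column ", k,
                   ": observed chain contains residues absent from the reference"))
    } else {
      ref_pos <- ref_pos + 1L
    }
  }
  if (mean(aligned_match) < min_identity)
    abort(sprintf("reference mismatch: %.1f%% identity over aligned positions (need >= %.0f%%)",
                  100 * mean(aligned_match), 100 * min_identity))
  tibble(chain = res$chain, resno = res$resno, ins = res$ins,
         orf = orf, obs = res$resid1,
         ref = strsplit(ref, "")[[1]][orf]) |>
    structure(reference_id = reference_id)
}

#' Assign ORF numbering to a chain of a model
#'
#' @inheritParams map_numbering
#' @param map Optionally a precomputed [map_numbering()] result; otherwise
#'   computed from `reference_sequence`.
#' @return The model with the `orf` column filled for that chain.
#' @export
assign_orf <- function(model, chain_id, reference_sequence = NULL, map = NULL,
                       reference_id = NULL) {
  if (is.null(map)) map <- map_numbering(model, chain_id, reference_sequence,
                                         reference_id)
  key <- paste(map$chain, map$resno, map$ins)
  akey <- paste(model$atoms$chain, model$atoms$resno, model$atoms$ins)
  hit <- match(akey, key)
  model$atoms$orf <- ifelse(is.na(hit), model$atoms$orf, map$orf[hit])
  model
}

#' Select atoms from a structure model
#'
#' Returns atoms in stable order (chain, residue, then N, CA, C, O before
#' other atom names).
#'
#' @param model A `structure_model`.
#' @param chain_ids Chains to select.
#' @param orf_range Optional closed interval `c(lo, hi)` in ORF numbering.
#' @param resno_range Optional closed interval in author numbering.
#' @param mainchain_only Keep only backbone N, CA, C, O (and OXT).
#' @return Atom tibble (same columns as `model$atoms`).
#' @export
select_atoms <- function(model, chain_ids, orf_range = NULL,
                         resno_range = NULL, mainchain_only = FALSE) {
  stopifnot(is_structure_model(model))
  missing_ch <- setdiff(chain_ids, unique(model$atoms$chain))
  if (length(missing_ch) > 0)
    abort(paste0("chain(s) not in model: ", paste(missing_ch, collapse = ", ")))
  a <- filter(model$atoms, .data$chain %in% chain_ids)
  if (!is.null(orf_range))
    a <- filter(a, !is.na(.data$orf), .data$orf >= orf_range[1],
                .data$orf <= orf_range[2])
  if (!is.null(resno_range))
    a <- filter(a, .data$resno >= resno_range[1], .data$resno <= resno_range[2])
  if (mainchain_only) a <- filter(a, .data$is_mainchain)
  if (nrow(a) == 0) abort("empty atom selection")
  arrange(a, .data$chain, .data$resno, .data$ins,
          match(.data$atom, MAINCHAIN_ATOMS, nomatch = 99L), .data$atom)
}

#' Keep only a subset of chains as a new model
#' @param model A `structure_model`.
#' @param chain_ids Chains to keep.
#' @export
subset_chains <- function(model, chain_ids) {
  a <- select_atoms(model, chain_ids)
  new_structure_model(a, id = paste0(model$id, "[", paste(chain_ids, collapse = ""), "]"),
                      metadata = model$metadata)
}

#' Apply a rigid transform to a model
#' @param model A `structure_model`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation (angstrom).
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]; model$atoms$z <- new[, 3]
  model
}

# residue-level table: one row per polymer residue
residue_table <- function(model_or_atoms) {
  a <- if (is_structure_model(model_or_atoms)) model_or_atoms$atoms else model_or_atoms
  a |>
    filter(.data$is_polymer) |>
    distinct(.data$chain, .data$resno, .data$ins, .data$orf, .data$resid,
             .data$resid1)
}
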