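#' @importFrom stats setNames
NULL

# Chain-ID alphabet used when writing multi-chain models (PDB column 22
# holds a single character, so at most 62 subunits can be written).
.CHAIN_IDS <- c(LETTERS, letters, as.character(0:9))

#' Construct a polypeptide chain structure
#'
#' A `chain_structure` is the unit placed into complex models: one
#' polypeptide chain with its residues and (heavy-atom) coordinates.
#' Residues without coordinates are retained and flagged, so disordered
#' stretches survive round trips and can be classified as such when
#' variants are mapped.
#'
#' @param chain_id Single-character (or short) chain label.
#' @param residues `data.frame` with columns `seq_index` (1-based integer,
#'   strictly increasing within an insertion-code group), `aa` (one-letter
#'   amino acid, `X` allowed) and optionally `insertion_code` (default `""`).
#' @param atoms `data.frame` with columns `seq_index`, `name` (atom label,
#'   e.g. `"CA"`), `element` (non-empty symbol) and `x`, `y`, `z`
#'   coordinates in Angstrom.  All coordinates must be finite.
#' @param source_entry Structure accession the chain came from (e.g. a PDB
#'   code); `NA` for chains built in memory.
#' @param source_protein Optional sequence-database accession of the protein
#'   the chain represents.
#'
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, residues, atoms,
                            source_entry = NA_character_,
                            source_protein = NA_character_) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  if (is.null(residues$insertion_code)) residues$insertion_code <- ""
  residues <- residues[, c("seq_index", "aa", "insertion_code")]
  residues$seq_index <- as.integer(residues$seq_index)
  if (any(residues$seq_index < 1L)) {
    stop("residue seq_index must be >= 1")
  }
  for (grp in split(residues$seq_index, residues$insertion_code)) {
    if (is.unsorted(grp, strictly = TRUE)) {
      stop("residues must be strictly increasing in seq_index within an ",
           "insertion-code group")
    }
  }
  if (nrow(atoms) > 0) {
    stopifnot(all(c("seq_index", "name", "element", "x", "y", "z") %in%
                    names(atoms)))
    atoms <- atoms[, c("seq_index", "name", "element", "x", "y", "z")]
    atoms$seq_index <- as.integer(atoms$seq_index)
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("atom coordinates must be finite")
    }
    if (any(!nzchar(atoms$element))) stop("atom element must be non-empty")
    if (!all(atoms$seq_index %in% residues$seq_index)) {
      stop("atoms reference residues absent from the residue table")
    }
  } else {
    atoms <- data.frame(seq_index = integer(), name = character(),
                        element = character(), x = numeric(), y = numeric(),
                        z = numeric(), stringsAsFactors = FALSE)
  }
  atoms$is_heavy <- toupper(atoms$element) != "H"
  residues$has_coords <- residues$seq_index %in% atoms$seq_index
  structure(list(chain_id = as.character(chain_id),
                 residues = residues, atoms = atoms,
                 source_entry = as.character(source_entry),
                 source_protein = as.character(source_protein)),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure %s> %d residues (%d with coordinates), %d atoms, entry=%s protein=%s\n",
              x$chain_id, nrow(x$residues), sum(x$residues$has_coords),
              nrow(x$atoms), x$source_entry, x$source_protein))
  invisible(x)
}

#' One-letter sequence of a chain
#'
#' @param chain A `chain_structure`.
#' @return Character scalar, one letter per residue in table order.
#' @export
chain_sequence <- function(chain) {
  paste0(chain$residues$aa, collapse = "")
}

#' C-alpha coordinate matrix of a chain
#'
#' @param chain A `chain_structure`.
#' @return Numeric matrix (n x 3); rownames are residue `seq_index` values.
#'   Residues without a CA atom are omitted.
#' @export
ca_coords <- function(chain) {
  ca <- chain$atoms[chain$atoms$name == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$seq_index), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$seq_index
  m
}

#' Construct a rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1 within
#'   1e-8).
#' @param translation Numeric 3-vector, Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' `compose_transform(s, t)` applies `t` first, then `s`.
#'
#' @param s,t `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transform <- function(s, t) {
  rigid_transform(s$rotation %*% t$rotation,
                  as.numeric(s$rotation %*% t$translation) + s$translation)
}

#' Apply a rigid transform to a chain
#'
#' Coordinates are mapped `x -> R x + t`; topology (residues, atom names)
#' is unchanged.
#'
#' @param chain A `chain_structure`.
#' @param t A `rigid_transform`.
#' @return The transformed `chain_structure`.
#' @export
apply_transform <- function(chain, t) {
  stopifnot(inherits(chain, "chain_structure"), inherits(t, "rigid_transform"))
  if (nrow(chain$atoms) > 0) {
    xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
    xyz <- xyz %*% t(t$rotation)
    chain$atoms$x <- xyz[, 1] + t$translation[1]
    chain$atoms$y <- xyz[, 2] + t$translation[2]
    chain$atoms$z <- xyz[, 3] + t$translation[3]
  }
  chain
}

# three-letter -> one-letter, with the common selenomethionine remap; other
# non-standard residues become X but keep their atoms.
.aa3to1 <- function(resid) {
  out <- bio3d::aa321(resid)
  out[resid == "MSE"] <- "M"
  out[is.na(out)] <- "X"
  out
}

.aa1to3 <- function(aa) {
  out <- bio3d::aa123(aa)
  out[is.na(out) | out == "---"] <- "UNK"
  out
}

#' Read a macromolecular structure file
#'
#' Parses a PDB or mmCIF file into one [chain_structure()] per polymer
#' chain.  Heteroatoms and waters are excluded; for multi-model entries only
#' the first model is used; for alternate locations the highest-occupancy
#' conformer is kept (first on ties).
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mmcif"`.  Default guesses from the file
#'   extension (`.cif` implies mmCIF).
#' @return List of `chain_structure`, in file chain order.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- parsed$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "DOD", "WAT")), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("no polymer chains in ", path)
  if (is.null(at$insert)) at$insert <- ""
  at$insert[is.na(at$insert)] <- ""
  if (!is.null(at$alt)) {
    at$alt[is.na(at$alt)] <- ""
    if (any(nzchar(at$alt))) {
      occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
      key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
      ord <- order(key, -occ, at$alt)
      at <- at[ord, , drop = FALSE]
      at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                                 sep = "|")), , drop = FALSE]
      at <- at[order(as.integer(rownames(at))), , drop = FALSE]
    }
  }
  entry <- sub("\\.(pdb|cif|ent)(\\.gz)?$", "", basename(path),
               ignore.case = TRUE)
  lapply(split(at, factor(at$chain, levels = unique(at$chain))), function(ch) {
    rkey <- paste(ch$resno, ch$insert, sep = "|")
    first <- !duplicated(rkey)
    residues <- data.frame(seq_index = ch$resno[first],
                           aa = .aa3to1(ch$resid[first]),
                           insertion_code = ch$insert[first],
                           stringsAsFactors = FALSE)
    elem <- if (!is.null(ch$elesy) && !all(is.na(ch$elesy)))
      ifelse(is.na(ch$elesy) | !nzchar(ch$elesy),
             substr(gsub("[0-9]", "", ch$elety), 1, 1), ch$elesy)
    else substr(gsub("[0-9]", "", ch$elety), 1, 1)
    atoms <- data.frame(seq_index = ch$resno, name = ch$elety, element = elem,
                        x = ch$x, y = ch$y, z = ch$z, stringsAsFactors = FALSE)
    atoms <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
    chain_structure(ch$chain[1], residues, atoms, source_entry = entry)
  })
}

#' Write a complex model as a multi-chain PDB file
#'
#' Chain IDs are remapped deterministically (`A`, `B`, `C`, ... in subunit
#' insertion order) so that repeated runs are diffable.  A companion JSON
#' provenance sidecar (`<path>.json`) records, per subunit, the source entry
#' and chain, the anchor subunit, the template pair and the placement
#' transform.
#'
#' @param model A `complex_model` (see [grow_model()]) or plain list of
#'   `chain_structure` objects.
#' @param path Output PDB path.
#' @return Invisibly, the vector of remapped chain IDs.
#' @export
write_complex <- function(model, path) {
  subunits <- if (inherits(model, "complex_model")) model$subunits
              else lapply(model, function(ch) list(chain = ch))
  if (length(subunits) == 0) stop("model has no subunits")
  if (length(subunits) > length(.CHAIN_IDS)) {
    stop("cannot write more than ", length(.CHAIN_IDS),
         " subunits to a PDB file (single-character chain IDs)")
  }
  ids <- .CHAIN_IDS[seq_along(subunits)]
  rows <- list()
  for (i in seq_along(subunits)) {
    ch <- subunits[[i]]$chain
    at <- ch$atoms
    if (nrow(at) == 0) next
    aa_of <- setNames(ch$residues$aa, as.character(ch$residues$seq_index))
    rows[[i]] <- data.frame(chain = ids[i], resno = at$seq_index,
                            resid = .aa1to3(aa_of[as.character(at$seq_index)]),
                            elety = at$name, elesy = at$element,
                            x = at$x, y = at$y, z = at$z,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  xyz <- as.numeric(t(as.matrix(all[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = all$resno,
                   resid = all$resid, chain = all$chain, elety = all$elety,
                   elesy = all$elesy, eleno = seq_len(nrow(all)))
  prov <- lapply(seq_along(subunits), function(i) {
    s <- subunits[[i]]
    tr <- s$transform
    list(subunit_id = if (!is.null(s$subunit_id)) s$subunit_id else ids[i],
         written_chain = ids[i],
         protein = if (!is.null(s$protein)) s$protein else s$chain$source_protein,
         source_entry = s$chain$source_entry,
         source_chain = s$chain$chain_id,
         anchor_subunit = if (!is.null(s$anchor)) s$anchor else NA,
         template_pair = if (!is.null(s$template_pair)) s$template_pair else NA,
         transform = if (!is.null(tr))
           list(rotation = as.numeric(tr$rotation),
                translation = as.numeric(tr$translation)) else NULL)
  })
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(ids)
}
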