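#' Structure model
#'
#' A light container for protein coordinates: a flat atom table plus free-form
#' metadata. All geometry in the package (SASA, interfaces, superposition)
#' operates on this class. Waters, ligands and other HETATM records are
#' excluded at parse time; hydrogens are kept but flagged so that surface and
#' contact calculations can skip them.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `resid`
#'   (3-letter residue name), `eleno`, `elety` (atom name), `element`, `x`,
#'   `y`, `z`, `o` (occupancy), `alt` (altloc, `""` when absent), `hydrogen`
#'   (logical).
#' @param metadata named list (source file, model number, ...).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, metadata = list()) {
  need <- c("chain", "resno", "icode", "resid", "eleno", "elety",
            "element", "x", "y", "z", "o", "alt", "hydrogen")
  .assert(is.data.frame(atoms), "atoms must be a data.frame")
  miss <- setdiff(need, names(atoms))
  .assert(length(miss) == 0, "atoms is missing columns: ", paste(miss, collapse = ", "))
  .assert(all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)),
          "non-finite coordinates")
  .assert(all(nzchar(atoms$element)), "empty element symbols")
  atoms$chain <- as.character(atoms$chain)
  atoms$icode <- ifelse(is.na(atoms$icode) | atoms$icode == " ", "", atoms$icode)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model:", nrow(a), "atoms,",
      length(unique(residue_key(a$chain, a$resno, a$icode))), "residues,",
      length(unique(a$chain)), "chain(s) [",
      paste(unique(a$chain), collapse = " "), "]\n")
  invisible(x)
}

#' @export
#' @rdname structure_model
#' @param model a `structure_model`.
n_atoms <- function(model) nrow(model$atoms)

#' Residue table of a model
#'
#' @param model a `structure_model`.
#' @return data.frame with one row per residue: `chain`, `resno`, `icode`,
#'   `resid`, `key`, in file order.
#' @export
residues_of <- function(model) {
  a <- model$atoms
  key <- residue_key(a$chain, a$resno, a$icode)
  i <- !duplicated(key)
  data.frame(chain = a$chain[i], resno = a$resno[i], icode = a$icode[i],
             resid = a$resid[i], key = key[i], stringsAsFactors = FALSE)
}

#' Subset a model by chain
#'
#' @param model a `structure_model`.
#' @param chains chain identifiers to keep.
#' @return a `structure_model` containing only the requested chains.
#' @export
subset_chains <- function(model, chains) {
  a <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  .assert(nrow(a) > 0, "no atoms left after chain subset")
  structure_model(a, model$metadata)
}

#' Read a PDB file
#'
#' Parses fixed-column PDB v3.3 via bio3d. Waters (HOH/WAT/DOD) and all other
#' HETATM records are dropped, mirroring the usual structure-cleansing step
#' before docking; hydrogens are kept but flagged. Alternate locations are
#' resolved per atom name by the requested policy.
#'
#' @param path PDB file path.
#' @param model_index 1-based model number for multi-model files.
#' @param altloc_policy `"highest_occupancy"` (ties broken by first
#'   encountered) or `"first"`.
#' @return a [structure_model()].
#' @export
read_pdb <- function(path, model_index = 1L,
                     altloc_policy = c("highest_occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  .assert(file.exists(path), "PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  .assert(nrow(at) > 0, "no ATOM records in ", path)
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  .assert(model_index >= 1 && model_index <= n_models,
          "model ", model_index, " absent (file has ", n_models, ")")
  if (model_index > 1) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    keep <- which(pdb$atom$type == "ATOM")
    at$x <- xyz[keep, 1]; at$y <- xyz[keep, 2]; at$z <- xyz[keep, 3]
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution, per (residue, atom name)
  if (any(at$alt != "")) {
    grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- seq_len(nrow(at))
    pick <- unlist(lapply(split(ord, grp), function(i) {
      if (length(i) == 1L) return(i)
      if (altloc_policy == "first") return(i[1L])
      i[which.max(at$o[i])] # which.max: first index on ties
    }), use.names = FALSE)
    at <- at[sort(pick), , drop = FALSE]
  }
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank)) {
    elem[blank] <- suppressWarnings(bio3d::atom2ele(at$elety[blank]))
  }
  elem <- trimws(elem)
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = at$insert, resid = at$resid,
    eleno = at$eleno, elety = at$elety, element = elem,
    x = at$x, y = at$y, z = at$z, o = at$o, alt = at$alt,
    hydrogen = elem %in% c("H", "D"), stringsAsFactors = FALSE
  )
  structure_model(atoms, metadata = list(source = path, model = model_index))
}

#' Write a structure model as PDB
#'
#' Fixed-column PDB v3.3 ATOM records; coordinates survive a round-trip to
#' three decimals.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  .assert(nrow(a) > 0, "cannot write an empty model")
  .assert(all(nchar(a$chain) == 1L),
          "PDB chain ids must be a single character: ",
          paste(unique(a$chain[nchar(a$chain) != 1L]), collapse = ", "))
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     insert = ifelse(a$icode == "", "", a$icode),
                     eleno = a$eleno, elety = a$elety, o = a$o,
                     elesy = a$element)
    TRUE
  }, error = function(e) FALSE, warning = function(w) TRUE)
  .assert(ok && file.exists(path), "could not write PDB to ", path)
  invisible(path)
}

#' Rigid-body transform
#'
#' @param rotation 3x3 rotation matrix (orthogonal, det +1).
#' @param translation length-3 numeric.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  .assert(is.matrix(rotation) && all(dim(rotation) == c(3, 3)), "rotation must be 3x3")
  .assert(max(abs(crossprod(rotation) - diag(3))) < 1e-8, "rotation is not orthogonal")
  .assert(abs(det(rotation) - 1) < 1e-8, "rotation determinant is not +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform
#'
#' @param x a `structure_model` or an n-by-3 coordinate matrix.
#' @param tf a [rigid_transform()].
#' @return the transformed object, same class as `x`.
#' @export
apply_transform <- function(x, tf) {
  .assert(inherits(tf, "rigid_transform"), "tf must be a rigid_transform")
  if (inherits(x, "structure_model")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(tf$rotation), 2, tf$translation, `+`)
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  sweep(as.matrix(x) %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

# pair atoms between two models by (chain, resno, icode, atom name);
# atom_names optionally restricts (e.g. "CA")
.paired_coords <- function(mobile, reference, atom_names = NULL) {
  key <- function(m) {
    a <- m$atoms[!m$atoms$hydrogen, , drop = FALSE]
    if (!is.null(atom_names)) a <- a[a$elety %in% atom_names, , drop = FALSE]
    list(a = a, k = paste(a$chain, a$resno, a$icode, a$elety, sep = "\r"))
  }
  mm <- key(mobile); rr <- key(reference)
  common <- intersect(mm$k, rr$k)
  im <- match(common, mm$k); ir <- match(common, rr$k)
  list(mobile = as.matrix(mm$a[im, c("x", "y", "z")]),
       reference = as.matrix(rr$a[ir, c("x", "y", "z")]))
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of paired atoms (Kabsch, via SVD).
#' Atoms are paired by `(chain, resno, icode, atom name)`, optionally
#' restricted to a set of atom names such as `"CA"`; alternatively explicit
#' paired coordinate matrices can be supplied.
#'
#' @param mobile,reference `structure_model`s, or n-by-3 coordinate matrices
#'   with rows already paired.
#' @param atom_names optional atom-name restriction for pairing (default all
#'   shared heavy atoms).
#' @return list with `transform` (a [rigid_transform()] mapping mobile onto
#'   reference), `rmsd` (in Angstrom) and `n` (number of atom pairs).
#' @export
kabsch_superpose <- function(mobile, reference, atom_names = NULL) {
  if (inherits(mobile, "structure_model")) {
    pc <- .paired_coords(mobile, reference, atom_names)
    P <- pc$mobile; Q <- pc$reference
  } else {
    P <- as.matrix(mobile); Q <- as.matrix(reference)
    .assert(nrow(P) == nrow(Q), "paired coordinate matrices differ in length")
  }
  n <- nrow(P)
  .assert(n >= 3, "need at least 3 paired atoms, got ", n)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  # degenerate (collinear) selections leave the rotation underdetermined
  .assert(svd(P0)$d[2] > 1e-6 * max(1, svd(P0)$d[1]),
          "degenerate (collinear) atom selection")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(transform = rigid_transform(R, t), rmsd = rmsd, n = n)
}

#' RMSD between paired coordinates
#'
#' @param a,b n-by-3 matrices with paired rows.
#' @return root-mean-square deviation in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  .assert(all(dim(a) == dim(b)), "coordinate matrices differ in shape")
  sqrt(mean(rowSums((a - b)^2)))
}
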