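# Independent oracles and fixture builders used across the suite.

# --- PDB text fixture writer (fixed-column v3.3) -----------------------------
write_pdb_fixture <- function(path, rows, multi_model = NULL) {
  fmt <- function(r) sprintf(
    "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    r$serial, sprintf(" %-3s", r$name), r$alt %||% " ", r$resn,
    r$chain, r$resno, r$icode %||% " ", r$x, r$y, r$z, r$occ %||% 1, 0,
    r$elem %||% substr(r$name, 1, 1))
  `%||%` <- function(a, b) if (is.null(a)) b else a
  lines <- character(0)
  if (is.null(multi_model)) {
    lines <- vapply(rows, fmt, "")
  } else {
    for (m in seq_along(multi_model)) {
      lines <- c(lines, sprintf("MODEL     %4d", m),
                 vapply(multi_model[[m]], fmt, ""), "ENDMDL")
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

pdb_row <- function(serial, name, resn, chain, resno, x, y, z,
                    icode = " ", alt = " ", occ = 1, elem = NULL) {
  list(serial = serial, name = name, resn = resn, chain = chain, resno = resno,
       x = x, y = y, z = z, icode = icode, alt = alt, occ = occ, elem = elem)
}

# --- analytic two-sphere SASA ------------------------------------------------
# area of one expanded sphere of radius R with a neighbour at distance d
two_sphere_area <- function(R, d) 4 * pi * R^2 - abscan::sphere_cap_area(R, d)

# --- affine-gap global alignment DP (Gotoh), written independently ----------
# convention: a gap of length L costs open + L * extend (as in the package)
gotoh_score <- function(a, b, submat, open = 10, extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- submat[a[i], b[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                           X[i, j + 1] - extend,
                           Y[i, j + 1] - open - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                           Y[i + 1, j] - extend,
                           X[i + 1, j] - open - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive enumeration of all global alignments (tiny inputs only),
# used to validate the Gotoh oracle itself
enum_align_score <- function(a, b, submat, open = 10, extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, submat[a[i], b[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(a))
      best <- max(best, -(if (last == "X") extend else open + extend) +
                    rec(i + 1, j, "X"))
    if (j <= length(b))
      best <- max(best, -(if (last == "Y") extend else open + extend) +
                    rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "M")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# --- random atom clusters for SASA cross-checks ------------------------------
random_cluster <- function(n_atoms, seed, box = 6) {
  set.seed(seed)
  atoms <- data.frame(
    chain = "A", resno = seq_len(n_atoms), icode = "", resid = "ALA",
    eleno = seq_len(n_atoms), elety = "CA",
    element = sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE),
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box), o = 1, alt = "", hydrogen = FALSE,
    stringsAsFactors = FALSE)
  abscan::structure_model(atoms)
}

# single-residue model from explicit atom specs (for contact geometry tests)
atoms_model <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(chain = r$chain, resno = r$resno, icode = "", resid = r$resid,
               eleno = i, elety = r$elety, element = r$element,
               x = r$x, y = r$y, z = r$z, o = 1, alt = "", hydrogen = FALSE,
               stringsAsFactors = FALSE)
  }))
  abscan::structure_model(df)
}

atom_spec <- function(chain, resno, resid, elety, element, x, y, z) {
  list(chain = chain, resno = resno, resid = resid, elety = elety,
       element = element, x = x, y = y, z = z)
}

# hotspot table derived from the constructed true interface of a toy complex
truth_hotspots <- function(fx, positive_fold = 50) {
  ann <- fx$annotation
  tested <- union(
    ann$residues$key[ann$residues$region %in% c("H1", "H2", "H3", "L1", "L2", "L3")],
    fx$truth$paratope)
  recs <- data.frame(mutant_id = tested, mode = "kd_ratio",
                     fold = ifelse(tested %in% fx$truth$paratope,
                                   positive_fold, 1),
                     censored = FALSE, censor_bound = 100,
                     stringsAsFactors = FALSE)
  recs$bin <- abscan::classify_bins(recs$fold)
  abscan::hotspot_table(recs)
}

# toy-scale ranking configuration: the published defaults assume full-size
# antibody-antigen interfaces; the miniature complexes here bury ~100-300 A^2
toy_config <- function() {
  cfg <- abscan::default_config()
  cfg$ranking$min_bsa <- 50
  cfg
}
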