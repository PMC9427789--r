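#' Global pairwise alignment of ortholog sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (a gap of length L
#' costs `gap_open + L * gap_extend`), scored with a standard substitution
#' matrix; Biostrings supplies the dynamic program. Identity is computed over
#' aligned non-gap columns.
#'
#' @param ref_seq,query_seq amino-acid strings (standard letters).
#' @param gap_open,gap_extend gap penalties (defaults 10 / 0.5).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param ref_id,query_id sequence identifiers.
#' @return an `ortholog_pair`: list with `ref_id`, `query_id`, `score`,
#'   `identity_percent`, and `aligned_positions` (data.frame `column`,
#'   `ref_pos`, `ref_aa`, `query_pos`, `query_aa`; NA on gaps).
#' @export
align_pair <- function(ref_seq, query_seq, gap_open = 10, gap_extend = 0.5,
                       matrix = "BLOSUM62", ref_id = "ref", query_id = "query") {
  ref_seq <- toupper(ref_seq); query_seq <- toupper(query_seq)
  .assert(nchar(ref_seq) > 0 && nchar(query_seq) > 0, "empty sequence")
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX*]+$"
  .assert(grepl(ok, ref_seq) && grepl(ok, query_seq),
          "invalid amino-acid letters")
  submat <- get(data(list = matrix, package = "Biostrings",
                     envir = environment()))
  aln <- Biostrings::pairwiseAlignment(ref_seq, query_seq, type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  ra <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  qa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- ifelse(ra == "-", NA_integer_, cumsum(ra != "-"))
  query_pos <- ifelse(qa == "-", NA_integer_, cumsum(qa != "-"))
  ap <- data.frame(column = seq_along(ra), ref_pos = ref_pos, ref_aa = ra,
                   query_pos = query_pos, query_aa = qa,
                   stringsAsFactors = FALSE)
  ap$ref_aa[ra == "-"] <- NA_character_
  ap$query_aa[qa == "-"] <- NA_character_
  both <- !is.na(ap$ref_pos) & !is.na(ap$query_pos)
  structure(list(ref_id = ref_id, query_id = query_id,
                 score = Biostrings::score(aln),
                 identity_percent = 100 * sum(both & ra == qa) / sum(both),
                 aligned_positions = ap),
            class = "ortholog_pair")
}

#' @export
print.ortholog_pair <- function(x, ...) {
  cat("ortholog_pair", x$ref_id, "vs", x$query_id, ": score", x$score,
      ", identity", round(x$identity_percent, 1), "%\n")
  invisible(x)
}

#' Sequence differences within a region
#'
#' Aligned columns inside a reference-position interval where reference and
#' query residues differ. Gap columns are reported separately, not as
#' differences; positions follow the reference (human) numbering.
#'
#' @param pair an `ortholog_pair` from [align_pair()].
#' @param region length-2 integer reference-position interval, or NULL for
#'   the whole reference.
#' @param epitope_positions optional integer set of reference positions
#'   making up the epitope; differences falling on it are flagged.
#' @return a `difference_map`: list with `differing` (data.frame `ref_pos`,
#'   `ref_aa`, `query_aa`, `on_epitope`), `gap_columns` (data.frame),
#'   `epitope_positions`, `region`.
#' @export
difference_positions <- function(pair, region = NULL, epitope_positions = integer(0)) {
  ap <- pair$aligned_positions
  max_ref <- max(ap$ref_pos, na.rm = TRUE)
  if (is.null(region)) region <- c(1L, max_ref)
  .assert(length(region) == 2 && region[1] <= region[2], "malformed region")
  .assert(region[1] >= 1 && region[2] <= max_ref, "region outside reference length")
  inr <- !is.na(ap$ref_pos) & ap$ref_pos >= region[1] & ap$ref_pos <= region[2]
  gaps <- ap[inr & is.na(ap$query_pos), , drop = FALSE]
  both <- inr & !is.na(ap$query_pos)
  diff <- ap[both & ap$ref_aa != ap$query_aa, , drop = FALSE]
  differing <- data.frame(ref_pos = diff$ref_pos, ref_aa = diff$ref_aa,
                          query_aa = diff$query_aa,
                          on_epitope = diff$ref_pos %in% epitope_positions,
                          stringsAsFactors = FALSE)
  structure(list(differing = differing,
                 gap_columns = gaps[, c("column", "ref_pos", "ref_aa")],
                 epitope_positions = epitope_positions, region = region),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat("difference_map:", nrow(x$differing), "differences in region",
      x$region[1], "-", x$region[2],
      "(", sum(x$differing$on_epitope), "on epitope )\n")
  invisible(x)
}

#' Overlap of sequence differences with the epitope
#'
#' @param diff a `difference_map`.
#' @param epitope_positions integer set of reference positions (defaults to
#'   the set stored in `diff`).
#' @return list with `count_on_epitope` and `fraction_percent`
#'   (count / number of differences, as percent; 0 when there are no
#'   differences).
#' @export
epitope_overlap <- function(diff, epitope_positions = NULL) {
  epitope_positions <- epitope_positions %||% diff$epitope_positions
  n <- nrow(diff$differing)
  k <- sum(diff$differing$ref_pos %in% epitope_positions)
  list(count_on_epitope = k,
       fraction_percent = if (n == 0) 0 else 100 * k / n)
}

#' Propose back-to-reference mutations
#'
#' For every difference at an epitope position, proposes mutating the query
#' (non-binder) residue back to the reference (binder) residue. Mutation
#' labels use reference numbering: `T49N` means the query's T at reference
#' position 49 is replaced by the reference's N. Under
#' `singles_plus_cumulative`, combination sets are built by adding mutations
#' in the given priority order: the first set holds the top two, then each
#' further set adds one more.
#'
#' @param diff a `difference_map`.
#' @param restrict_to reference positions to consider (e.g. the epitope).
#' @param priority_order reference positions in the order combinations are
#'   accumulated (default: ascending position).
#' @param combination_policy `"singles"` or `"singles_plus_cumulative"`.
#' @return a `back_mutation_proposal`: list with `mutations` (data.frame
#'   `ref_pos`, `query_aa`, `ref_aa`, `label`) and `combination_sets` (list
#'   of label vectors).
#' @export
propose_back_mutations <- function(diff, restrict_to,
                                   priority_order = NULL,
                                   combination_policy = c("singles_plus_cumulative",
                                                          "singles")) {
  combination_policy <- match.arg(combination_policy)
  .assert(nrow(diff$differing) > 0, "difference map is empty")
  d <- diff$differing[diff$differing$ref_pos %in% restrict_to, , drop = FALSE]
  .assert(nrow(d) > 0, "no differences at the restricted positions")
  d$label <- paste0(d$query_aa, d$ref_pos, d$ref_aa)
  mutations <- d[order(d$ref_pos), c("ref_pos", "query_aa", "ref_aa", "label")]
  rownames(mutations) <- NULL
  combos <- list()
  if (combination_policy == "singles_plus_cumulative" && nrow(mutations) >= 2) {
    po <- priority_order %||% sort(mutations$ref_pos)
    po <- po[po %in% mutations$ref_pos]
    lab <- mutations$label[match(po, mutations$ref_pos)]
    combos <- lapply(2:length(lab), function(k) sort(lab[seq_len(k)]))
  }
  structure(list(mutations = mutations, combination_sets = combos),
            class = "back_mutation_proposal")
}

#' Read sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  .assert(file.exists(path), "FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  .assert(length(ss) > 0, "no sequences in ", path)
  stats::setNames(as.character(ss), sub(" .*", "", names(ss)))
}

#' Export a difference map (with proposals) as CSV
#'
#' @param diff a `difference_map`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_differences_csv <- function(diff, path) {
  d <- diff$differing
  d$mutation_label <- paste0(d$query_aa, d$ref_pos, d$ref_aa)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
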