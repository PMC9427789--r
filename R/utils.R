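#' Residue keys
#'
#' Residues are identified throughout the package by a `(chain, resno, icode)`
#' triple rendered as a compact string, e.g. `"A:52"` or `"H:52A"`. Insertion
#' codes are part of the key because antibody numbering schemes rely on them.
#'
#' @param chain chain identifier (single character).
#' @param resno residue number (integer).
#' @param icode insertion code; `""` or `NA` when absent.
#' @return character vector of keys.
#' @export
residue_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}

#' @rdname residue_key
#' @param key keys produced by [residue_key()].
#' @return `parse_residue_key` returns a data.frame with columns
#'   `chain`, `resno`, `icode`.
#' @export
parse_residue_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):(-?[0-9]+)([A-Za-z]?)$", key))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed residue key(s): ", paste(key[bad], collapse = ", "))
  data.frame(
    chain = vapply(m, `[`, "", 2L),
    resno = as.integer(vapply(m, `[`, "", 3L)),
    icode = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# deterministic per-generator RNG substream: fold the generator name into the
# user seed so generators never share a stream
.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) * 131L + as.integer(h %% 1000L)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
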