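.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Convert between one- and three-letter amino-acid codes
#' @param x character vector of codes.
#' @return character vector of the converted codes ("UNK"/"X" if unknown).
#' @export
aa_three <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 3, x, .AA3[match(x, .AA1)])
  out[is.na(out) | !(out %in% .AA3)] <- "UNK"
  out
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 1, x, .AA1[match(x, .AA3)])
  out[is.na(out)] <- "X"
  out
}

#' Residue identifier
#'
#' A residue is identified by its 1-based sequence position (the protein's
#' native 1-124 numbering is preserved, never renumbered), a three-letter
#' amino-acid code, and an atom label (default the backbone amide "N-H").
#'
#' @param seq_number integer position, >= 1.
#' @param residue_code three-letter code (one-letter accepted and converted);
#'   must be one of the 20 standard codes or "UNK".
#' @param atom_label atom name within the residue.
#' @return object of class `"residue_id"`.
#' @export
residue_id <- function(seq_number, residue_code = "UNK", atom_label = "N-H") {
  seq_number <- as.integer(seq_number)
  if (length(seq_number) != 1L || is.na(seq_number) || seq_number < 1L)
    stop("seq_number must be a single integer >= 1")
  code <- aa_three(residue_code)
  structure(list(seq_number = seq_number, residue_code = code,
                 atom_label = atom_label),
            class = "residue_id")
}

#' @export
format.residue_id <- function(x, ...) {
  sprintf("%s%d[%s]", x$residue_code, x$seq_number, x$atom_label)
}

#' @export
print.residue_id <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# compact label used in tables, e.g. "HIS12"
residue_label <- function(x) sprintf("%s%d", x$residue_code, x$seq_number)
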