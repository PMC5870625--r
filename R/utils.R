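# Internal helpers shared across modules.

#' Build a full site key
#'
#' Site keys identify a phosphosite as `PROTEIN_POSITION_RESIDUE`
#' (e.g. `P00533_1068_Y`). Matching between quantification data and the
#' kinase-substrate network uses the residue-free form `PROTEIN_POSITION`,
#' because residue annotations frequently disagree across databases.
#'
#' @param protein protein accession
#' @param position 1-based site position
#' @param residue phosphoacceptor letter (S/T/Y)
#' @return character vector of keys
#' @export
site_key <- function(protein, position, residue) {
  paste(protein, position, residue, sep = "_")
}

#' @rdname site_key
#' @export
match_key <- function(protein, position) {
  paste(protein, position, sep = "_")
}

# set.seed only when the caller supplied one
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# derive a bounded child seed from a parent seed and an index
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 7919L * as.integer(i)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
PAD <- "_"
PWM_ALPHABET <- c(AA20, PAD)
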