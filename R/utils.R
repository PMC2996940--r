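# Internal helpers shared across modules.

# Stop with a call-free message (tidyverse style).
abort_ipcon <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "ipcon_error")
}

warn_ipcon <- function(msg, ...) {
  rlang::warn(sprintf(msg, ...), class = "ipcon_warning")
}

# Canonical empty marks table (one row per intron mark on a protein).
empty_marks <- function() {
  tibble::tibble(residue_index = integer(), phase = integer())
}

# Distinct marked residue indices of a marks tibble (codon-level collapse:
# two introns in the same codon count as one marked residue).
marked_residues <- function(marks) {
  if (is.null(marks) || nrow(marks) == 0L) return(integer())
  sort(unique(marks$residue_index))
}

# readr wrappers with quiet, reproducible settings
read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
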