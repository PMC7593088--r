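# Compact container for batches of DNA sequences: integer codes (1=A, 2=C,
# 3=G, 4=T, 5=N) concatenated into one vector plus cumulative end offsets.
# Generators and the motif scanner work on this representation; conversion to
# character strings / FASTA happens only at the package boundary.

SEQ_LETTERS <- c("A", "C", "G", "T", "N")

seq_code_lut <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("N")] <- 5L; lut[utf8ToInt("n")] <- 5L
  lut
})

seq_codes <- function(s) {
  codes <- seq_code_lut[as.integer(charToRaw(s))]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop("non-ACGTN character '", substr(s, bad, bad), "' at position ", bad)
  }
  codes
}

codes_to_string <- function(codes) {
  paste(SEQ_LETTERS[codes], collapse = "")
}

#' Build a sequence set
#'
#' @param x character vector of ACGTN sequences (optionally named), or a
#'   `seq_set` (returned unchanged).
#' @return An object of class `seq_set`.
#' @export
seqset <- function(x) {
  if (inherits(x, "seq_set")) return(x)
  stopifnot(is.character(x))
  codes <- lapply(x, seq_codes)
  lens <- lengths(codes)
  structure(list(codes = as.integer(unlist(codes, use.names = FALSE)),
                 ends = as.integer(cumsum(lens)),
                 names = if (is.null(names(x))) paste0("seq_", seq_along(x))
                         else names(x)),
            class = "seq_set")
}

new_seqset <- function(codes, lens, names = NULL) {
  structure(list(codes = as.integer(codes), ends = as.integer(cumsum(lens)),
                 names = if (is.null(names)) paste0("seq_", seq_along(lens))
                         else names),
            class = "seq_set")
}

seqset_n <- function(ss) length(ss$ends)

seqset_lengths <- function(ss) diff(c(0L, ss$ends))

seqset_extract <- function(ss, i) {
  s0 <- if (i == 1L) 1L else ss$ends[i - 1L] + 1L
  ss$codes[s0:ss$ends[i]]
}

#' Subset a sequence set by index
#' @param ss a `seq_set`.
#' @param idx integer or logical index over sequences.
#' @return a `seq_set` with the selected sequences.
#' @export
seqset_subset <- function(ss, idx) {
  stopifnot(inherits(ss, "seq_set"))
  if (is.logical(idx)) idx <- which(idx)
  idx <- sort(unique(as.integer(idx)))
  lens <- seqset_lengths(ss)
  keep <- rep(FALSE, length(lens))
  keep[idx] <- TRUE
  sel <- rep(keep, lens)
  new_seqset(ss$codes[sel], lens[idx], ss$names[idx])
}

#' @export
as.character.seq_set <- function(x, ...) {
  lens <- seqset_lengths(x)
  out <- vapply(seq_len(seqset_n(x)), function(i) {
    codes_to_string(seqset_extract(x, i))
  }, character(1))
  names(out) <- x$names
  out
}

#' @export
print.seq_set <- function(x, ...) {
  lens <- seqset_lengths(x)
  cat(sprintf("seq_set: %d sequence(s), %d bp total (lengths %d-%d)\n",
              seqset_n(x), length(x$codes),
              if (length(lens)) min(lens) else 0L,
              if (length(lens)) max(lens) else 0L))
  invisible(x)
}

#' Read DNA sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write DNA sequences to FASTA
#' @param x named character vector or `seq_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path) {
  if (inherits(x, "seq_set")) x <- as.character(x)
  dss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
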