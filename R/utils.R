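# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive an independent seed for a named random stream
#'
#' All stochastic steps draw from streams derived from one master seed, so
#' that adding or reordering a simulated matrix does not perturb the draws of
#' the others.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the stream.
#' @return an integer usable with [set.seed()].
#' @export
sub_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 1009 + as.numeric(stream) * 9973) %%
               2147483629)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, stream))
  expr
}

# Reverse complement for plain character vectors (DNA or RNA spelling).
revcomp <- function(x) {
  rna <- grepl("U", x, fixed = TRUE)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    chartr("Uu", "Tt", x))))
  ifelse(rna, chartr("Tt", "Uu", out), out)
}

#' Read and write FASTA files of plain sequences
#'
#' Thin wrappers around Biostrings that return/accept named character
#' vectors, the representation the sequence-level functions in this package
#' work with.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  setNames(as.character(s), names(s))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = 70L)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             ...)
}

# deterministic largest-remainder apportionment of n into fractions
apportion <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
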