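`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' @param x A single nucleotide string (IUPAC alphabet).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random nucleotide sequence
#'
#' i.i.d. bases at a given GC content; draws from the current RNG stream.
#'
#' @param n Length in bp.
#' @param gc GC content in `[0, 1]` (default 0.5).
#' @return A character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Oriented-contig helpers: a path is a data.frame(id, strand) with
# strand in {"+","-"}. Strings like "006+" are the on-disk notation.
oriented <- function(id, strand) {
  data.frame(id = as.character(id), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

orient_key <- function(members) paste0(members$id, members$strand)

flip_strand <- function(strand) ifelse(strand == "+", "-", "+")

#' Serialize an oriented contig path
#'
#' Canonical notation: contig id, strand sign, colon-separated, e.g.
#' `"006+:116+:091+"`.
#'
#' @param members data.frame with columns `id`, `strand`.
#' @return A character scalar.
#' @export
format_contig_path <- function(members) {
  if (is.null(members) || nrow(members) == 0L) return("")
  paste(paste0(members$id, members$strand), collapse = ":")
}

#' Parse the colon-separated oriented path notation
#'
#' Exact inverse of [format_contig_path()]. Leading zeros in ids are
#' preserved; ids are text tokens, never integers.
#'
#' @param x A path string such as `"006+:116+:091+"`.
#' @return data.frame with columns `id`, `strand`.
#' @export
parse_contig_path <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(oriented(character(0), character(0)))
  toks <- strsplit(x, ":", fixed = TRUE)[[1]]
  m <- regmatches(toks, regexec("^(.+?)([+-])$", toks))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed path token(s): ", paste(toks[bad], collapse = ", "))
  oriented(vapply(m, `[`, "", 2L), vapply(m, `[`, "", 3L))
}
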