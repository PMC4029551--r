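#' In-silico restriction digestion
#'
#' Finds every occurrence of the enzyme recognition site on the forward
#' strand (and, for non-palindromic sites, of its reverse complement) and
#' cleaves at `site start + cut_offset`. Overlapping occurrences all count.
#' Degenerate IUPAC letters in the *sequence* never satisfy a site letter
#' (conservative cut calling near ambiguous assembly bases); degenerate
#' letters in the *site* match the bases they code for.
#'
#' @param sequence Nucleotide string (linear).
#' @param enzyme A [rest_enzyme()] or built-in enzyme name.
#' @param id Identifier stored in the digest (default `"seq"`).
#' @return A `contig_digest`: list with `contig_id`, `length`,
#'   `cut_positions` (sorted 0-based bp offsets, strictly inside the
#'   sequence) and `fragments` (ordered RF lengths; `sum(fragments)` equals
#'   the sequence length).
#' @export
digest_sequence <- function(sequence, enzyme, id = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("cannot digest an empty sequence")
  enzyme <- get_enzyme(enzyme)
  subj <- Biostrings::DNAString(toupper(sequence))
  cuts <- site_cuts(subj, enzyme$site, enzyme$cut_offset)
  if (!is_palindromic(enzyme)) {
    rc <- revcomp(enzyme$site)
    # a site on the reverse strand cleaves at the mirrored offset
    cuts <- c(cuts, site_cuts(subj, rc, nchar(enzyme$site) - enzyme$cut_offset))
  }
  len <- length(subj)
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < len]
  new_digest(id, len, cuts)
}

# cut offsets (0-based) for one pattern on the forward strand
site_cuts <- function(subject, site, cut_offset) {
  hits <- Biostrings::matchPattern(site, subject,
                                   fixed = c(pattern = FALSE, subject = TRUE))
  as.integer(Biostrings::start(hits)) - 1L + as.integer(cut_offset)
}

new_digest <- function(id, len, cuts) {
  structure(list(contig_id = as.character(id),
                 length = as.integer(len),
                 cut_positions = as.integer(cuts),
                 fragments = as.integer(diff(c(0L, cuts, len)))),
            class = "contig_digest")
}

#' Reverse-complement a digest
#'
#' Mirrors cut positions and reverses the fragment list without touching
#' the sequence itself. Applying it twice is the identity.
#'
#' @param digest A `contig_digest`.
#' @return A `contig_digest` for the reverse complement.
#' @export
digest_reverse_complement <- function(digest) {
  stopifnot(inherits(digest, "contig_digest"))
  new_digest(digest$contig_id, digest$length,
             sort(digest$length - digest$cut_positions))
}

# digest viewed in path orientation
oriented_digest <- function(digest, strand) {
  if (strand == "-") digest_reverse_complement(digest) else digest
}

#' @export
print.contig_digest <- function(x, ...) {
  cat(sprintf("<contig_digest> %s  %d bp, %d cut site(s)\n",
              x$contig_id, x$length, length(x$cut_positions)))
  invisible(x)
}
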