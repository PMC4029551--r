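#' Restriction enzyme definition
#'
#' @param name Enzyme name, e.g. `"AflII"`.
#' @param site Recognition sequence (IUPAC letters allowed).
#' @param cut_offset Distance in bp from the site start to the cleavage
#'   point on the forward strand; must lie in `[0, nchar(site)]`.
#' @return An object of class `rest_enzyme`.
#' @export
rest_enzyme <- function(name, site, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(site), length(site) == 1L, nzchar(site))
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie in [0, nchar(site)]")
  structure(list(name = name, site = toupper(site), cut_offset = cut_offset),
            class = "rest_enzyme")
}

#' Built-in restriction enzymes
#'
#' AflII (C^TTAAG) and NheI (G^CTAGC); both sites are palindromic, so
#' forward-strand site matching is complete for them.
#'
#' @return Named list of [rest_enzyme()] objects.
#' @export
builtin_enzymes <- function() {
  list(
    AflII = rest_enzyme("AflII", "CTTAAG", 1L),
    NheI  = rest_enzyme("NheI",  "GCTAGC", 1L)
  )
}

#' Resolve an enzyme argument
#'
#' Accepts a `rest_enzyme` object or the name of a built-in.
#'
#' @param x Enzyme object or name.
#' @return A `rest_enzyme`.
#' @export
get_enzyme <- function(x) {
  if (inherits(x, "rest_enzyme")) return(x)
  if (is.character(x) && length(x) == 1L) {
    tab <- builtin_enzymes()
    if (x %in% names(tab)) return(tab[[x]])
    stop("unknown enzyme name: ", x,
         " (built-ins: ", paste(names(tab), collapse = ", "),
         "); pass a rest_enzyme() object for custom enzymes")
  }
  stop("enzyme must be a rest_enzyme object or a built-in name")
}

is_palindromic <- function(enzyme) {
  site <- enzyme$site
  # only meaningful for plain ACGT sites; degenerate sites are compared textually
  identical(site, revcomp(site))
}

#' @export
print.rest_enzyme <- function(x, ...) {
  before <- substr(x$site, 1L, x$cut_offset)
  after <- substr(x$site, x$cut_offset + 1L, nchar(x$site))
  cat(sprintf("<rest_enzyme> %s  %s^%s\n", x$name, before, after))
  invisible(x)
}
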