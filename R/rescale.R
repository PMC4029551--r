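#' Collect 1-vs-1 RF blocks from placements
#'
#' During alignment, runs of fragments on one side are sometimes matched to
#' a single fragment on the other (missed or spurious restriction sites,
#' assembly errors); those merged blocks carry conflated sizing. Only blocks
#' pairing exactly one map RF with exactly one contig RF are retained for
#' rescaling.
#'
#' @param placements Placements carrying block pairings (typically the
#'   unique ones).
#' @param digests Named list of digests (contig-side fragment lengths).
#' @param map A [restriction_map()].
#' @return data.frame with one row per 1-vs-1 block: `contig_id`,
#'   `map_length`, `contig_length`, `map_rf_count`, `contig_rf_count`,
#'   `ratio` (map/contig).
#' @export
collect_blocks <- function(placements, digests, map) {
  N <- length(map$fragments)
  rows <- lapply(placements, function(p) {
    if (is.null(p$blocks)) return(NULL)
    b <- p$blocks
    one <- (b$map_last - b$map_first == 0L) &
      (b$contig_last - b$contig_first == 0L)
    if (!any(one)) return(NULL)
    b <- b[one, , drop = FALSE]
    d <- digests[[p$contig_id]]
    if (is.null(d)) return(NULL)
    od <- oriented_digest(d, p$strand)
    data.frame(contig_id = p$contig_id,
               map_length = map$fragments[((b$map_first - 1L) %% N) + 1L],
               contig_length = od$fragments[b$contig_first],
               map_rf_count = 1L, contig_rf_count = 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig_id = character(0), map_length = numeric(0),
                      contig_length = numeric(0), map_rf_count = integer(0),
                      contig_rf_count = integer(0))
  out$ratio <- out$map_length / out$contig_length
  out
}

#' Fit the global map rescaling factor
#'
#' The factor is the arithmetic mean of map/contig length ratios over 1-vs-1
#' blocks whose contig-side fragment is at least `min_rf_for_fit` bp: the
#' ratio is erratic for short fragments and stabilises above 10 Kb. If no
#' block qualifies, rescaling is disabled (factor 1) with a warning.
#'
#' @param blocks data.frame from [collect_blocks()].
#' @param min_rf_for_fit Contig-side length cutoff in bp (default 10000).
#' @param robust Use the median instead of the mean (default FALSE; the mean
#'   is the method's definition).
#' @return A `rescale_model`: list with `factor`, `n_blocks_used`,
#'   `min_rf_for_fit`, and the per-block `ratios` kept for diagnostics.
#' @export
fit_factor <- function(blocks, min_rf_for_fit = 10000, robust = FALSE) {
  keep <- blocks$contig_length >= min_rf_for_fit
  ratios <- blocks$ratio[keep]
  if (length(ratios) == 0L) {
    warning("no 1-vs-1 RF block with contig fragment >= ", min_rf_for_fit,
            " bp; rescaling DISABLED (factor = 1)")
    factor <- 1
  } else {
    factor <- if (robust) stats::median(ratios) else mean(ratios)
  }
  structure(list(factor = factor, n_blocks_used = length(ratios),
                 min_rf_for_fit = min_rf_for_fit, ratios = ratios,
                 all_blocks = blocks),
            class = "rescale_model")
}

#' Rescale a raw map length into sequence bp
#'
#' Divides by the fitted factor (ratios are map/contig, so a factor below 1
#' means the map under-measures sequence length and rescaled gaps grow) and
#' rounds to the nearest integer bp.
#'
#' @param raw_size Raw (floored) map length in bp.
#' @param model A `rescale_model` from [fit_factor()].
#' @return Rescaled size in bp.
#' @export
rescale_gap <- function(raw_size, model) {
  stopifnot(inherits(model, "rescale_model"))
  if (!is.finite(model$factor) || model$factor <= 0)
    stop("rescaling factor must be > 0")
  round(raw_size / model$factor)
}

#' Write per-block ratio diagnostics
#'
#' @param model A `rescale_model`.
#' @param path Output TSV (contig-side length vs map/contig ratio for every
#'   collected 1-vs-1 block).
#' @export
write_rescale_diagnostics <- function(model, path) {
  utils::write.table(model$all_blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.rescale_model <- function(x, ...) {
  cat(sprintf("<rescale_model> factor %.4f from %d block(s) (contig RF >= %g bp)\n",
              x$factor, x$n_blocks_used, x$min_rf_for_fit))
  invisible(x)
}
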