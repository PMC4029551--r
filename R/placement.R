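#' Alignment parameters for the built-in RF aligner
#'
#' The built-in aligner is a functional stand-in for an external placement
#' tool, not a replica of one: the pipeline is placement-source-agnostic and
#' external placements can be imported with [read_placements()].
#'
#' @param sizing_tolerance Relative sizing tolerance per matched block
#'   (default 0.10).
#' @param max_merged_rfs Maximum fragments merged on either side of a block
#'   (default 3).
#' @param min_matched_rfs Minimum internal contig RFs that must be matched
#'   for a contig to be placeable (default 5).
#' @param uniqueness_margin A best placement is unique only when the
#'   second-best score exceeds it by this fraction (default 0.20).
#' @param max_unmatched_ends Up to this many leading/trailing internal
#'   contig fragments may be left unmatched, tolerating contig-boundary
#'   restriction sites that vanished from the map (default 2).
#' @param end_skip_penalty Score added per unmatched end fragment
#'   (default 0.5).
#' @param merge_penalty Score added per fragment merged beyond one on either
#'   side of a block -- a missed restriction site. Without it the aligner
#'   would always merge maximally, since summed blocks let sizing noise
#'   cancel (default 0.25).
#' @return A list of class `align_params`.
#' @export
align_params <- function(sizing_tolerance = 0.10, max_merged_rfs = 3L,
                         min_matched_rfs = 5L, uniqueness_margin = 0.20,
                         max_unmatched_ends = 2L, end_skip_penalty = 0.5,
                         merge_penalty = 0.25) {
  p <- list(sizing_tolerance = sizing_tolerance,
            max_merged_rfs = as.integer(max_merged_rfs),
            min_matched_rfs = as.integer(min_matched_rfs),
            uniqueness_margin = uniqueness_margin,
            max_unmatched_ends = as.integer(max_unmatched_ends),
            end_skip_penalty = end_skip_penalty,
            merge_penalty = merge_penalty)
  if (any(unlist(p[c(1, 2, 3, 4)]) <= 0)) stop("align parameters must be positive")
  class(p) <- "align_params"
  p
}

new_placement <- function(contig_id, strand, map_first, map_last,
                          contig_first, contig_last, score, blocks,
                          unique = NA) {
  structure(list(contig_id = contig_id, strand = strand,
                 map_first = as.integer(map_first),
                 map_last = as.integer(map_last),
                 contig_first = as.integer(contig_first),
                 contig_last = as.integer(contig_last),
                 score = score, blocks = blocks, unique = unique),
            class = "om_placement")
}

#' Align a contig digest to an optical map
#'
#' Places one contig on the map by dynamic programming over restriction
#' fragments. Only *internal* contig RFs are matched -- the fragments before
#' the first and after the last cut site are truncated by the contig
#' boundaries, not by enzyme sites, and carry no sizing information. Both
#' strands are tried; all feasible locations are returned, best score first.
#'
#' Placements use 1-based inclusive fragment indices. `map_first`/`map_last`
#' delimit the matched map fragments (`map_last` may exceed the fragment
#' count on circular maps when the match wraps the origin);
#' `contig_first`/`contig_last` index fragments of the *oriented* digest
#' (reverse-complemented for strand `-`). `blocks` is a data.frame of
#' matched block index ranges in the same conventions.
#'
#' @param digest A [digest_sequence()] result.
#' @param map A [restriction_map()].
#' @param params [align_params()].
#' @param scale_hint Known or previously estimated global map/sequence scale
#'   factor; map fragment lengths are divided by it before scoring so that a
#'   systematic sizing offset does not eat into the per-block tolerance
#'   (default 1). Placement coordinates are unaffected.
#' @return List of placements (possibly empty = unplaceable).
#' @export
align_contig <- function(digest, map, params = align_params(),
                         scale_hint = 1) {
  stopifnot(inherits(digest, "contig_digest"), inherits(map, "restriction_map"))
  m <- length(digest$fragments)
  if (m < 3L || (m - 2L) < params$min_matched_rfs) return(list())
  out <- list()
  for (strand in c("+", "-")) {
    od <- oriented_digest(digest, strand)
    internal <- od$fragments[2:(m - 1L)]
    hits <- align_dp_cpp(map$fragments / scale_hint, as.numeric(internal),
                         params$sizing_tolerance, params$max_merged_rfs,
                         params$min_matched_rfs, params$max_unmatched_ends,
                         params$end_skip_penalty, params$merge_penalty,
                         map$circular)
    for (h in hits) {
      b <- h$blocks
      blocks <- data.frame(map_first = b[, 1] + 1L, map_last = b[, 2],
                           contig_first = b[, 3] + 2L, contig_last = b[, 4] + 1L)
      out[[length(out) + 1L]] <- new_placement(
        digest$contig_id, strand,
        map_first = h$ms + 1L, map_last = h$me,
        contig_first = h$cs + 2L, contig_last = h$ce + 1L,
        score = h$score, blocks = blocks)
    }
  }
  out <- out[order(vapply(out, `[[`, 0, "score"))]
  collapse_overlaps(out, length(map$fragments))
}

# hits whose map spans substantially overlap are one genomic locus seen
# through slightly different block decompositions: keep the best-scoring one
collapse_overlaps <- function(placements, N) {
  kept <- list()
  spans <- list()
  for (p in placements) {
    idx <- (seq.int(p$map_first, p$map_last) - 1L) %% N
    dup <- FALSE
    for (s in spans) {
      if (length(intersect(idx, s)) * 2L >= min(length(idx), length(s))) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- p
      spans[[length(spans) + 1L]] <- idx
    }
  }
  kept
}

#' Classify placement uniqueness
#'
#' Groups placements by contig. A contig's placement is unique iff it is the
#' only one, or its score beats the second best by the uniqueness margin
#' (relative positions of uniquely aligned contigs on the map are of higher
#' confidence, and unique contigs terminate path searches).
#'
#' @param placements Flat list of placements (any number of contigs).
#' @param params [align_params()].
#' @return The same list with the `unique` flag filled in.
#' @export
classify_uniqueness <- function(placements, params = align_params()) {
  ids <- vapply(placements, `[[`, "", "contig_id")
  for (id in unique(ids)) {
    k <- which(ids == id)
    if (length(k) == 1L) {
      placements[[k]]$unique <- TRUE
      next
    }
    sc <- vapply(placements[k], `[[`, 0, "score")
    o <- order(sc)
    uniq <- sc[o[2]] > sc[o[1]] * (1 + params$uniqueness_margin)
    for (i in seq_along(k))
      placements[[k[i]]]$unique <- if (i == o[1]) uniq else FALSE
  }
  placements
}

#' Read a contig-to-map placement table
#'
#' Preferred route for reproducing runs made with an external aligner.
#' TSV columns: `contig_id`, `strand` (+/-), `map_start_rf`, `map_end_rf`
#' (0-based half-open RF indices), `unique` (U/N), and optionally `blocks`
#' (semicolon-separated `mapStart-mapEnd:contigStart-contigEnd` 0-based
#' half-open index ranges; contig ranges count fragments of the oriented
#' digest). A header row naming the first column `contig_id` is skipped.
#'
#' @param path Placement TSV.
#' @param contigs A [contig_set()].
#' @param map A [restriction_map()].
#' @param digests Optional named list of [digest_sequence()] results; used
#'   to fill in the full internal fragment span when `blocks` is absent.
#' @return List of placements with `unique` flags set.
#' @export
read_placements <- function(path, contigs, map, digests = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) && grepl("^contig_id\\b", lines[1])) lines <- lines[-1]
  N <- length(map$fragments)
  out <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed placement line ", k, " in ", path)
    id <- f[1]
    if (!(id %in% contigs$id)) stop("placement references unknown contig: ", id)
    if (!(f[2] %in% c("+", "-"))) stop("bad strand on line ", k)
    s <- as.integer(f[3]); e <- as.integer(f[4])
    if (is.na(s) || is.na(e) || s < 0L || e <= s || s >= N || e > N)
      stop("placement span [", f[3], ",", f[4], ") out of bounds on a ",
           N, "-RF map (line ", k, ")")
    if (!(f[5] %in% c("U", "N"))) stop("unique flag must be U or N (line ", k, ")")
    cf <- cl <- NA_integer_
    blocks <- NULL
    if (length(f) >= 6L && nzchar(f[6])) {
      parts <- strsplit(strsplit(f[6], ";", fixed = TRUE)[[1]], "[:-]")
      bm <- do.call(rbind, lapply(parts, as.integer))
      if (is.null(bm) || ncol(bm) != 4L || any(is.na(bm)))
        stop("malformed blocks field on line ", k)
      blocks <- data.frame(map_first = bm[, 1] + 1L, map_last = bm[, 2],
                           contig_first = bm[, 3] + 1L, contig_last = bm[, 4])
      cf <- blocks$contig_first[1]
      cl <- blocks$contig_last[nrow(blocks)]
    } else if (!is.null(digests) && id %in% names(digests)) {
      m <- length(digests[[id]]$fragments)
      if (m >= 3L) { cf <- 2L; cl <- m - 1L }
    }
    out[[length(out) + 1L]] <- new_placement(
      id, f[2], map_first = s + 1L, map_last = e,
      contig_first = cf, contig_last = cl,
      score = if (length(f) >= 7L) as.numeric(f[7]) else 0,
      blocks = blocks, unique = f[5] == "U")
  }
  out
}

# map fragment indices (1-based) strictly between site `site_a` and site
# `site_b` (site k = boundary after fragment k); wrap-aware for circular maps
frags_between <- function(site_a, site_b, N, circular) {
  site_a <- site_a %% N
  site_b <- site_b %% N
  if (site_b == site_a) return(integer(0))
  if (site_b > site_a) return(seq.int(site_a + 1L, site_b))
  if (!circular) stop("inverted gap on a linear map")
  c(seq.int(site_a + 1L, N), seq_len(site_b))
}

#' Build inter-contig gaps from classified placements
#'
#' Placements are ordered along the map; each consecutive pair of retained
#' placements becomes a gap running from the rightmost matched restriction
#' site of the left contig to the leftmost matched site of the right one.
#' Circular maps add the wrap-around pair. A map RF shorter than `rf_floor`
#' counts as `rf_floor` bp in the raw gap size (such fragments tend to
#' disappear from real maps, so their measured absence is floored at the
#' map's resolution). By default only unique placements are used;
#' `include_nonunique` adds the best placement of every non-unique contig.
#'
#' @param placements Classified placements ([classify_uniqueness()]).
#' @param map A [restriction_map()].
#' @param digests Named list of digests (for the flank tail/head bp of the
#'   gap-delimiting sites).
#' @param include_nonunique Also use non-unique contigs (default FALSE).
#' @param rf_floor Minimum credited RF length in bp (default 2000).
#' @return List of gap specs with fields `left`, `right` (oriented contigs),
#'   `gap_rfs` (raw RF lengths strictly between the flanking matched sites),
#'   `raw_size`, `rescaled_size` (NA until rescaling), `left_tail`,
#'   `right_head` (bp from the delimiting site to the flank's path-facing
#'   end). Overlapping placements skip the pair with a warning.
#' @export
build_gaps <- function(placements, map, digests, include_nonunique = FALSE,
                       rf_floor = 2000) {
  used <- Filter(function(p) isTRUE(p$unique), placements)
  if (include_nonunique) {
    uniq_ids <- vapply(used, `[[`, "", "contig_id")
    rest <- Filter(function(p) !isTRUE(p$unique), placements)
    for (id in unique(vapply(rest, `[[`, "", "contig_id"))) {
      if (id %in% uniq_ids) next
      cand <- Filter(function(p) p$contig_id == id, rest)
      best <- cand[[which.min(vapply(cand, `[[`, 0, "score"))]]
      used[[length(used) + 1L]] <- best
    }
  }
  if (length(used) < 2L) return(list())
  N <- length(map$fragments)
  starts <- vapply(used, function(p) ((p$map_first - 1L) %% N) + 1L, 0L)
  used <- used[order(starts)]
  n <- length(used)
  pairs <- if (map$circular) cbind(seq_len(n), c(seq_len(n)[-1], 1L))
           else cbind(seq_len(n - 1L), seq.int(2L, n))
  gaps <- list()
  for (r in seq_len(nrow(pairs))) {
    L <- used[[pairs[r, 1]]]
    R <- used[[pairs[r, 2]]]
    site_l <- L$map_last
    site_r <- R$map_first - 1L
    wrap_pair <- map$circular && pairs[r, 2] == 1L && n > 1L
    if (wrap_pair) site_r <- site_r + N
    if (site_r < site_l) {
      warning("overlapping placements, skipping gap ",
              L$contig_id, L$strand, " -> ", R$contig_id, R$strand)
      next
    }
    idx <- frags_between(site_l, site_r, N, map$circular)
    rfs <- map$fragments[idx]
    gaps[[length(gaps) + 1L]] <- list(
      left = list(id = L$contig_id, strand = L$strand),
      right = list(id = R$contig_id, strand = R$strand),
      gap_rfs = rfs,
      raw_size = sum(pmax(rfs, rf_floor)),
      rescaled_size = NA_real_,
      left_tail = flank_tail(L, digests),
      right_head = flank_head(R, digests))
  }
  gaps
}

# bp from the rightmost matched site of a flank to its path-facing end
flank_tail <- function(p, digests) {
  d <- digests[[p$contig_id]]
  if (is.null(d) || is.na(p$contig_last)) return(NA_real_)
  od <- oriented_digest(d, p$strand)
  if (p$contig_last > length(od$cut_positions)) return(NA_real_)
  od$length - od$cut_positions[p$contig_last]
}

# bp from the oriented start of a flank to its leftmost matched site
flank_head <- function(p, digests) {
  d <- digests[[p$contig_id]]
  if (is.null(d) || is.na(p$contig_first)) return(NA_real_)
  od <- oriented_digest(d, p$strand)
  if (p$contig_first - 1L < 1L || p$contig_first - 1L > length(od$cut_positions))
    return(NA_real_)
  od$cut_positions[p$contig_first - 1L]
}

#' @export
print.om_placement <- function(x, ...) {
  cat(sprintf("<placement> %s%s map RFs [%d..%d] score %.4g unique=%s\n",
              x$contig_id, x$strand, x$map_first, x$map_last, x$score,
              x$unique))
  invisible(x)
}
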