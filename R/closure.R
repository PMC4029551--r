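optimal_copies <- function(base_length, loop_length, gap_size) {
  if (loop_length <= 0) return(0L)
  t <- (gap_size - base_length) / loop_length
  cand <- unique(pmax(0L, c(floor(t), ceiling(t), 0)))
  err <- abs(base_length + cand * loop_length - gap_size)
  # ties break toward fewer copies
  best <- cand[order(err, cand)][1]
  as.integer(best)
}

#' Optimize repeat-loop copy numbers for one candidate path
#'
#' For each recorded loop independently, the copy count `n >= 0` minimising
#' `|base_length + n * loop_length - gap_size|` is chosen (ties toward
#' smaller `n`); combinations of loops are never enumerated -- with several
#' loops the independent optima simply add up, which is deliberately
#' conservative and usually leaves multi-loop gaps unclosed. Chosen copies
#' are spliced into the member list immediately after the loop's anchor;
#' a loop whose anchor only exists inside another chosen loop is spliced
#' after that loop is (nested repeats), and is dropped (0 copies) if its
#' anchor never materialises.
#'
#' @param path Candidate from [find_paths()] (`members`, `base_length`,
#'   `loops`).
#' @param gap_size Rescaled gap size in bp.
#' @param junction_overlap bp trimmed per junction (default 0).
#' @return List with `members` (expanded oriented list), `final_length`,
#'   `copies` (named integer vector per loop key).
#' @export
optimize_loop_copies <- function(path, gap_size, junction_overlap = 0) {
  members <- path$members
  final <- path$base_length
  copies <- integer(0)
  loops <- path$loops %||% list()
  if (length(loops)) {
    n <- vapply(loops, function(lp)
      optimal_copies(path$base_length, lp$loop_length, gap_size), 0L)
    names(n) <- vapply(loops, `[[`, "", "key")
    pending <- which(n > 0L)
    repeat {
      placed_any <- FALSE
      for (k in pending) {
        lp <- loops[[k]]
        akey <- paste0(lp$anchor$id, lp$anchor$strand)
        pos <- match(akey, orient_key(members))
        if (is.na(pos)) next
        splice <- do.call(rbind, rep(list(lp$members), n[k]))
        members <- rbind(members[seq_len(pos), , drop = FALSE], splice,
                         if (pos < nrow(members))
                           members[seq.int(pos + 1L, nrow(members)), , drop = FALSE])
        final <- final + unname(n[k]) * lp$loop_length
        pending <- setdiff(pending, k)
        placed_any <- TRUE
      }
      if (!placed_any || !length(pending)) break
    }
    n[pending] <- 0L   # anchor never materialised
    copies <- n
  }
  rownames(members) <- NULL
  list(members = members, final_length = final, copies = copies)
}

#' Select the best contig path for a gap
#'
#' Candidates are loop-optimized, then ranked by |final length - rescaled
#' gap size|. The gap closes only when the best candidate lies within
#' `match_tolerance` of the gap size AND (if a runner-up exists) the two
#' best path lengths differ by more than `ambiguity_cutoff`; otherwise the
#' gap stays open and, when the failure is ambiguity, every surviving
#' candidate is kept for the intermediate file. When the best path carries
#' several loops and more than one candidate survives the tolerance, the
#' gap is also left unclosed (loop combinations are not arbitrated).
#'
#' @param candidates `candidates` element from [find_paths()].
#' @param gap Gap spec with `rescaled_size`.
#' @param params [search_params()].
#' @param junction_overlap bp trimmed per junction (default 0).
#' @return A closure record: list with `gap`, `status` (`closed`,
#'   `ambiguous`, `no_path`, `out_of_tolerance`), `best_path`,
#'   `final_length`, `length_difference`, `runner_up_margin`,
#'   `candidates_considered`, `ranked`.
#' @export
select_best <- function(candidates, gap, params = search_params(),
                        junction_overlap = 0) {
  base <- list(gap = gap, status = NULL, best_path = NULL,
               final_length = NA_real_, length_difference = NA_real_,
               runner_up_margin = NA_real_,
               candidates_considered = length(candidates), ranked = list())
  if (length(candidates) == 0L) {
    base$status <- "no_path"
    return(base)
  }
  opt <- lapply(candidates, optimize_loop_copies, gap_size = gap$rescaled_size,
                junction_overlap = junction_overlap)
  # distinct expansions only (different bases can expand identically)
  sig <- vapply(opt, function(o) paste(orient_key(o$members), collapse = ":"), "")
  keep <- !duplicated(sig)
  opt <- opt[keep]
  n_loops <- vapply(candidates[keep], function(p) length(p$loops %||% list()), 0L)
  finals <- vapply(opt, `[[`, 0, "final_length")
  diffs <- abs(finals - gap$rescaled_size)
  o <- order(diffs, finals)
  ranked <- lapply(o, function(i) list(members = opt[[i]]$members,
                                       final_length = finals[i],
                                       diff = diffs[i],
                                       n_loops = n_loops[i],
                                       copies = opt[[i]]$copies))
  base$ranked <- ranked
  best <- ranked[[1]]
  base$final_length <- best$final_length
  base$length_difference <- best$diff
  if (length(ranked) > 1L)
    base$runner_up_margin <- abs(best$final_length - ranked[[2]]$final_length)
  if (best$diff > params$match_tolerance) {
    base$status <- "out_of_tolerance"
    return(base)
  }
  within_tol <- sum(vapply(ranked, `[[`, 0, "diff") <= params$match_tolerance)
  if (length(ranked) > 1L && base$runner_up_margin <= params$ambiguity_cutoff) {
    base$status <- "ambiguous"
    return(base)
  }
  if (best$n_loops > 1L && within_tol > 1L) {
    base$status <- "ambiguous"
    return(base)
  }
  base$status <- "closed"
  base$best_path <- best$members
  base
}

#' Stitch a closed path into nucleotide sequence
#'
#' Members are concatenated in order, minus-strand members
#' reverse-complemented, and `junction_overlap` bp trimmed from the start of
#' each incoming member.
#'
#' @param members Oriented member data.frame (flanks included), e.g.
#'   `best_path` of a closed gap.
#' @param sequences Named character vector or list of contig sequences.
#' @param junction_overlap bp trimmed per junction (default 0).
#' @return The stitched nucleotide sequence.
#' @export
stitch_path <- function(members, sequences, junction_overlap = 0) {
  sequences <- as.list(sequences)
  parts <- character(nrow(members))
  for (i in seq_len(nrow(members))) {
    s <- sequences[[members$id[i]]]
    if (is.null(s) || is.na(s))
      stop("no sequence available for contig ", members$id[i])
    if (members$strand[i] == "-") s <- revcomp(s)
    if (i > 1L && junction_overlap > 0L)
      s <- substring(s, junction_overlap + 1L)
    parts[i] <- s
  }
  paste(parts, collapse = "")
}

#' Assembly statistics (count, total length, N50)
#'
#' N50 is the largest length L such that contigs of length >= L sum to at
#' least half the total length.
#'
#' @param lengths Contig lengths in bp (non-empty).
#' @return List with `n`, `total_bp`, `n50_bp`.
#' @export
assembly_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L || any(!is.finite(lengths)))
    stop("lengths must be a non-empty finite vector")
  s <- sort(lengths, decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= sum(s) / 2)[1]]
  list(n = length(lengths), total_bp = sum(lengths), n50_bp = n50)
}

#' Audit the closure invariant
#'
#' Every closed gap must satisfy: length difference within the match
#' tolerance and (when a runner-up exists) runner-up margin above the
#' ambiguity cutoff.
#'
#' @param closures List of closure records.
#' @param params [search_params()].
#' @return TRUE invisibly; stops with the offending gaps otherwise.
#' @export
audit_closures <- function(closures, params = search_params()) {
  for (cl in closures) {
    if (!identical(cl$status, "closed")) next
    ok <- cl$length_difference <= params$match_tolerance &&
      (is.na(cl$runner_up_margin) ||
         cl$runner_up_margin > params$ambiguity_cutoff)
    if (!ok)
      stop("closure invariant violated for gap ",
           cl$gap$left$id, cl$gap$left$strand, " -> ",
           cl$gap$right$id, cl$gap$right$strand)
  }
  invisible(TRUE)
}
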