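#' Path-search parameters
#'
#' @param length_slack A branch is abandoned once the accumulated path
#'   length exceeds `length_slack` times the rescaled gap size (default 1.2).
#' @param rf_floor Minimum credited map RF length in bp (default 2000).
#' @param ambiguity_cutoff The two best candidate path lengths must differ
#'   by more than this many bp for a gap to close (default 2000).
#' @param match_tolerance Maximum |path length - gap size| for closure, bp
#'   (default 2000).
#' @param max_paths Safety valve on the candidate count (default 10000).
#' @param max_steps Safety valve on DFS expansions (default 1e6).
#' @return A list of class `search_params`.
#' @export
search_params <- function(length_slack = 1.2, rf_floor = 2000,
                          ambiguity_cutoff = 2000, match_tolerance = 2000,
                          max_paths = 10000L, max_steps = 1e6) {
  if (length_slack <= 1) stop("length_slack must exceed 1")
  if (min(rf_floor, ambiguity_cutoff, match_tolerance) < 0)
    stop("bp parameters must be >= 0")
  structure(list(length_slack = length_slack, rf_floor = rf_floor,
                 ambiguity_cutoff = ambiguity_cutoff,
                 match_tolerance = match_tolerance,
                 max_paths = as.integer(max_paths), max_steps = max_steps),
            class = "search_params")
}

# adjacency of the bidirected graph: "id|end" -> data.frame(id, end) of
# opposite endpoints, deduplicated and lexicographically ordered so the
# traversal (and hence all output) is reproducible
build_adjacency <- function(edges) {
  adj <- new.env(parent = emptyenv())
  add <- function(from_id, from_end, to_id, to_end) {
    key <- paste0(from_id, "|", from_end)
    cur <- if (!is.null(adj[[key]])) adj[[key]] else
      data.frame(id = character(0), end = character(0), stringsAsFactors = FALSE)
    adj[[key]] <- rbind(cur, data.frame(id = to_id, end = to_end,
                                        stringsAsFactors = FALSE))
  }
  for (r in seq_len(nrow(edges))) {
    add(edges$id1[r], edges$end1[r], edges$id2[r], edges$end2[r])
    if (!(edges$id1[r] == edges$id2[r] && edges$end1[r] == edges$end2[r]))
      add(edges$id2[r], edges$end2[r], edges$id1[r], edges$end1[r])
  }
  for (key in ls(adj)) {
    nb <- adj[[key]]
    nb <- nb[!duplicated(paste0(nb$id, "|", nb$end)), , drop = FALSE]
    adj[[key]] <- nb[order(nb$id, nb$end), , drop = FALSE]
  }
  adj
}

#' Sequence-side length of a contig path
#'
#' The stitched-sequence distance between the two restriction sites that
#' delimit the gap on the map: the left flank's tail after its delimiting
#' site (in path orientation), the intermediate contig lengths, and the
#' right flank's head before its delimiting site, minus `junction_overlap`
#' bp per junction. By default the delimiting sites are the flanks' last /
#' first cut sites; pass `left_tail` / `right_head` to use the matched
#' sites recorded in a placement.
#'
#' @param path A candidate path (list with `$members`) or a data.frame of
#'   oriented members (`id`, `strand`), flanks included.
#' @param digests Named list of [digest_sequence()] results for all members.
#' @param junction_overlap bp trimmed at each junction (default 0).
#' @param left_tail,right_head Optional flank offsets in bp.
#' @return Length in bp.
#' @export
path_length <- function(path, digests, junction_overlap = 0,
                        left_tail = NULL, right_head = NULL) {
  members <- if (is.data.frame(path)) path else path$members
  n <- nrow(members)
  stopifnot(n >= 2L)
  if (is.null(left_tail)) {
    od <- oriented_digest(digests[[members$id[1]]], members$strand[1])
    if (!length(od$cut_positions))
      stop("left flank ", members$id[1], " has no restriction site; gap undefined")
    left_tail <- od$length - max(od$cut_positions)
  }
  if (is.null(right_head)) {
    od <- oriented_digest(digests[[members$id[n]]], members$strand[n])
    if (!length(od$cut_positions))
      stop("right flank ", members$id[n], " has no restriction site; gap undefined")
    right_head <- min(od$cut_positions)
  }
  mid <- 0
  if (n > 2L)
    mid <- sum(vapply(members$id[2:(n - 1L)],
                      function(id) as.numeric(digests[[id]]$length), 0))
  left_tail + mid + right_head - junction_overlap * (n - 1L)
}

#' Enumerate length-admissible candidate paths across a gap
#'
#' Modified depth-first search over the bidirected contig graph, starting at
#' the left flank's exit end (3' for `+`, 5' for `-`) and honouring end
#' orientation throughout. A branch is abandoned when its accumulated length
#' exceeds `length_slack` times the rescaled gap size, or when the next
#' contig is uniquely placed (it appears once in the genome) and is not the
#' right flank. When the next contig already lies on the current path in the
#' same orientation, a loop is recorded -- anchor, members traversed around
#' the cycle, and bp contributed per extra traversal -- and the branch is
#' not re-expanded; loop copy numbers are decided later against the gap
#' size. A contig may be re-entered in the opposite orientation (tandem
#' arrangements flanked by the same inverted repeat).
#'
#' Recorded loops are attached to every candidate whose members (or
#' transitively, an attached loop's members) contain the loop anchor; a
#' loop found while already inside another loop therefore rides along with
#' its inner anchor.
#'
#' @param graph A [contig_graph()].
#' @param left,right Oriented flanks: lists with `id`, `strand`.
#' @param gap Gap spec from [build_gaps()] with `rescaled_size`,
#'   `left_tail`, `right_head` set.
#' @param unique_ids Character vector of uniquely placed contig ids.
#' @param params [search_params()].
#' @param junction_overlap bp trimmed per junction (default 0).
#' @return List with `candidates` (each: `members` data.frame, `base_length`,
#'   `loops`) and `overflow` (TRUE when a safety valve tripped; no closure
#'   should be attempted then).
#' @export
find_paths <- function(graph, left, right, gap, unique_ids,
                       params = search_params(), junction_overlap = 0) {
  lens <- stats::setNames(as.numeric(graph$contigs$length), graph$contigs$id)
  adj <- build_adjacency(graph$edges)
  bound <- params$length_slack * gap$rescaled_size
  if (!is.finite(gap$left_tail) || !is.finite(gap$right_head))
    stop("gap flank without a matched restriction site")
  res <- new.env(parent = emptyenv())
  res$cands <- list()
  res$loops <- list()
  res$steps <- 0
  res$overflow <- FALSE
  right_key <- paste0(right$id, right$strand)

  recurse <- function(ids, strands, okeys, acc) {
    if (res$overflow) return(invisible())
    res$steps <- res$steps + 1
    if (res$steps > params$max_steps || length(res$cands) > params$max_paths) {
      res$overflow <- TRUE
      return(invisible())
    }
    cur <- length(ids)
    exit_end <- if (strands[cur] == "+") "3'" else "5'"
    nb <- adj[[paste0(ids[cur], "|", exit_end)]]
    if (is.null(nb)) return(invisible())
    for (t in seq_len(nrow(nb))) {
      nid <- nb$id[t]
      nstrand <- if (nb$end[t] == "5'") "+" else "-"
      nkey <- paste0(nid, nstrand)
      if (nkey == right_key) {
        total <- acc + gap$right_head - junction_overlap
        if (total <= bound) {
          members <- oriented(c(ids, right$id), c(strands, right$strand))
          res$cands[[paste(okeys, collapse = ":")]] <-
            list(members = members, base_length = total)
        }
        next
      }
      if (nid %in% unique_ids) next   # uniquely placed: appears once
      if (nid == left$id) next        # the left flank may not be re-entered
      j <- match(nkey, okeys)
      if (!is.na(j)) {
        # oriented revisit: record the cycle, do not re-expand it
        midx <- if (j < cur) seq.int(j + 1L, cur) else integer(0)
        mids <- c(ids[midx], nid)
        mstr <- c(strands[midx], nstrand)
        lkey <- paste(nkey, paste(paste0(mids, mstr), collapse = ":"), sep = "@")
        if (is.null(res$loops[[lkey]]))
          res$loops[[lkey]] <- list(
            anchor = list(id = nid, strand = nstrand),
            members = oriented(mids, mstr),
            loop_length = sum(lens[mids]) - junction_overlap * length(mids),
            key = lkey)
        next
      }
      nacc <- acc + lens[nid] - junction_overlap
      if (nacc > bound) next
      recurse(c(ids, nid), c(strands, nstrand), c(okeys, nkey), nacc)
    }
    invisible()
  }

  recurse(left$id, left$strand, paste0(left$id, left$strand), gap$left_tail)

  loops <- if (length(res$loops)) res$loops[order(names(res$loops))] else list()
  cands <- if (length(res$cands)) res$cands[order(names(res$cands))] else list()
  candidates <- lapply(cands, function(cand) {
    present <- orient_key(cand$members)
    attached <- list()
    repeat {
      grew <- FALSE
      for (lp in loops) {
        akey <- paste0(lp$anchor$id, lp$anchor$strand)
        if (!is.null(attached[[lp$key]])) next
        if (akey %in% present) {
          attached[[lp$key]] <- lp
          present <- union(present, orient_key(lp$members))
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    cand$loops <- if (length(attached)) unname(attached[order(names(attached))])
                  else list()
    cand
  })
  list(candidates = unname(candidates), overflow = res$overflow,
       n_steps = res$steps)
}
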