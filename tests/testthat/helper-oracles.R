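# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive so it never shares code paths with the implementation.

with_seed <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# brute-force substring scan for enzyme sites (exact ACGT sites only)
naive_cut_positions <- function(sequence, site, cut_offset) {
  n <- nchar(sequence)
  w <- nchar(site)
  cuts <- integer(0)
  for (i in seq_len(max(0L, n - w + 1L))) {
    if (substr(sequence, i, i + w - 1L) == site)
      cuts <- c(cuts, i - 1L + cut_offset)
  }
  cuts[cuts > 0L & cuts < n]
}

# quick oriented-contig constructors
oc <- function(id, strand) list(id = id, strand = strand)

# contig set + graph from a compact edge table; ends written "3" / "5"
toy_graph <- function(lengths, edges) {
  cs <- contig_set(names(lengths), unname(lengths), large_threshold = 1L)
  e <- do.call(rbind, lapply(edges, function(x)
    data.frame(id1 = x[1], end1 = paste0(x[2], "'"),
               id2 = x[3], end2 = paste0(x[4], "'"),
               stringsAsFactors = FALSE)))
  contig_graph(cs, e)
}

toy_gap <- function(left, right, size, left_tail, right_head) {
  list(left = left, right = right, gap_rfs = numeric(0), raw_size = size,
       rescaled_size = size, left_tail = left_tail, right_head = right_head)
}

# ---- brute-force bounded-walk enumeration over the bidirected graph ------

# all walks from left (exit end) to right (entry end) with sequence-side
# length <= bound; unique contigs may appear only as flanks. Returns a list
# of character vectors of oriented keys ("id+"/"id-"), flanks included.
brute_walks <- function(graph, left, right, left_tail, right_head, bound,
                        unique_ids) {
  lens <- stats::setNames(as.numeric(graph$contigs$length), graph$contigs$id)
  E <- graph$edges
  neighbours <- function(id, end) {
    hit1 <- E$id1 == id & E$end1 == end
    hit2 <- E$id2 == id & E$end2 == end
    rbind(data.frame(id = E$id2[hit1], end = E$end2[hit1]),
          data.frame(id = E$id1[hit2], end = E$end1[hit2]))
  }
  out <- list()
  rec <- function(id, strand, acc, walk) {
    exit_end <- if (strand == "+") "3'" else "5'"
    nb <- neighbours(id, exit_end)
    if (!nrow(nb)) return()
    for (t in seq_len(nrow(nb))) {
      nid <- nb$id[t]
      nstrand <- if (nb$end[t] == "5'") "+" else "-"
      if (nid == right$id && nstrand == right$strand) {
        if (acc + right_head <= bound)
          out[[length(out) + 1L]] <<- c(walk, paste0(nid, nstrand))
      }
      if (nid %in% unique_ids) next
      nacc <- acc + lens[[nid]]
      if (nacc <= bound)
        rec(nid, nstrand, nacc, c(walk, paste0(nid, nstrand)))
    }
  }
  rec(left$id, left$strand, left_tail, paste0(left$id, left$strand))
  unique(out)
}

# canonicalise a walk by first-repeat cycle excision: returns the simple
# base path and a named count vector of loops keyed "anchor@m1:m2:...:anchor"
reduce_walk <- function(walk) {
  loops <- character(0)
  repeat {
    dup <- NA_integer_
    seen <- character(0)
    for (i in seq_along(walk)) {
      if (walk[i] %in% seen) { dup <- i; break }
      seen <- c(seen, walk[i])
    }
    if (is.na(dup)) break
    j <- match(walk[dup], walk)
    loops <- c(loops, paste0(walk[dup], "@",
                             paste(walk[(j + 1L):dup], collapse = ":")))
    walk <- walk[-((j + 1L):dup)]
  }
  cnt <- table(loops)
  list(base = paste(walk, collapse = ":"),
       loops = stats::setNames(as.integer(cnt), names(cnt)))
}

canon_form <- function(base, loop_counts) {
  used <- if (length(loop_counts)) loop_counts[loop_counts > 0L] else integer(0)
  tag <- if (length(used)) {
    used <- used[order(names(used))]
    paste(names(used), used, sep = "x", collapse = ";")
  } else ""
  paste(base, tag, sep = " | ")
}

# every feasible (loop copy assignment) of a candidate within the bound,
# respecting anchor availability (a nested loop needs its anchor spliced in)
candidate_forms <- function(cand, bound) {
  base_key <- paste(paste0(cand$members$id, cand$members$strand), collapse = ":")
  loops <- cand$loops
  if (!length(loops)) {
    if (cand$base_length <= bound) return(canon_form(base_key, integer(0)))
    return(character(0))
  }
  lls <- vapply(loops, `[[`, 0, "loop_length")
  keys <- vapply(loops, `[[`, "", "key")
  nmax <- pmax(0, floor((bound - cand$base_length) / lls))
  grid <- expand.grid(lapply(nmax, function(m) 0:m))
  forms <- character(0)
  base_present <- paste0(cand$members$id, cand$members$strand)
  for (r in seq_len(nrow(grid))) {
    n <- as.integer(grid[r, ])
    if (cand$base_length + sum(n * lls) > bound) next
    # anchors of chosen loops must materialise (transitively)
    present <- base_present
    active <- which(n > 0L)
    repeat {
      ok <- vapply(active, function(k)
        paste0(loops[[k]]$anchor$id, loops[[k]]$anchor$strand) %in% present,
        NA)
      if (all(ok)) break
      progressed <- FALSE
      for (k in active[ok]) {
        mem <- paste0(loops[[k]]$members$id, loops[[k]]$members$strand)
        if (!all(mem %in% present)) { present <- union(present, mem); progressed <- TRUE }
      }
      if (!progressed) break
    }
    feasible <- all(vapply(active, function(k)
      paste0(loops[[k]]$anchor$id, loops[[k]]$anchor$strand) %in% present, NA))
    if (!feasible) next
    forms <- c(forms, canon_form(base_key, stats::setNames(n, keys)))
  }
  unique(forms)
}

# random bidirected search instance with a known backbone path
random_search_instance <- function(seed) {
  with_seed(seed, {
    n <- sample(4:7, 1)
    ids <- sprintf("n%02d", seq_len(n))
    lens <- stats::setNames(round(stats::runif(n, 5000, 50000)), ids)
    k <- sample(0:(n - 2L), 1)
    mid <- if (k > 0) sample(ids[2:(n - 1L)], k) else character(0)
    chain <- c(ids[1], mid, ids[n])
    edges <- lapply(seq_len(length(chain) - 1L), function(i)
      c(chain[i], "3", chain[i + 1L], "5"))
    for (m in seq_len(sample(2:4, 1))) {
      a <- sample(ids, 1); b <- sample(ids, 1)
      edges[[length(edges) + 1L]] <- c(a, sample(c("3", "5"), 1),
                                       b, sample(c("3", "5"), 1))
    }
    graph <- toy_graph(lens, edges)
    left <- oc(ids[1], "+")
    right <- oc(ids[n], "+")
    left_tail <- round(lens[[1]] / 2)
    right_head <- round(lens[[n]] / 2)
    gap_size <- left_tail + sum(lens[mid]) + right_head
    list(graph = graph, left = left, right = right,
         gap = toy_gap(left, right, gap_size, left_tail, right_head),
         unique_ids = c(ids[1], ids[n]))
  })
}
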