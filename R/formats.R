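#' Construct a contig set
#'
#' A contig set is a data.frame (class `contig_set`) with columns `id`,
#' `name`, `length`, `coverage`, `is_large`, `sequence`. `sequence` and
#' `coverage` may be `NA`. Ids are text tokens and compare as strings
#' (leading zeros preserved).
#'
#' @param id,name,length,coverage,sequence Column vectors (recycled where
#'   length one).
#' @param large_threshold Contigs of at least this length (bp) are flagged
#'   `is_large` (default 500).
#' @return A `contig_set`.
#' @export
contig_set <- function(id, length, name = id, coverage = NA_real_,
                       sequence = NA_character_, large_threshold = 500L) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate contig ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  length <- as.integer(length)
  if (any(is.na(length)) || any(length < 1L)) stop("contig lengths must be >= 1")
  sequence <- as.character(sequence)
  ok <- is.na(sequence) | nchar(sequence) == length
  if (!all(ok)) stop("sequence length disagrees with declared length for: ",
                     paste(id[!ok], collapse = ", "))
  out <- data.frame(id = id, name = as.character(name), length = length,
                    coverage = as.numeric(coverage),
                    is_large = length >= large_threshold,
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("contig_set", "data.frame")
  attr(out, "large_threshold") <- as.integer(large_threshold)
  out
}

#' Read contigs from FASTA
#'
#' One contig per record; the id is the first whitespace-delimited token of
#' the header and must be unique. Order of appearance is preserved.
#'
#' @param path FASTA file.
#' @param large_threshold Large-contig length threshold in bp (default 500).
#' @return A [contig_set()].
#' @export
read_contigs <- function(path, large_threshold = 500L) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  hdr <- names(seqs)
  ids <- sub("\\s.*$", "", hdr)
  contig_set(id = ids, length = Biostrings::width(seqs), name = hdr,
             sequence = as.character(seqs), large_threshold = large_threshold)
}

#' Write contig sequences to FASTA
#'
#' @param ids Header lines (without `>`).
#' @param sequences Character vector of sequences, parallel to `ids`.
#' @param path Output file.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- sequences[i]
    starts <- seq(1L, max(1L, nchar(s)), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

# canonical edge representation: endpoint tokens "id|end", lexicographically
# ordered within the pair so duplicates collapse regardless of direction
canon_edges <- function(id1, end1, id2, end2) {
  a <- paste0(id1, "|", end1)
  b <- paste0(id2, "|", end2)
  swap <- a > b
  e <- data.frame(id1 = ifelse(swap, id2, id1), end1 = ifelse(swap, end2, end1),
                  id2 = ifelse(swap, id1, id2), end2 = ifelse(swap, end1, end2),
                  stringsAsFactors = FALSE)
  e[!duplicated(paste(e$id1, e$end1, e$id2, e$end2)), , drop = FALSE]
}

#' Construct a contig graph
#'
#' Bidirected adjacency between contig ends. Edges are unordered pairs of
#' (contig id, end) with end in `"5'"`/`"3'"`; duplicates are collapsed and
#' self-edges (same contig, same or different end) are permitted -- they
#' arise from tandem and palindromic repeats.
#'
#' @param contigs A [contig_set()].
#' @param edges data.frame with columns `id1`, `end1`, `id2`, `end2`.
#' @return A `contig_graph` (list with `contigs`, `edges`).
#' @export
contig_graph <- function(contigs, edges) {
  stopifnot(inherits(contigs, "contig_set"))
  ends_ok <- c("5'", "3'")
  if (nrow(edges)) {
    if (!all(edges$end1 %in% ends_ok) || !all(edges$end2 %in% ends_ok))
      stop("edge ends must be 5' or 3'")
    known <- c(edges$id1, edges$id2) %in% contigs$id
    if (!all(known))
      stop("edge endpoint names unknown contig(s): ",
           paste(unique(c(edges$id1, edges$id2)[!known]), collapse = ", "))
    edges <- canon_edges(edges$id1, edges$end1, edges$id2, edges$end2)
  } else {
    edges <- data.frame(id1 = character(0), end1 = character(0),
                        id2 = character(0), end2 = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(contigs = contigs, edges = edges), class = "contig_graph")
}

#' Read a contig graph
#'
#' Two dialects. `generic_tsv` is a 4-column TSV (`idA endA idB endB`,
#' ends `5'`/`3'`; `#` comment lines skipped). `newbler` parses a Newbler
#' `454ContigGraph.txt`: numeric contig records
#' (`index  name  length  coverage`) and `C` edge records
#' (`C  indexA  endA  indexB  endB`); all other record types are skipped.
#' Contigs present in the graph file but absent from `contigs` are added as
#' length-only synthetic entries with a warning.
#'
#' @param path Graph file.
#' @param dialect `"generic_tsv"` or `"newbler"`.
#' @param contigs A [contig_set()] the edges are bound to.
#' @return A [contig_graph()].
#' @export
read_contig_graph <- function(path, dialect = c("generic_tsv", "newbler"),
                              contigs) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "generic_tsv") {
    keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
    idx <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- vapply(fields, length, 1L) != 4L
    if (any(bad)) stop("malformed edge line ", idx[bad][1], " in ", path)
    e <- do.call(rbind, fields)
    edges <- data.frame(id1 = e[, 1], end1 = e[, 2], id2 = e[, 3], end2 = e[, 4],
                        stringsAsFactors = FALSE)
    bad_end <- !(edges$end1 %in% c("5'", "3'")) | !(edges$end2 %in% c("5'", "3'"))
    if (any(bad_end)) stop("edge end token not in {3',5'} at line ", idx[bad_end][1])
  } else {
    recs <- strsplit(lines, "\t", fixed = TRUE)
    first <- vapply(recs, function(f) if (length(f)) f[[1]] else "", "")
    is_contig <- grepl("^[0-9]+$", first) &
      vapply(recs, length, 1L) >= 4L
    ctab <- recs[is_contig]
    idx_name <- vapply(ctab, `[`, "", 2L)
    names(idx_name) <- vapply(ctab, `[`, "", 1L)
    idx_len <- as.integer(vapply(ctab, `[`, "", 3L))
    idx_cov <- suppressWarnings(as.numeric(vapply(ctab, `[`, "", 4L)))
    names(idx_len) <- names(idx_cov) <- names(idx_name)
    is_edge <- first == "C"
    eidx <- which(is_edge)
    etab <- recs[is_edge]
    if (any(vapply(etab, length, 1L) != 5L))
      stop("malformed C edge record at line ",
           eidx[vapply(etab, length, 1L) != 5L][1], " in ", path)
    resolve <- function(tok) {
      # edges reference contigs by numeric index; map to record name
      unname(ifelse(tok %in% names(idx_name), idx_name[tok], tok))
    }
    edges <- data.frame(
      id1 = resolve(vapply(etab, `[`, "", 2L)),
      end1 = vapply(etab, `[`, "", 3L),
      id2 = resolve(vapply(etab, `[`, "", 4L)),
      end2 = vapply(etab, `[`, "", 5L), stringsAsFactors = FALSE)
    bad_end <- !(edges$end1 %in% c("5'", "3'")) | !(edges$end2 %in% c("5'", "3'"))
    if (any(bad_end)) stop("edge end token not in {3',5'} at line ", eidx[bad_end][1])
    # synthesize contigs known to the graph file but missing from the FASTA
    missing <- setdiff(unique(c(edges$id1, edges$id2)), contigs$id)
    if (length(missing)) {
      warning("contig(s) in graph but not in FASTA, adding length-only entries: ",
              paste(missing, collapse = ", "))
      ml <- idx_len[match(missing, idx_name)]
      mc <- idx_cov[match(missing, idx_name)]
      ml[is.na(ml)] <- 1L
      add <- contig_set(missing, ml, coverage = mc,
                        large_threshold = attr(contigs, "large_threshold") %||% 500L)
      contigs <- rbind_contigs(contigs, add)
    }
  }
  missing <- setdiff(unique(c(edges$id1, edges$id2)), contigs$id)
  if (dialect == "generic_tsv" && length(missing)) {
    warning("contig(s) in graph but not in FASTA, adding length-only entries: ",
            paste(missing, collapse = ", "))
    contigs <- rbind_contigs(contigs, contig_set(missing, 1L))
  }
  contig_graph(contigs, edges)
}

rbind_contigs <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("contig_set", "data.frame")
  attr(out, "large_threshold") <- attr(a, "large_threshold")
  out
}

#' Construct a restriction map
#'
#' @param fragments Ordered RF lengths in bp (each > 0).
#' @param enzyme Enzyme name (free text; digestion only needs it when a map
#'   is generated in silico).
#' @param circular Is the map circular? Fragment index arithmetic is then
#'   modulo the fragment count.
#' @return A `restriction_map` (list with `enzyme`, `circular`,
#'   `fragments`, `total_length`).
#' @export
restriction_map <- function(fragments, enzyme = "unknown", circular = FALSE) {
  fragments <- as.numeric(fragments)
  if (length(fragments) == 0L || any(!is.finite(fragments)) || any(fragments <= 0))
    stop("RF lengths must all be > 0")
  structure(list(enzyme = as.character(enzyme), circular = isTRUE(circular),
                 fragments = fragments, total_length = sum(fragments)),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat(sprintf("<restriction_map> %s, %s, %d RFs, total %.0f bp\n", x$enzyme,
              if (x$circular) "circular" else "linear",
              length(x$fragments), x$total_length))
  invisible(x)
}

#' Read an optical map
#'
#' `internal` dialect: first line `<enzyme>\t<circular|linear>`, then one
#' integer RF length (bp) per line; `#` comments skipped. `opgen` dialect:
#' a MapSolver-style text export (see the packaged
#' `extdata/example_mapsolver.txt`; the vendor format is not a published
#' spec, the reader targets that documented example): `Enzyme:` and
#' `Orientation:` header fields, then numbered fragment rows with sizes in
#' Kb, converted to bp on read.
#'
#' @param path Map file.
#' @param dialect `"internal"` or `"opgen"`.
#' @return A [restriction_map()].
#' @export
read_optical_map <- function(path, dialect = c("internal", "opgen")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "internal") {
    lines <- lines[!grepl("^#", lines)]
    if (length(lines) < 2L) stop("internal map file needs a header and >= 1 RF line")
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(hdr) != 2L || !(hdr[2] %in% c("circular", "linear")))
      stop("bad internal map header (expected '<enzyme>\\t<circular|linear>'): ", lines[1])
    frags <- suppressWarnings(as.numeric(lines[-1]))
    if (any(is.na(frags))) stop("non-numeric RF length at data line ",
                                which(is.na(frags))[1])
    if (any(frags <= 0)) stop("RF length <= 0 at data line ", which(frags <= 0)[1])
    if (!(hdr[1] %in% names(builtin_enzymes())))
      warning("unknown enzyme name '", hdr[1],
              "' (only needed for in-silico digestion)")
    restriction_map(frags, enzyme = hdr[1], circular = hdr[2] == "circular")
  } else {
    enz <- sub("^Enzyme:\\s*", "", grep("^Enzyme:", lines, value = TRUE)[1])
    ori <- sub("^Orientation:\\s*", "", grep("^Orientation:", lines, value = TRUE)[1])
    if (is.na(enz)) stop("MapSolver export lacks an 'Enzyme:' line")
    rows <- grep("^[0-9]+\\s", lines, value = TRUE)
    if (!length(rows)) stop("MapSolver export lacks fragment rows")
    kb <- as.numeric(vapply(strsplit(rows, "\\s+"), `[`, "", 2L))
    if (any(is.na(kb))) stop("non-numeric fragment size in MapSolver export")
    frags <- round(kb * 1000)
    if (any(frags <= 0)) stop("RF length <= 0 after Kb conversion")
    restriction_map(frags, enzyme = enz,
                    circular = isTRUE(tolower(ori) == "circular"))
  }
}

#' Write an optical map in the internal dialect
#'
#' @param map A [restriction_map()].
#' @param path Output file.
#' @export
write_optical_map <- function(map, path) {
  stopifnot(inherits(map, "restriction_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(map$enzyme, if (map$circular) "circular" else "linear",
                   sep = "\t"), con)
  writeLines(format(map$fragments, scientific = FALSE, trim = TRUE), con)
  invisible(path)
}

report_columns <- c("neighboring_contigs", "gap_size_bp", "best_contig_path",
                    "path_length_bp", "length_difference_bp", "status")

#' Write the gap-closure report
#'
#' One row per closed gap, in the tabular layout
#' `left+right | rescaled gap size | best path | path length | |difference| |
#' status`. Ambiguous gaps carry no row here; their full surviving candidate
#' lists go to the intermediate file written by [write_candidate_paths()].
#'
#' @param closures List of closure records from [select_best()].
#' @param path Output TSV.
#' @export
write_report <- function(closures, path) {
  rows <- lapply(closures, function(cl) {
    if (!identical(cl$status, "closed")) return(NULL)
    data.frame(
      neighboring_contigs = paste0(cl$gap$left$id, cl$gap$left$strand, ",",
                                   cl$gap$right$id, cl$gap$right$strand),
      gap_size_bp = cl$gap$rescaled_size,
      best_contig_path = format_contig_path(cl$best_path),
      path_length_bp = cl$final_length,
      length_difference_bp = cl$length_difference,
      status = cl$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(report_columns)),
                                  report_columns))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ambiguous candidate paths to the intermediate file
#'
#' Every surviving candidate of every ambiguous gap, one row per candidate.
#'
#' @param closures List of closure records.
#' @param path Output TSV.
#' @export
write_candidate_paths <- function(closures, path) {
  rows <- lapply(closures, function(cl) {
    if (!identical(cl$status, "ambiguous")) return(NULL)
    do.call(rbind, lapply(cl$ranked, function(r) data.frame(
      neighboring_contigs = paste0(cl$gap$left$id, cl$gap$left$strand, ",",
                                   cl$gap$right$id, cl$gap$right$strand),
      gap_size_bp = cl$gap$rescaled_size,
      candidate_path = format_contig_path(r$members),
      path_length_bp = r$final_length,
      length_difference_bp = r$diff, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    cols <- c("neighboring_contigs", "gap_size_bp", "candidate_path",
              "path_length_bp", "length_difference_bp")
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
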