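#' Pipeline parameters
#'
#' Houses every numeric threshold of the four-step workflow.
#'
#' @param large_threshold Large-contig length threshold, bp (default 500).
#' @param min_rf_for_fit Rescaling block cutoff, bp (default 10000).
#' @param rf_floor Minimum credited map RF, bp (default 2000).
#' @param length_slack Path-search length bound multiplier (default 1.2).
#' @param ambiguity_cutoff Minimum separation of the two best path lengths,
#'   bp (default 2000).
#' @param match_tolerance Maximum |path length - gap size| for closure, bp
#'   (default 2000).
#' @param junction_overlap bp trimmed per junction when stitching (0 for
#'   Newbler-style graphs; k-1 for k-mer graph dialects).
#' @param include_nonunique Also place non-uniquely aligned contigs
#'   (default FALSE: unique placements are far more reliable).
#' @param align [align_params()] for the built-in aligner.
#' @param max_paths,max_steps Search safety valves.
#' @param robust_rescale Median instead of mean rescaling factor
#'   (default FALSE).
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(large_threshold = 500L, min_rf_for_fit = 10000,
                            rf_floor = 2000, length_slack = 1.2,
                            ambiguity_cutoff = 2000, match_tolerance = 2000,
                            junction_overlap = 0, include_nonunique = FALSE,
                            align = align_params(), max_paths = 10000L,
                            max_steps = 1e6, robust_rescale = FALSE) {
  structure(list(large_threshold = as.integer(large_threshold),
                 min_rf_for_fit = min_rf_for_fit, rf_floor = rf_floor,
                 length_slack = length_slack,
                 ambiguity_cutoff = ambiguity_cutoff,
                 match_tolerance = match_tolerance,
                 junction_overlap = junction_overlap,
                 include_nonunique = include_nonunique,
                 align = align, max_paths = as.integer(max_paths),
                 max_steps = max_steps, robust_rescale = robust_rescale),
            class = "pipeline_params")
}

as_search_params <- function(p) {
  search_params(length_slack = p$length_slack, rf_floor = p$rf_floor,
                ambiguity_cutoff = p$ambiguity_cutoff,
                match_tolerance = p$match_tolerance,
                max_paths = p$max_paths, max_steps = p$max_steps)
}

#' Run the four-step gap-closing workflow
#'
#' 1) place contigs on the optical map (built-in RF aligner, or an imported
#' placement table), 2) rescale the map from 1-vs-1 RF blocks, 3) search the
#' contig graph for length-admissible candidate paths across every gap
#' between neighbouring placed contigs, 4) pick the best path per gap,
#' stitch its sequence, and report. Deterministic: identical inputs give
#' byte-identical reports.
#'
#' @param contigs A [contig_set()] with sequences.
#' @param graph A [contig_graph()].
#' @param map A [restriction_map()].
#' @param placements Optional pre-computed placements
#'   ([read_placements()]); when NULL the built-in aligner places every
#'   large contig with enough internal RFs.
#' @param params [pipeline_params()].
#' @param out_dir Optional output directory: writes `report.tsv`,
#'   `ambiguous_candidates.tsv`, `closed_sequences.fasta`,
#'   `rescale_blocks.tsv`, `manifest.txt`.
#' @return List of class `om_run`: `placements`, `model`, `gaps`,
#'   `closures`, `stitched` (named by path notation), `stats_before`,
#'   `stats_after`, `report` (data.frame of every gap with status).
#' @export
run_pipeline <- function(contigs, graph, map, placements = NULL,
                         params = pipeline_params(), out_dir = NULL) {
  seqs <- stats::setNames(contigs$sequence, contigs$id)
  have_seq <- !is.na(seqs)
  digests <- lapply(stats::setNames(contigs$id[have_seq], contigs$id[have_seq]),
                    function(id) digest_sequence(seqs[[id]], map$enzyme, id))

  if (is.null(placements)) {
    align_all <- function(ap, hint) {
      pl <- list()
      for (id in contigs$id[contigs$is_large & have_seq])
        pl <- c(pl, align_contig(digests[[id]], map, ap, scale_hint = hint))
      classify_uniqueness(pl, ap)
    }
    # pass 1 at a widened tolerance (the global map scale is still unknown),
    # then re-align with the scale implied by the pass-1 1-vs-1 blocks
    coarse <- params$align
    coarse$sizing_tolerance <- 2 * params$align$sizing_tolerance
    placements <- align_all(coarse, 1)
    b1 <- collect_blocks(Filter(function(p) isTRUE(p$unique), placements),
                         digests, map)
    hint <- suppressWarnings(
      fit_factor(b1, params$min_rf_for_fit, robust = TRUE)$factor)
    placements <- align_all(params$align, hint)
  }

  uniq <- Filter(function(p) isTRUE(p$unique), placements)
  unique_ids <- unique(vapply(uniq, `[[`, "", "contig_id"))
  gaps <- build_gaps(placements, map, digests,
                     include_nonunique = params$include_nonunique,
                     rf_floor = params$rf_floor)

  blocks <- collect_blocks(uniq, digests, map)
  model <- fit_factor(blocks, params$min_rf_for_fit,
                      robust = params$robust_rescale)
  for (i in seq_along(gaps))
    gaps[[i]]$rescaled_size <- rescale_gap(gaps[[i]]$raw_size, model)

  sp <- as_search_params(params)
  closures <- lapply(gaps, function(gap) {
    if (!is.finite(gap$left_tail) || !is.finite(gap$right_head)) {
      return(list(gap = gap, status = "flank_without_site", best_path = NULL,
                  final_length = NA_real_, length_difference = NA_real_,
                  runner_up_margin = NA_real_, candidates_considered = 0L,
                  ranked = list()))
    }
    found <- find_paths(graph, gap$left, gap$right, gap, unique_ids, sp,
                        junction_overlap = params$junction_overlap)
    if (found$overflow) {
      return(list(gap = gap, status = "search_overflow", best_path = NULL,
                  final_length = NA_real_, length_difference = NA_real_,
                  runner_up_margin = NA_real_,
                  candidates_considered = length(found$candidates),
                  ranked = list()))
    }
    select_best(found$candidates, gap, sp,
                junction_overlap = params$junction_overlap)
  })

  stitched <- character(0)
  for (cl in closures) {
    if (!identical(cl$status, "closed")) next
    if (!all(cl$best_path$id %in% names(seqs)[have_seq])) next
    stitched[[format_contig_path(cl$best_path)]] <-
      stitch_path(cl$best_path, seqs, params$junction_overlap)
  }

  large_lens <- contigs$length[contigs$is_large]
  stats_before <- assembly_stats(large_lens)
  stats_after <- assembly_stats(merged_lengths(contigs, closures, digests,
                                               params$junction_overlap))

  report <- do.call(rbind, lapply(closures, function(cl) data.frame(
    neighboring_contigs = paste0(cl$gap$left$id, cl$gap$left$strand, ",",
                                 cl$gap$right$id, cl$gap$right$strand),
    gap_size_bp = cl$gap$rescaled_size,
    best_contig_path = if (is.null(cl$best_path)) ""
                       else format_contig_path(cl$best_path),
    path_length_bp = cl$final_length,
    length_difference_bp = cl$length_difference,
    status = cl$status, stringsAsFactors = FALSE)))

  run <- structure(list(placements = placements, model = model, gaps = gaps,
                        closures = closures, stitched = stitched,
                        stats_before = stats_before, stats_after = stats_after,
                        report = report, params = params),
                   class = "om_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# post-closure contig lengths: chains of neighbouring placements whose gaps
# closed melt into one super-contig; members consumed inside closed paths
# are flagged as used, and remaining large contigs keep their own entry
merged_lengths <- function(contigs, closures, digests, junction_overlap) {
  closed <- Filter(function(cl) identical(cl$status, "closed"), closures)
  if (!length(closed)) return(contigs$length[contigs$is_large])
  succ <- list()
  for (cl in closed) {
    succ[[paste0(cl$gap$left$id, cl$gap$left$strand)]] <- cl
  }
  used <- character(0)
  chain_lens <- numeric(0)
  starts <- setdiff(names(succ), vapply(closed, function(cl)
    paste0(cl$gap$right$id, cl$gap$right$strand), ""))
  if (!length(starts)) starts <- names(succ)[1]   # fully circular closure
  for (st in starts) {
    members <- NULL
    key <- st
    repeat {
      cl <- succ[[key]]
      if (is.null(cl)) break
      add <- cl$best_path
      members <- if (is.null(members)) add else rbind(members, add[-1, ])
      succ[[key]] <- NULL
      key <- paste0(cl$gap$right$id, cl$gap$right$strand)
      if (key == st) break
    }
    if (is.null(members)) next
    used <- union(used, members$id)
    lens <- contigs$length[match(members$id, contigs$id)]
    chain_lens <- c(chain_lens,
                    sum(lens) - junction_overlap * (nrow(members) - 1L))
  }
  rest <- contigs$is_large & !(contigs$id %in% used)
  c(chain_lens, contigs$length[rest])
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(run$closures, file.path(out_dir, "report.tsv"))
  write_candidate_paths(run$closures,
                        file.path(out_dir, "ambiguous_candidates.tsv"))
  if (length(run$stitched))
    write_fasta(names(run$stitched), unname(unlist(run$stitched)),
                file.path(out_dir, "closed_sequences.fasta"))
  write_rescale_diagnostics(run$model, file.path(out_dir, "rescale_blocks.tsv"))
  p <- run$params
  manifest <- c(
    sprintf("omconnect %s", as.character(utils::packageVersion("omconnect"))),
    sprintf("rescale_factor\t%.6f", run$model$factor),
    sprintf("blocks_used\t%d", run$model$n_blocks_used),
    sprintf("gaps\t%d", length(run$gaps)),
    sprintf("closed\t%d", sum(vapply(run$closures, function(cl)
      identical(cl$status, "closed"), NA))),
    sprintf("n50_before\t%.0f", run$stats_before$n50_bp),
    sprintf("n50_after\t%.0f", run$stats_after$n50_bp),
    vapply(setdiff(names(p), "align"), function(k)
      sprintf("param %s\t%s", k, paste(format(p[[k]]), collapse = ",")), ""))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.om_run <- function(x, ...) {
  st <- table(vapply(x$closures, `[[`, "", "status"))
  cat(sprintf("<om_run> %d gap(s); %s | rescale factor %.4f | N50 %d -> %d bp\n",
              length(x$gaps),
              paste(names(st), as.integer(st), sep = "=", collapse = " "),
              x$model$factor, as.integer(x$stats_before$n50_bp),
              as.integer(x$stats_after$n50_bp)))
  invisible(x)
}
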