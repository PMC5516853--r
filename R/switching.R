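#' Consensus ternary state of a stage
#'
#' Aggregates replicate states per gene by the sign of the replicate mean
#' (`sign(0)` gives 0, i.e. no consensus). A singleton stage returns that
#' sample's states verbatim.
#'
#' @param states integer genes x samples ternary matrix.
#' @param ann a [stage_annotation()].
#' @param stage a stage label present in `ann`.
#' @return named integer vector in `{-1, 0, +1}` of length n genes.
#' @export
stage_consensus <- function(states, ann, stage) {
  if (!stage %in% levels(ann$stage)) {
    stop("unknown stage label: ", stage, call. = FALSE)
  }
  ids <- samples_of(ann, stage)
  if (length(ids) == 0) stop("stage has no samples: ", stage, call. = FALSE)
  m <- rowMeans(states[, ids, drop = FALSE])
  out <- as.integer(sign(m))
  names(out) <- rownames(states)
  out
}

#' Detect genes switching state between stages
#'
#' A switched gene is a candidate driver of a cell-state transition: its
#' consensus state is `-1` in one stage and `+1` in the other (the strict
#' rule; transitions through 0 are excluded). With `lenient = TRUE` any
#' change of consensus state is reported, including `0 <-> +/-1` -- a
#' broader rule offered for exploration.
#'
#' @param states integer genes x samples ternary matrix.
#' @param ann a [stage_annotation()].
#' @param pairs `"successive"` (default: consecutive stages in the
#'   developmental order), `"all_pairs"`, or a list of length-2 character
#'   vectors of stage labels.
#' @param lenient also report `0 <-> +/-1` changes.
#' @return a `switch_report`: list with `transitions` (data frame:
#'   stage_a, stage_b, n_switched), `switches` (one data frame per
#'   transition: gene_id, state_a, state_b, direction `"up"` = -1 -> +1 /
#'   `"down"` = +1 -> -1), and the consensus matrix.
#' @export
detect_switches <- function(states, ann, pairs = "successive",
                            lenient = FALSE) {
  validate_annotation(ann, states)
  stages <- stage_order(ann)
  if (length(stages) < 2) stop("need >=2 stages", call. = FALSE)
  pair_list <- resolve_pairs(pairs, stages)
  cons <- vapply(stages, function(sg) stage_consensus(states, ann, sg),
                 integer(nrow(states)))
  rownames(cons) <- rownames(states)

  switches <- lapply(pair_list, function(pr) {
    a <- cons[, pr[1]]
    b <- cons[, pr[2]]
    hit <- if (lenient) which(a != b) else which(a * b == -1L)
    data.frame(gene_id = rownames(cons)[hit],
               state_a = unname(a[hit]), state_b = unname(b[hit]),
               direction = ifelse(b[hit] > a[hit], "up", "down"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(switches) <- vapply(pair_list, paste, character(1), collapse = "->")
  transitions <- data.frame(
    stage_a = vapply(pair_list, `[`, character(1), 1),
    stage_b = vapply(pair_list, `[`, character(1), 2),
    n_switched = vapply(switches, nrow, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(transitions = transitions, switches = switches,
                 consensus = cons, lenient = lenient),
            class = "switch_report")
}

resolve_pairs <- function(pairs, stages) {
  if (is.character(pairs) && length(pairs) == 1 &&
      pairs %in% c("successive", "all_pairs")) {
    if (pairs == "successive") {
      return(lapply(seq_len(length(stages) - 1),
                    function(i) stages[c(i, i + 1)]))
    }
    cmb <- utils::combn(stages, 2)
    return(lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  if (!is.list(pairs)) pairs <- list(pairs)
  lapply(pairs, function(pr) {
    pr <- as.character(pr)
    if (length(pr) != 2) {
      stop("each custom pair must have exactly 2 stage labels",
           call. = FALSE)
    }
    unknown <- setdiff(pr, stages)
    if (length(unknown)) {
      stop("unknown stage label(s) in custom pair: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    pr
  })
}

#' @export
print.switch_report <- function(x, ...) {
  cat(sprintf("Switch report (%s rule):\n",
              if (x$lenient) "lenient" else "strict -1 <-> +1"))
  print(x$transitions, row.names = FALSE)
  invisible(x)
}

#' Write a switch report (one TSV per transition plus a JSON count summary)
#'
#' @param report a `switch_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the per-transition tables.
#' @return invisibly, the paths written.
#' @export
write_switch_report <- function(report, dir, prefix = "switches") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report$switches)) {
    safe <- gsub("[^A-Za-z0-9._-]+", "_", sub("->", "-", nm, fixed = TRUE))
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, safe))
    utils::write.table(report$switches[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, sprintf("%s_counts.json", prefix))
  jsonlite::write_json(list(rule = if (report$lenient) "lenient" else "strict",
                            transitions = report$transitions),
                       jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
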