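#' Construct a stranded 5'-read-start count track
#'
#' A sparse per-position, per-orientation count of mapped 5' read ends
#' (Cappable-seq-style), together with the library's total mapped read count
#' N used for reads-per-million normalization. Positions absent from the
#' sparse map carry an implicit count of zero; N may exceed the sum of the
#' sparse counts because it counts all mapped reads of the library.
#'
#' @param counts data.frame with columns `pos` (1-based bp), `strand`
#'   (`"+"`/`"-"`) and `count` (integer >= 0). Zero-count rows are dropped.
#' @param N total mapped reads of the library (> 0).
#' @param replicon_id replicon name.
#' @param length replicon length in bp.
#' @param condition,replicate experiment labels.
#' @return Object of class `read_start_track`.
#' @export
read_start_track <- function(counts, N, replicon_id = "replicon",
                             length = NA_integer_, condition = NA_character_,
                             replicate = NA_integer_) {
  if (!all(c("pos", "strand", "count") %in% names(counts))) {
    stop("counts needs columns 'pos', 'strand', 'count'", call. = FALSE)
  }
  if (!all(counts$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(counts$count < 0)) stop("counts must be >= 0", call. = FALSE)
  stopifnot_scalar_number(N, "N", positive = TRUE)
  counts <- counts[counts$count > 0, , drop = FALSE]
  if (sum(counts$count) > N) {
    stop("sum of counts exceeds total mapped reads N", call. = FALSE)
  }
  structure(list(counts = counts[order(counts$strand, counts$pos), ,
                                 drop = FALSE],
                 N = N, replicon_id = replicon_id, length = length,
                 condition = condition, replicate = replicate),
            class = "read_start_track")
}

#' @export
print.read_start_track <- function(x, ...) {
  cat(sprintf("read_start_track: %s (%s bp), %d positions, N = %g [%s, rep %s]\n",
              x$replicon_id, format(x$length), nrow(x$counts), x$N,
              x$condition, x$replicate))
  invisible(x)
}

#' Reads-per-million normalization of a read-start track
#'
#' Scales each per-position, per-orientation count to a reads-per-million
#' score, \eqn{RRS_{io} = (n_{io} / N) \times 10^6}, making tracks of
#' different sequencing depth comparable.
#'
#' @param track a `read_start_track`.
#' @return Object of class `rrs_track`: same sparse layout with an `rrs`
#'   column added to `counts`.
#' @export
compute_rrs <- function(track) {
  if (!inherits(track, "read_start_track")) {
    stop("'track' must be a read_start_track", call. = FALSE)
  }
  track$counts$rrs <- track$counts$count / track$N * 1e6
  class(track) <- c("rrs_track", "read_start_track")
  track
}

#' Candidate TSS positions above an RRS cutoff
#'
#' Retains all positions/orientations with an RRS at or above the cutoff
#' (default 5 reads per million), applied per orientation independently.
#'
#' @param rrs an `rrs_track` from [compute_rrs()].
#' @param cutoff minimum RRS (> 0); positions with `rrs >= cutoff` are kept.
#' @return data.frame with columns `pos`, `strand`, `count`, `rrs`.
#' @export
candidate_positions <- function(rrs, cutoff = 5) {
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (!inherits(rrs, "rrs_track")) {
    stop("'rrs' must be an rrs_track; run compute_rrs() first", call. = FALSE)
  }
  rrs$counts[rrs$counts$rrs >= cutoff, , drop = FALSE]
}

#' Cluster candidate positions into TSS peaks
#'
#' Single-linkage grouping of same-orientation candidates: two candidates
#' belong to the same cluster when they are at most `cluster_value` bp apart
#' (the cluster value defines the up- and downstream clustering window). The
#' cluster representative is the position of maximal RRS; ties go to the
#' 5'-most position relative to the orientation (smallest coordinate on `+`,
#' largest on `-`).
#'
#' @param candidates data.frame from [candidate_positions()].
#' @param cluster_value clustering distance in bp (default 5).
#' @return data.frame with one row per cluster: `strand`, `position`
#'   (representative), `span_min`, `span_max`, `rrs` (representative's RRS),
#'   `n_candidates`.
#' @export
cluster_candidates <- function(candidates, cluster_value = 5) {
  out <- list()
  for (s in c("+", "-")) {
    cand <- candidates[candidates$strand == s, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[order(cand$pos), , drop = FALSE]
    gap <- c(0, diff(cand$pos))
    cluster_id <- cumsum(gap > cluster_value)
    for (id in unique(cluster_id)) {
      cl <- cand[cluster_id == id, , drop = FALSE]
      top <- cl[cl$rrs == max(cl$rrs), , drop = FALSE]
      rep_pos <- if (s == "+") min(top$pos) else max(top$pos)
      out[[length(out) + 1L]] <- data.frame(
        strand = s, position = rep_pos,
        span_min = min(cl$pos), span_max = max(cl$pos),
        rrs = max(cl$rrs), n_candidates = nrow(cl),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(strand = character(), position = integer(),
                      span_min = integer(), span_max = integer(),
                      rrs = numeric(), n_candidates = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$position), , drop = FALSE]
}

#' Cross-replicate matching of clustered TSS candidates
#'
#' Matches cluster representatives across biological replicates: same
#' orientation, positions within `match_dist` bp (single linkage across the
#' pooled representatives). With `require_all = TRUE` (default) only TSSs
#' present in every replicate are reported — the reproducibility filter.
#' Each call carries the per-replicate RRS (maximum over a replicate's
#' matched clusters) and their mean; the call position is the representative
#' with the highest RRS overall, ties going 5'-most.
#'
#' @param per_replicate_clusters list of cluster data.frames from
#'   [cluster_candidates()], one per replicate.
#' @param require_all keep only TSSs found in all replicates (default TRUE).
#' @param match_dist matching radius in bp (default 5).
#' @return data.frame of class `tss_calls`: `strand`, `position`,
#'   `span_min`, `span_max`, `label` (TSS_<position>+<span offset>),
#'   `n_replicates`, one `rrs_rep<i>` column per replicate (NA where
#'   absent), `mean_rrs`.
#' @export
reproducible_tss <- function(per_replicate_clusters, require_all = TRUE,
                             match_dist = 5) {
  k <- length(per_replicate_clusters)
  if (k < 1L) stop("need at least one replicate", call. = FALSE)
  pooled <- do.call(rbind, lapply(seq_len(k), function(i) {
    cl <- per_replicate_clusters[[i]]
    if (nrow(cl) == 0L) return(NULL)
    cbind(cl, rep_idx = i)
  }))
  empty <- tss_calls_frame(k)
  if (is.null(pooled) || nrow(pooled) == 0L) return(empty)
  out <- list()
  for (s in c("+", "-")) {
    grp <- pooled[pooled$strand == s, , drop = FALSE]
    if (nrow(grp) == 0L) next
    grp <- grp[order(grp$position), , drop = FALSE]
    gid <- cumsum(c(0, diff(grp$position)) > match_dist)
    for (id in unique(gid)) {
      g <- grp[gid == id, , drop = FALSE]
      reps_present <- sort(unique(g$rep_idx))
      if (require_all && length(reps_present) < k) next
      rrs_by_rep <- rep(NA_real_, k)
      for (i in reps_present) {
        rrs_by_rep[i] <- max(g$rrs[g$rep_idx == i])
      }
      top <- g[g$rrs == max(g$rrs), , drop = FALSE]
      pos <- if (s == "+") min(top$position) else max(top$position)
      row <- data.frame(strand = s, position = pos,
                        span_min = min(g$span_min), span_max = max(g$span_max),
                        n_replicates = length(reps_present),
                        stringsAsFactors = FALSE)
      row$label <- sprintf("TSS_%d+%d", pos, row$span_max - row$span_min)
      for (i in seq_len(k)) row[[paste0("rrs_rep", i)]] <- rrs_by_rep[i]
      row$mean_rrs <- mean(rrs_by_rep, na.rm = TRUE)
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$strand, res$position), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tss_calls", "data.frame")
  res
}

tss_calls_frame <- function(k) {
  res <- data.frame(strand = character(), position = integer(),
                    span_min = integer(), span_max = integer(),
                    n_replicates = integer(), label = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) res[[paste0("rrs_rep", i)]] <- numeric()
  res$mean_rrs <- numeric()
  class(res) <- c("tss_calls", "data.frame")
  res
}

#' Score TSS calls against a control and apply the score threshold
#'
#' The score of a TSS is its mean RRS divided by the mean control RRS at the
#' same site; when control coverage is absent or too sparse to normalize
#' against (the common case for Cappable-seq controls), the score is simply
#' the mean RRS. A `pseudo_floor` on the control mean (default 1 RRS unit)
#' prevents division by near-zero control values. A call passes when its
#' score reaches `score_min` (default 10).
#'
#' @param calls a `tss_calls` data.frame from [reproducible_tss()].
#' @param control optional numeric vector of mean control RRS per call
#'   (same order as `calls`), or NULL to score without a control.
#' @param pseudo_floor lower bound applied to the control mean.
#' @param score_min minimum score for a call to pass (default 10).
#' @return `calls` with `score` and `passed` columns appended.
#' @export
score_tss <- function(calls, control = NULL, pseudo_floor = 1,
                      score_min = 10) {
  if (any(calls$mean_rrs < 0)) stop("mean RRS must be >= 0", call. = FALSE)
  if (is.null(control)) {
    calls$score <- calls$mean_rrs
  } else {
    if (length(control) != nrow(calls) || any(control < 0)) {
      stop("'control' must be a non-negative vector, one value per call",
           call. = FALSE)
    }
    calls$score <- calls$mean_rrs / pmax(control, pseudo_floor)
  }
  calls$passed <- calls$score >= score_min
  calls
}

#' Fold change of a TSS score between two conditions
#'
#' Ratio of mean scores (e.g. metal-challenged over nonchallenged), with the
#' distance statistic [d_statistic()] deciding significance. Folds of 10 and
#' above are rounded to the nearest integer for reporting, smaller folds to
#' two decimals.
#'
#' @param scores_a,scores_b `measured_value` objects holding mean, deviation
#'   and replicate count of the scores in each condition.
#' @param pseudo_floor lower bound on the denominator mean.
#' @return list with `fold`, `fold_rounded`, `d`, `significant`,
#'   `significance_label`.
#' @examples
#' condition_fold_change(measured_value(60069, 10166, 3),
#'                       measured_value(232, 42, 3))
#' @export
condition_fold_change <- function(scores_a, scores_b, pseudo_floor = 1) {
  if (scores_a$mean < 0) stop("mean scores must be >= 0", call. = FALSE)
  fold <- scores_a$mean / max(scores_b$mean, pseudo_floor)
  d <- d_statistic(scores_a, scores_b)
  list(fold = fold,
       fold_rounded = if (fold >= 10) round(fold) else round(fold, 2),
       d = d$d, significant = d$d > 1,
       significance_label = d$significance_label)
}

#' End-to-end TSS calling on replicated read-start tracks
#'
#' Runs the full caller: reads-per-million normalization per replicate,
#' cutoff filtering, per-replicate clustering, cross-replicate matching and
#' scoring.
#'
#' @param tracks list of `read_start_track` objects, one per biological
#'   replicate of the same condition.
#' @param cutoff RRS cutoff (default 5).
#' @param cluster_value clustering distance in bp (default 5).
#' @param match_dist cross-replicate matching radius in bp (default 5).
#' @param require_all require presence in all replicates (default TRUE).
#' @param control optional per-call control RRS, see [score_tss()].
#' @param pseudo_floor,score_min see [score_tss()].
#' @return `tss_calls` data.frame with scores and pass flags.
#' @export
call_tss <- function(tracks, cutoff = 5, cluster_value = 5, match_dist = 5,
                     require_all = TRUE, control = NULL, pseudo_floor = 1,
                     score_min = 10) {
  clusters <- lapply(tracks, function(tr) {
    cluster_candidates(candidate_positions(compute_rrs(tr), cutoff),
                       cluster_value)
  })
  calls <- reproducible_tss(clusters, require_all = require_all,
                            match_dist = match_dist)
  score_tss(calls, control = control, pseudo_floor = pseudo_floor,
            score_min = score_min)
}

#' Extract the promoter window around a TSS
#'
#' Returns the genomic window from `upstream` bp before to `downstream` bp
#' after the TSS (defaults 290 and 110), orientation-aware: on the `-`
#' strand the mirror-image window is taken and reverse-complemented, so the
#' returned sequence always reads 5' to 3' of the transcript. Windows
#' extending past the end of a linear replicon are truncated with a warning;
#' on a circular replicon they wrap around.
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector)
#'   holding the replicon sequence(s).
#' @param position TSS position, 1-based.
#' @param strand `"+"` or `"-"`.
#' @param replicon_id name of the replicon in `genome` (default: first).
#' @param upstream,downstream window extent in bp.
#' @param circular treat the replicon as circular (default FALSE).
#' @return list with `sequence` (a [Biostrings::DNAString]), `window`
#'   (start/end on the reference strand, 1-based inclusive, before any
#'   wrap), `strand`, `replicon_id`.
#' @export
extract_promoter <- function(genome, position, strand,
                             replicon_id = NULL, upstream = 290,
                             downstream = 110, circular = FALSE) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(replicon_id)) replicon_id <- names(genome)[1] %||% 1L
  seq <- genome[[replicon_id]]
  len <- length(seq)
  win <- if (strand == "+") {
    c(position - upstream, position + downstream)
  } else {
    c(position - downstream, position + upstream)
  }
  idx <- win[1]:win[2]
  if (circular) {
    idx <- ((idx - 1L) %% len) + 1L
  } else if (win[1] < 1 || win[2] > len) {
    warning("promoter window [", win[1], ", ", win[2],
            "] truncated at the ends of linear replicon ", replicon_id,
            call. = FALSE)
    idx <- idx[idx >= 1 & idx <= len]
  }
  s <- seq[idx]
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  list(sequence = s, window = win, strand = strand,
       replicon_id = as.character(replicon_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write promoter windows for a set of TSS calls as FASTA
#'
#' @param genome see [extract_promoter()].
#' @param calls `tss_calls` data.frame.
#' @param file output FASTA path.
#' @param replicon_id replicon the calls refer to.
#' @param upstream,downstream,circular see [extract_promoter()].
#' @return `file`, invisibly.
#' @export
write_promoters <- function(genome, calls, file, replicon_id = NULL,
                            upstream = 290, downstream = 110,
                            circular = FALSE) {
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(calls)), function(i) {
    extract_promoter(genome, calls$position[i], calls$strand[i],
                     replicon_id, upstream, downstream, circular)$sequence
  }))
  names(seqs) <- sprintf("%s|%s|pos=%d", calls$label, calls$strand,
                         calls$position)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Read a per-replicate read-start track from delimited text
#'
#' Two dialects: `"tsv"` with 1-based columns `replicon`, `pos`, `strand`,
#' `count`, or BED-like `"bed"` with 0-based half-open `chrom`, `start`,
#' `end`, `name`, `count`, `strand` (start is converted to a 1-based
#' position at this boundary). The total mapped read count N is taken from a
#' `# N=<int>` comment on the first line, unless given explicitly.
#'
#' @param file input path.
#' @param N total mapped reads; overrides any header value.
#' @param format `"tsv"` or `"bed"`.
#' @param condition,replicate labels attached to the track.
#' @param replicon_length replicon length in bp (optional).
#' @return A `read_start_track`.
#' @export
read_read_starts <- function(file, N = NULL, format = c("tsv", "bed"),
                             condition = NA_character_,
                             replicate = NA_integer_,
                             replicon_length = NA_integer_) {
  format <- match.arg(format)
  first <- readLines(file, n = 1L)
  if (is.null(N)) {
    m <- regmatches(first, regexec("^#\\s*N\\s*=\\s*([0-9]+)", first))[[1]]
    if (length(m) == 2L) N <- as.numeric(m[2])
    else stop("no 'N' given and no '# N=<int>' header in ", file,
              call. = FALSE)
  }
  tab <- read.delim(file, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (format == "tsv") {
    counts <- data.frame(pos = tab[[2]], strand = tab[[3]], count = tab[[4]])
    replicon <- tab[[1]][1]
  } else {
    counts <- data.frame(pos = tab[[2]] + 1L, strand = tab[[6]],
                         count = tab[[5]])
    replicon <- tab[[1]][1]
  }
  read_start_track(counts, N = N, replicon_id = replicon,
                   length = replicon_length, condition = condition,
                   replicate = replicate)
}

#' Write a read-start track as delimited text
#'
#' Writes the sparse counts in the `"tsv"` (1-based) or `"bed"` (0-based
#' half-open) dialect understood by [read_read_starts()], with the total
#' mapped read count in a `# N=<int>` header line.
#'
#' @param track a `read_start_track`.
#' @param file output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `file`, invisibly.
#' @export
write_read_starts <- function(track, file, format = c("tsv", "bed")) {
  format <- match.arg(format)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d", as.integer(track$N)), con)
  cnt <- track$counts
  out <- if (format == "tsv") {
    data.frame(track$replicon_id, cnt$pos, cnt$strand, cnt$count)
  } else {
    data.frame(track$replicon_id, cnt$pos - 1L, cnt$pos,
               sprintf("start_%d", cnt$pos), cnt$count, cnt$strand)
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Write TSS calls as TSV
#'
#' @param calls `tss_calls` data.frame (scored or not).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tss_calls <- function(calls, file) {
  write.table(as.data.frame(calls), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
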