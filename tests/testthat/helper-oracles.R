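# Independent brute-force oracles used to cross-check the pipeline.

# Exhaustive RRS filter over a dense per-strand representation of a track:
# every position of the replicon is materialized, scaled and compared,
# independently of the package's sparse filtering path.
brute_candidates <- function(track, cutoff) {
  out <- list()
  for (s in c("+", "-")) {
    dense <- numeric(track$length)
    sel <- track$counts$strand == s
    dense[track$counts$pos[sel]] <- track$counts$count[sel]
    rrs <- dense / track$N * 1e6
    keep <- which(rrs >= cutoff)
    if (length(keep)) {
      out[[s]] <- data.frame(pos = keep, strand = s, count = dense[keep],
                             rrs = rrs[keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(pos = integer(), strand = character(),
                      count = numeric(), rrs = numeric()))
  }
  res[order(res$strand, res$pos), , drop = FALSE]
}

# Transitive closure clustering: repeatedly merge any two same-strand groups
# whose closest members are within cluster_value bp.
brute_cluster_partition <- function(candidates, cluster_value) {
  parts <- list()
  for (s in c("+", "-")) {
    pos <- sort(candidates$pos[candidates$strand == s])
    if (length(pos) == 0L) next
    groups <- as.list(pos)
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        for (j in seq_along(groups)) {
          if (i >= j) next
          if (min(abs(outer(groups[[i]], groups[[j]], "-"))) <= cluster_value) {
            groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    for (g in groups) parts[[length(parts) + 1L]] <- list(strand = s, pos = g)
  }
  parts
}

# Simple deterministic time-course fixture on an exact line.
exact_line_course <- function(a, b, times = seq(0, 180, 30)) {
  data.frame(time = times, activity = a + b * times, replicate = 1L)
}

# A track whose sparse counts account for every one of N reads.
random_full_track <- function(n_pos, seed) {
  set.seed(seed)
  pos <- sample.int(5000, n_pos)
  counts <- data.frame(pos = pos,
                       strand = sample(c("+", "-"), n_pos, replace = TRUE),
                       count = sample.int(50, n_pos, replace = TRUE))
  # collapse duplicated (pos, strand) keys
  key <- paste(counts$pos, counts$strand)
  counts <- aggregate(count ~ pos + strand, counts, sum)
  read_start_track(counts, N = sum(counts$count), length = 5000)
}
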