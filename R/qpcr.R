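#' Convert Ct values to relative transcript levels
#'
#' \eqn{level = efficiency^{-Ct}} with a per-assay amplification efficiency
#' in (1, 2]; the default 2 assumes perfect doubling per cycle.
#'
#' @param ct cycle-threshold values.
#' @param efficiency amplification efficiency per cycle, in (1, 2].
#' @return Relative transcript levels (positive reals).
#' @export
ct_to_level <- function(ct, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2)) {
    stop("'efficiency' must be in (1, 2]", call. = FALSE)
  }
  efficiency^(-ct)
}

# Mean and SD of one gene x condition cell. Nested averaging: technical
# (cDNA) replicates are averaged within each biological replicate first, then
# the biological means are averaged; the SD is taken over biological means.
condition_mean <- function(m, averaging) {
  if (anyNA(m$level) || any(m$level <= 0)) {
    stop("levels must be positive", call. = FALSE)
  }
  if (averaging == "nested" && "bio_rep" %in% names(m)) {
    bio <- tapply(m$level, m$bio_rep, mean)
    list(mean = mean(bio), sd = if (length(bio) > 1L) sd(bio) else 0)
  } else {
    list(mean = mean(m$level), sd = if (nrow(m) > 1L) sd(m$level) else 0)
  }
}

split_conditions <- function(m, what) {
  if (!all(c("condition", "level") %in% names(m))) {
    stop(what, " measurements need 'condition' and 'level' columns",
         call. = FALSE)
  }
  got <- unique(m$condition)
  if (!all(c("induced", "uninduced") %in% got)) {
    stop("incomplete design: ", what, " is missing the ",
         paste(setdiff(c("induced", "uninduced"), got), collapse = " and "),
         " condition", call. = FALSE)
  }
  list(ind = m[m$condition == "induced", , drop = FALSE],
       un = m[m$condition == "uninduced", , drop = FALSE])
}

#' Reference-normalized induction quotient for one gene
#'
#' Transcription ratio induced/uninduced for a target gene, normalized by an
#' internal-standard reference gene measured under the same conditions:
#' \deqn{Q = \frac{\bar T_{ind} / \bar R_{ind}}{\bar T_{un} / \bar R_{un}}.}
#' Means are nested by default (technical replicates within biological
#' replicate first); the deviation is first-order (delta-method) propagation
#' of the four means' dispersions, taken over biological replicates. A gene
#' is flagged induced when the quotient is at least `threshold` (default 2).
#'
#' @param target data.frame of measurements for the target gene: columns
#'   `condition` (`"induced"`/`"uninduced"`), `level` (positive relative
#'   transcript level; convert Ct values with [ct_to_level()] first),
#'   optionally `bio_rep` and `tech_rep`.
#' @param reference same layout for the reference gene.
#' @param threshold induction flag threshold on the quotient.
#' @param averaging `"nested"` (tech within bio, then bio; default) or
#'   `"flat"` (plain mean over all determinations).
#' @return Object of class `expression_quotient`: `quotient`, `dev`,
#'   `induced`.
#' @export
induction_quotient <- function(target, reference, threshold = 2,
                               averaging = c("nested", "flat")) {
  averaging <- match.arg(averaging)
  tg <- split_conditions(target, "target")
  rf <- split_conditions(reference, "reference")
  ti <- condition_mean(tg$ind, averaging); tu <- condition_mean(tg$un, averaging)
  ri <- condition_mean(rf$ind, averaging); ru <- condition_mean(rf$un, averaging)
  q <- (ti$mean / ri$mean) / (tu$mean / ru$mean)
  rel2 <- (ti$sd / ti$mean)^2 + (tu$sd / tu$mean)^2 +
    (ri$sd / ri$mean)^2 + (ru$sd / ru$mean)^2
  structure(list(quotient = q, dev = q * sqrt(rel2),
                 induced = q >= threshold),
            class = "expression_quotient")
}

#' @export
print.expression_quotient <- function(x, ...) {
  cat(sprintf("induction quotient %.3g +/- %.2g%s\n", x$quotient, x$dev,
              if (x$induced) " (induced)" else ""))
  invisible(x)
}

#' Induction quotients for all genes of a qRT-PCR table
#'
#' One reference-normalized quotient per non-reference gene, plus the
#' reference gene's own un-normalized induced/uninduced quotient (expected
#' near 1 for a stable internal standard). Quotients at or above `threshold`
#' are flagged induced.
#'
#' @param measurements data.frame with columns `gene`, `condition`
#'   (`"induced"`/`"uninduced"`), `level` (or `ct` plus optional
#'   `efficiency`, converted internally), optionally `bio_rep`, `tech_rep`.
#' @param reference_gene internal-standard gene name; default `"rpoZ"`.
#' @param threshold induction flag threshold; default 2.
#' @param averaging see [induction_quotient()].
#' @return data.frame with columns `gene`, `quotient`, `dev`, `induced`,
#'   `is_reference`.
#' @export
quotient_table <- function(measurements, reference_gene = "rpoZ",
                           threshold = 2, averaging = c("nested", "flat")) {
  averaging <- match.arg(averaging)
  if (!"level" %in% names(measurements)) {
    if (!"ct" %in% names(measurements)) {
      stop("measurements need a 'level' or 'ct' column", call. = FALSE)
    }
    eff <- if ("efficiency" %in% names(measurements)) measurements$efficiency else 2
    measurements$level <- ct_to_level(measurements$ct, eff)
  }
  if (!reference_gene %in% measurements$gene) {
    stop("reference gene '", reference_gene, "' not present in measurements",
         call. = FALSE)
  }
  ref <- measurements[measurements$gene == reference_gene, , drop = FALSE]
  genes <- setdiff(unique(measurements$gene), reference_gene)
  rows <- lapply(genes, function(g) {
    q <- induction_quotient(measurements[measurements$gene == g, , drop = FALSE],
                            ref, threshold, averaging)
    data.frame(gene = g, quotient = q$quotient, dev = q$dev,
               induced = q$induced, is_reference = FALSE,
               stringsAsFactors = FALSE)
  })
  # raw (un-normalized) quotient of the reference itself
  rc <- split_conditions(ref, "reference")
  mi <- condition_mean(rc$ind, averaging); mu <- condition_mean(rc$un, averaging)
  qr <- mi$mean / mu$mean
  dr <- qr * sqrt((mi$sd / mi$mean)^2 + (mu$sd / mu$mean)^2)
  rows <- c(rows, list(data.frame(gene = reference_gene, quotient = qr,
                                  dev = dr, induced = qr >= threshold,
                                  is_reference = TRUE,
                                  stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Read a tidy qRT-PCR measurement TSV
#'
#' Expected columns: `gene`, `condition`, `bio_rep`, `tech_rep`, and `level`
#' or `ct` (optionally `efficiency`).
#'
#' @param file path to the TSV.
#' @return data.frame of measurements.
#' @export
read_qpcr_table <- function(file) {
  tab <- read.delim(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene", "condition") %in% names(tab)) ||
      !any(c("level", "ct") %in% names(tab))) {
    stop("qPCR file needs 'gene', 'condition' and 'level' or 'ct' columns",
         call. = FALSE)
  }
  tab
}

#' Write a quotient table as TSV
#'
#' @param quotients data.frame from [quotient_table()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_quotient_table <- function(quotients, file) {
  write.table(quotients, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
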