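#' Kinetic profile of a reporter strain
#'
#' Parameter bundle for [gen_time_course()]: the baseline level, an
#' uninduced drift (typically a small negative slope from reporter dilution),
#' a condition-dependent lag before induction, the induced linear slope, an
#' optional quadratic term for accelerating induction, Gaussian measurement
#' noise and an optional saturation ceiling.
#'
#' @param strain strain label.
#' @param a0 baseline specific activity (U/mg).
#' @param drift uninduced slope (U/mg/min).
#' @param lag lag before induction starts (minutes, >= 0).
#' @param slope induced slope after the lag (U/mg/min).
#' @param curvature quadratic term after the lag (U/mg/min^2).
#' @param noise_sd Gaussian noise SD (U/mg, >= 0).
#' @param max_activity saturation ceiling (U/mg); `Inf` for none.
#' @return list of class `kinetic_profile`.
#' @export
kinetic_profile <- function(strain = "strain", a0, drift = 0, lag = 0,
                            slope = 0, curvature = 0, noise_sd = 0,
                            max_activity = Inf) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (lag < 0) stop("'lag' must be >= 0", call. = FALSE)
  structure(list(strain = strain, a0 = a0, drift = drift, lag = lag,
                 slope = slope, curvature = curvature, noise_sd = noise_sd,
                 max_activity = max_activity),
            class = "kinetic_profile")
}

#' Generate a replicated reporter time course
#'
#' Simulates specific-activity measurements of a reporter strain. The
#' noise-free induced trajectory is
#' \deqn{y(t) = a_0 + drift \cdot \min(t, lag) + slope \cdot (t - lag)_+ +
#'   curvature \cdot (t - lag)_+^2,}
#' the uninduced one \eqn{y(t) = a_0 + drift \cdot t}. Gaussian noise of SD
#' `noise_sd` is added per observation and values are clipped at
#' `max_activity`. Deterministic given `seed`; the caller's RNG state is
#' untouched.
#'
#' @param profile a [kinetic_profile()].
#' @param times measurement times (minutes).
#' @param n_replicates replicates per time point.
#' @param induced simulate the induced (TRUE) or uninduced course.
#' @param seed integer RNG seed.
#' @param condition condition label; defaults to `"induced"`/`"uninduced"`.
#' @return data.frame with columns `strain`, `condition`, `replicate`,
#'   `time`, `activity`.
#' @export
gen_time_course <- function(profile, times, n_replicates = 6, induced = TRUE,
                            seed = 1,
                            condition = if (induced) "induced" else "uninduced") {
  if (length(times) == 0L) stop("'times' must be non-empty", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(n_replicates), time = times)
  mu <- if (induced) {
    post <- pmax(0, grid$time - profile$lag)
    profile$a0 + profile$drift * pmin(grid$time, profile$lag) +
      profile$slope * post + profile$curvature * post^2
  } else {
    profile$a0 + profile$drift * grid$time
  }
  y <- with_seed(seed, mu + rnorm(nrow(grid), sd = profile$noise_sd))
  data.frame(strain = profile$strain, condition = condition,
             replicate = grid$replicate, time = grid$time,
             activity = pmin(y, profile$max_activity),
             stringsAsFactors = FALSE)
}

#' Generate plate-reader absorbances for known activities
#'
#' Inverts the plate-assay relation so that [activity_plate()] recovers the
#' planted activities exactly at zero noise:
#' \eqn{E_{420} = activity \cdot t / 315.8 + 1.75 \cdot E_{550} + noise}.
#'
#' @param activities planted activities (U).
#' @param reaction_time reaction time in minutes.
#' @param dry_mass optional dry mass (mg) per reading.
#' @param e550 planted scattering extinction(s); recycled.
#' @param noise_sd Gaussian noise SD on E420.
#' @param seed integer RNG seed.
#' @return data.frame with columns `e420`, `e550`, `reaction_time` and
#'   optionally `dry_mass`.
#' @export
gen_absorbance <- function(activities, reaction_time, dry_mass = NULL,
                           e550 = 0, noise_sd = 0, seed = 1) {
  stopifnot_scalar_number(reaction_time, "reaction_time", positive = TRUE)
  n <- length(activities)
  e550 <- rep_len(e550, n)
  e420 <- activities * reaction_time / 315.8 + 1.75 * e550 +
    with_seed(seed, rnorm(n, sd = noise_sd))
  out <- data.frame(e420 = e420, e550 = e550, reaction_time = reaction_time)
  if (!is.null(dry_mass)) out$dry_mass <- rep_len(dry_mass, n)
  out
}

#' Generate a qRT-PCR measurement table with planted induction quotients
#'
#' Emulates a relative-quantification design with a flat reference gene and
#' per-gene planted induced/uninduced fold changes: each gene's uninduced
#' level is `base_level`, its induced level `base_level * quotient`; the
#' reference gene is flat at `base_level` in both conditions. Multiplicative
#' lognormal noise with coefficient of variation `noise_cv` is applied
#' per determination (mean-preserving). The default design of 2 biological
#' by 2 technical replicates mirrors a typical qRT-PCR setup with two
#' independent cultivations and two cDNA preparations.
#'
#' @param quotients named numeric vector of planted quotients (> 0), one per
#'   target gene.
#' @param reference_gene reference gene name (default `"rpoZ"`).
#' @param n_bio,n_tech biological and technical replicates per condition.
#' @param noise_cv lognormal coefficient of variation (0 for noise-free).
#' @param base_level uninduced transcript level.
#' @param seed integer RNG seed.
#' @return data.frame with columns `gene`, `condition`, `bio_rep`,
#'   `tech_rep`, `level` — a valid input for [quotient_table()].
#' @export
gen_qpcr <- function(quotients, reference_gene = "rpoZ", n_bio = 2,
                     n_tech = 2, noise_cv = 0, base_level = 1, seed = 1) {
  if (any(quotients <= 0)) stop("quotients must be > 0", call. = FALSE)
  genes <- c(names(quotients), reference_gene)
  fold <- c(unname(quotients), 1)
  grid <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      condition = c("uninduced", "induced"),
                      gene_idx = seq_along(genes), stringsAsFactors = FALSE)
  mu <- base_level * ifelse(grid$condition == "induced", fold[grid$gene_idx], 1)
  level <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_seed(seed, rlnorm(nrow(grid), meanlog = log(mu) - sdlog^2 / 2,
                           sdlog = sdlog))
  } else {
    mu
  }
  data.frame(gene = genes[grid$gene_idx], condition = grid$condition,
             bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
             level = level, stringsAsFactors = FALSE)
}

#' Generate replicated 5'-read-start tracks with planted TSS peaks
#'
#' Emulates Cappable-seq count tracks: independent background counts
#' Poisson(`background_rate`) at every position and orientation, plus
#' planted peak counts Poisson(strength x N / 1e6) at the specified TSS
#' positions, so a planted peak's expected RRS equals its strength. Each
#' replicate and condition is an independent draw; everything is
#' deterministic given `seed`. An optional negative-binomial mode
#' (`overdispersion < Inf`, the NB size parameter) inflates replicate
#' variance beyond Poisson.
#'
#' @param replicon_length replicon length in bp.
#' @param tss_specs data.frame with columns `pos`, `strand` and either a
#'   single `strength` column (expected RRS, all conditions) or one
#'   `strength_<condition>` column per entry of `conditions`.
#' @param background_rate expected background count per position and
#'   orientation (>= 0).
#' @param N total mapped reads recorded on each track.
#' @param n_replicates biological replicates per condition.
#' @param conditions character vector of condition labels.
#' @param seed integer RNG seed.
#' @param overdispersion negative-binomial size; `Inf` (default) = Poisson.
#' @param replicon_id replicon name on the tracks.
#' @return Nested list: `tracks[[condition]][[replicate]]`, each a
#'   [read_start_track()].
#' @export
gen_read_starts <- function(replicon_length, tss_specs, background_rate,
                            N = 1e6, n_replicates = 3, conditions = "treated",
                            seed = 1, overdispersion = Inf,
                            replicon_id = "synthetic_replicon") {
  stopifnot_scalar_number(replicon_length, "replicon_length", positive = TRUE)
  stopifnot_scalar_number(N, "N", positive = TRUE)
  if (background_rate < 0) stop("'background_rate' must be >= 0", call. = FALSE)
  draw <- function(n, mu) {
    if (is.finite(overdispersion)) {
      stats::rnbinom(n, size = overdispersion, mu = mu)
    } else {
      rpois(n, mu)
    }
  }
  strength_for <- function(cond) {
    col <- paste0("strength_", cond)
    if (col %in% names(tss_specs)) tss_specs[[col]]
    else if ("strength" %in% names(tss_specs)) tss_specs$strength
    else stop("tss_specs needs a 'strength' or 'strength_", cond,
              "' column", call. = FALSE)
  }
  with_seed(seed, {
    out <- list()
    for (cond in conditions) {
      strength <- strength_for(cond)
      reps <- vector("list", n_replicates)
      for (r in seq_len(n_replicates)) {
        counts <- data.frame(pos = integer(), strand = character(),
                             count = integer(), stringsAsFactors = FALSE)
        for (s in c("+", "-")) {
          bg <- if (background_rate > 0) {
            draw(replicon_length, background_rate)
          } else {
            integer(replicon_length)
          }
          hit <- which(bg > 0)
          if (length(hit)) {
            counts <- rbind(counts, data.frame(pos = hit, strand = s,
                                               count = bg[hit]))
          }
        }
        planted <- draw(nrow(tss_specs), strength * N / 1e6)
        for (i in seq_len(nrow(tss_specs))) {
          sel <- counts$pos == tss_specs$pos[i] &
            counts$strand == tss_specs$strand[i]
          if (any(sel)) {
            counts$count[sel] <- counts$count[sel] + planted[i]
          } else if (planted[i] > 0) {
            counts <- rbind(counts, data.frame(pos = tss_specs$pos[i],
                                               strand = tss_specs$strand[i],
                                               count = planted[i]))
          }
        }
        total <- sum(counts$count)
        n_track <- N
        if (total > N) {
          # only reachable when planted strengths sum near 1e6: the library
          # is saturated, so the drawn total becomes the library size
          warning("drawn counts (", total, ") exceed N; track N raised",
                  call. = FALSE)
          n_track <- total
        }
        reps[[r]] <- read_start_track(counts, N = n_track,
                                      replicon_id = replicon_id,
                                      length = replicon_length,
                                      condition = cond, replicate = r)
      }
      out[[cond]] <- reps
    }
    out
  })
}

#' Generate a random genome sequence with planted motifs
#'
#' Uniform random nucleotides with optional motifs written in at fixed
#' positions (e.g. promoter elements at known offsets from planted TSSs).
#' Overlapping motif placements are an error.
#'
#' @param length sequence length in bp.
#' @param planted_motifs optional data.frame with columns `motif` (DNA
#'   string) and `at` (1-based start position).
#' @param seed integer RNG seed.
#' @param name sequence name in the returned set.
#' @return A [Biostrings::DNAStringSet] of one sequence.
#' @export
gen_genome <- function(length, planted_motifs = NULL, seed = 1,
                       name = "synthetic_replicon") {
  stopifnot_scalar_number(length, "length", positive = TRUE)
  chars <- with_seed(seed, sample(c("A", "C", "G", "T"), length,
                                  replace = TRUE))
  if (!is.null(planted_motifs) && nrow(planted_motifs) > 0L) {
    spans <- cbind(planted_motifs$at,
                   planted_motifs$at + nchar(planted_motifs$motif) - 1L)
    if (any(spans[, 1] < 1) || any(spans[, 2] > length)) {
      stop("planted motif extends outside the sequence", call. = FALSE)
    }
    ord <- order(spans[, 1])
    if (nrow(spans) > 1L &&
        any(spans[ord, 1][-1] <= spans[ord, 2][-nrow(spans)])) {
      stop("planted motifs overlap", call. = FALSE)
    }
    for (i in seq_len(nrow(planted_motifs))) {
      m <- strsplit(planted_motifs$motif[i], "")[[1]]
      chars[seq(planted_motifs$at[i], length.out = length(m))] <- m
    }
  }
  out <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(out) <- name
  out
}
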