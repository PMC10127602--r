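#' Beta-galactosidase activity from a microtiter-plate assay
#'
#' Converts a plate-reader extinction pair into an enzyme activity using the
#' scattering-corrected relation
#' \deqn{activity = 315.8 \times (E_{420} - 1.75 \times E_{550}) / t}
#' where \eqn{t} is the reaction time in minutes. The factor 315.8 is a lumped
#' calibration constant combining the optical path length of the well with the
#' molar extinction coefficient of o-nitrophenol; 1 U corresponds to 1 nmol
#' o-nitrophenol formed per minute at 30 degrees C. The E550 term corrects for
#' light scattering by cell debris in permeabilized-cell assays.
#'
#' The corrected extinction may be negative when scattering exceeds the ONPG
#' signal; the activity is then negative and a warning is emitted, but the
#' value is not clamped because clamping would bias baseline subtraction in
#' downstream time-course fits.
#'
#' @param e420 extinction at 420 nm (dimensionless, >= 0).
#' @param e550 extinction at 550 nm (dimensionless, >= 0). Required for this
#'   assay variant; use [activity_tube()] when no E550 was read.
#' @param reaction_time reaction time in minutes (> 0).
#' @param dry_mass optional cellular dry mass in mg; when given, the specific
#'   activity (U/mg) is returned as well.
#' @return A data.frame with columns `activity` (U) and, when `dry_mass` is
#'   supplied, `specific_activity` (U/mg). Vectorized over readings.
#' @seealso [activity_tube()], [specific_activity()]
#' @examples
#' activity_plate(e420 = 0.60, e550 = 0.08, reaction_time = 20)
#' @export
activity_plate <- function(e420, e550, reaction_time, dry_mass = NULL) {
  if (missing(e550) || is.null(e550) || anyNA(e550)) {
    stop("activity_plate() requires E550 readings; ",
         "use activity_tube() for the tube assay without an E550 correction",
         call. = FALSE)
  }
  check_absorbance_inputs(e420, reaction_time)
  if (any(e550 < 0)) stop("'e550' must be >= 0", call. = FALSE)
  activity <- 315.8 * (e420 - 1.75 * e550) / reaction_time
  if (any(activity < 0)) {
    warning("negative corrected extinction (E420 < 1.75 * E550) in ",
            sum(activity < 0), " reading(s); activity reported as negative",
            call. = FALSE)
  }
  finish_activity(activity, dry_mass)
}

#' Beta-galactosidase activity from the tube assay
#'
#' Tube-assay variant without the scattering correction:
#' \eqn{activity = 355.6 \times E_{420} / t}, with \eqn{t} in minutes and
#' 1 U = 1 nmol o-nitrophenol per minute at 30 degrees C. The constant 355.6
#' absorbs the cuvette path length and extinction coefficient.
#'
#' @inheritParams activity_plate
#' @return A data.frame with column `activity` (U) and, when `dry_mass` is
#'   supplied, `specific_activity` (U/mg).
#' @examples
#' activity_tube(e420 = 1.0, reaction_time = 10)
#' @export
activity_tube <- function(e420, reaction_time, dry_mass = NULL) {
  check_absorbance_inputs(e420, reaction_time)
  finish_activity(355.6 * e420 / reaction_time, dry_mass)
}

check_absorbance_inputs <- function(e420, reaction_time) {
  if (any(!is.finite(e420)) || any(e420 < 0)) {
    stop("'e420' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(reaction_time)) || any(reaction_time <= 0)) {
    stop("'reaction_time' must be > 0 minutes", call. = FALSE)
  }
}

finish_activity <- function(activity, dry_mass) {
  out <- data.frame(activity = activity)
  if (!is.null(dry_mass)) {
    out$specific_activity <- specific_activity(activity, dry_mass)
  }
  out
}

#' Specific activity per unit dry mass
#'
#' @param activity enzyme activity in U.
#' @param dry_mass cellular dry mass in mg (> 0).
#' @return Specific activity in U/mg.
#' @examples
#' specific_activity(15.79, 0.5)
#' @export
specific_activity <- function(activity, dry_mass) {
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0)) {
    stop("'dry_mass' must be > 0 mg", call. = FALSE)
  }
  activity / dry_mass
}

#' Read a delimited plate table of absorbance readings
#'
#' Expects a header row. Column names are configurable so exports from
#' different readers can be ingested without editing the file.
#'
#' @param file path to a CSV or TSV file (delimiter auto-detected from the
#'   extension, override with `sep`).
#' @param columns named character vector mapping the canonical names
#'   (`e420`, `e550`, `reaction_time`, `dry_mass`, `strain`, `condition`,
#'   `replicate`, `well_id`) to the column names used in the file. Only
#'   remaps the names given; others keep the canonical spelling.
#' @param sep field delimiter; default inferred from the file extension.
#' @return A data.frame with canonical column names.
#' @export
read_plate_table <- function(file, columns = character(), sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  }
  tab <- read.delim(file, sep = sep, header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (canon in names(columns)) {
    src <- columns[[canon]]
    if (!src %in% names(tab)) {
      stop(sprintf("column '%s' (mapped to '%s') not found in %s",
                   src, canon, file), call. = FALSE)
    }
    names(tab)[names(tab) == src] <- canon
  }
  tab
}

#' Compute activities for a whole plate table
#'
#' Applies [activity_plate()] or [activity_tube()] row-wise to a table read
#' with [read_plate_table()] and returns the table with `activity` (and
#' `specific_activity` when a `dry_mass` column is present) appended.
#'
#' @param readings data.frame with canonical columns (`e420`,
#'   `reaction_time`, and for the plate assay `e550`; optionally `dry_mass`).
#' @param assay `"plate"` (E550-corrected) or `"tube"`.
#' @return The input data.frame with activity columns appended.
#' @export
activity_table <- function(readings, assay = c("plate", "tube")) {
  assay <- match.arg(assay)
  dm <- if ("dry_mass" %in% names(readings)) readings$dry_mass else NULL
  res <- if (assay == "plate") {
    activity_plate(readings$e420, readings$e550, readings$reaction_time, dm)
  } else {
    activity_tube(readings$e420, readings$reaction_time, dm)
  }
  cbind(readings, res)
}

#' Write per-well activities as TSV
#'
#' @param activities data.frame as returned by [activity_table()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_activity_table <- function(activities, file) {
  write.table(activities, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
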