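#' Aggregation time course for a single well
#'
#' Container for one well's ThT fluorescence trace plus the condition
#' metadata needed to group replicates: tau concentration, inhibitor
#' identity and concentration, heparin flag and replicate label.
#'
#' @param times Numeric vector of time points in hours, strictly increasing,
#'   length >= 4.
#' @param fluorescence Numeric vector of fluorescence values (arbitrary
#'   units), same length as `times`.
#' @param tau_conc Tau monomer concentration in uM (>= 0).
#' @param inhibitor_id Inhibitor label (e.g. `"apiCCT3"`) or `NA` for none.
#' @param inhibitor_conc Inhibitor concentration in uM (0 when none).
#' @param heparin Logical; was heparin present (aggregation induced)?
#' @param replicate_id Replicate label (well name or index).
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, fluorescence, tau_conc,
                        inhibitor_id = NA_character_, inhibitor_conc = 0,
                        heparin = TRUE, replicate_id = "r1") {
  times <- as.numeric(times)
  fluorescence <- as.numeric(fluorescence)
  if (length(times) != length(fluorescence))
    stop("times and fluorescence must have the same length")
  if (length(times) < 4L)
    stop("a time course needs at least 4 points")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing")
  if (!is.finite(tau_conc) || tau_conc < 0)
    stop("tau_conc must be >= 0")
  structure(
    list(times = times, fluorescence = fluorescence,
         tau_conc = as.numeric(tau_conc),
         inhibitor_id = as.character(inhibitor_id),
         inhibitor_conc = as.numeric(inhibitor_conc),
         heparin = isTRUE(heparin), replicate_id = as.character(replicate_id)),
    class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %d points, %.2f-%.2f h, tau %g uM, %s%s, rep %s\n",
              length(x$times), min(x$times), max(x$times), x$tau_conc,
              if (is.na(x$inhibitor_id)) "no inhibitor"
              else sprintf("%s %g uM", x$inhibitor_id, x$inhibitor_conc),
              if (x$heparin) "" else ", no heparin", x$replicate_id))
  invisible(x)
}

#' Averaged aggregation curve
#'
#' The pointwise mean of replicate time courses for one condition, with
#' processing state flags (control subtraction, normalisation) carried
#' along so downstream steps can check their preconditions.
#'
#' @param times Time grid in hours.
#' @param mean_fluorescence Mean fluorescence (a.u.) on that grid.
#' @param n_replicates Number of replicates averaged.
#' @param control_subtracted Has a heparin-free control been subtracted?
#' @param normalized Has the curve been min-max normalised?
#' @param norm_reference Length-2 numeric `c(F_min, F_max)` used for
#'   normalisation, or `NULL`.
#' @param condition Optional list of condition metadata (tau_conc, ...).
#' @return An object of class `averaged_curve`.
#' @export
averaged_curve <- function(times, mean_fluorescence, n_replicates = 1L,
                           control_subtracted = FALSE, normalized = FALSE,
                           norm_reference = NULL, condition = list()) {
  times <- as.numeric(times)
  mean_fluorescence <- as.numeric(mean_fluorescence)
  if (length(times) != length(mean_fluorescence))
    stop("times and mean_fluorescence must have the same length")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (isTRUE(normalized)) {
    if (is.null(norm_reference) || length(norm_reference) != 2L)
      stop("a normalized curve must record its (F_min, F_max) reference")
    if (norm_reference[2] <= norm_reference[1])
      stop("norm_reference must satisfy F_max > F_min")
  }
  structure(
    list(times = times, mean_fluorescence = mean_fluorescence,
         n_replicates = as.integer(n_replicates),
         control_subtracted = isTRUE(control_subtracted),
         normalized = isTRUE(normalized),
         norm_reference = norm_reference, condition = condition),
    class = "averaged_curve")
}

#' @export
print.averaged_curve <- function(x, ...) {
  cat(sprintf("<averaged_curve> %d points, n=%d%s%s\n", length(x$times),
              x$n_replicates,
              if (x$control_subtracted) ", control-subtracted" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

condition_key <- function(tc) {
  paste(tc$tau_conc, tc$inhibitor_id, tc$inhibitor_conc, tc$heparin,
        sep = "|")
}

#' Read a plate-reader export plus well metadata
#'
#' The plate file is delimited text with a `time` column (hours) and one
#' column per well; the metadata file maps each well to its condition
#' (columns `well`, `tau_conc_uM`, `inhibitor`, `inhibitor_conc_uM`,
#' `heparin`, `replicate`).
#'
#' @param plate_file Path to the plate CSV/TSV.
#' @param meta_file Path to the well-metadata CSV/TSV.
#' @param sep Field separator; `","` by default.
#' @return A named list of [time_course()] objects, one per well column.
#' @export
load_plate <- function(plate_file, meta_file, sep = ",") {
  plate <- utils::read.table(plate_file, header = TRUE, sep = sep,
                             check.names = FALSE, comment.char = "#")
  meta <- utils::read.table(meta_file, header = TRUE, sep = sep,
                            check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
  tcol <- grep("^time", names(plate), ignore.case = TRUE, value = TRUE)
  if (length(tcol) != 1L)
    stop("plate file must have exactly one time column")
  times <- plate[[tcol]]
  if (any(diff(times) <= 0))
    stop("plate time column must be strictly increasing (duplicate or ",
         "non-monotone time values found)")
  wells <- setdiff(names(plate), tcol)
  need <- c("well", "tau_conc_uM", "inhibitor", "inhibitor_conc_uM",
            "heparin", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata file lacks columns: ", paste(missing_cols, collapse = ", "))
  out <- vector("list", length(wells))
  names(out) <- wells
  for (w in wells) {
    row <- meta[meta$well == w, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("no metadata for well '", w, "'")
    if (nrow(row) > 1L)
      stop("duplicated metadata for well '", w, "'")
    inh <- as.character(row$inhibitor)
    if (is.na(inh) || inh %in% c("", "none", "NA")) inh <- NA_character_
    out[[w]] <- time_course(
      times = times, fluorescence = plate[[w]],
      tau_conc = row$tau_conc_uM, inhibitor_id = inh,
      inhibitor_conc = row$inhibitor_conc_uM,
      heparin = as.logical(row$heparin),
      replicate_id = as.character(row$replicate))
  }
  out
}

#' Average replicate time courses
#'
#' Pointwise arithmetic mean of replicates sharing one condition and one
#' time grid. No interpolation is attempted: a grid mismatch is an error,
#' because silently resampling plate-reader data hides acquisition bugs.
#'
#' @param curves List of [time_course()] objects.
#' @return An [averaged_curve()].
#' @export
average_replicates <- function(curves) {
  if (!length(curves)) stop("no curves supplied")
  stopifnot(all(vapply(curves, inherits, logical(1), "time_course")))
  ref <- curves[[1L]]
  keys <- vapply(curves, condition_key, character(1))
  if (length(unique(keys)) != 1L)
    stop("curves mix conditions: ", paste(unique(keys), collapse = " vs "))
  for (tc in curves)
    if (length(tc$times) != length(ref$times) ||
        any(tc$times != ref$times))
      stop("replicates must share an identical time grid")
  mat <- vapply(curves, function(tc) tc$fluorescence,
                numeric(length(ref$times)))
  mat <- matrix(mat, nrow = length(ref$times))
  averaged_curve(
    times = ref$times, mean_fluorescence = rowMeans(mat),
    n_replicates = length(curves),
    condition = list(tau_conc = ref$tau_conc,
                     inhibitor_id = ref$inhibitor_id,
                     inhibitor_conc = ref$inhibitor_conc,
                     heparin = ref$heparin))
}

#' Subtract the heparin-free control curve
#'
#' Removes the non-aggregation fluorescence background so the remaining
#' signal is attributable to fibril formation.
#'
#' @param avg The averaged curve for a condition.
#' @param control The matching heparin-free averaged control.
#' @return The control-subtracted [averaged_curve()].
#' @export
subtract_control <- function(avg, control) {
  stopifnot(inherits(avg, "averaged_curve"), inherits(control, "averaged_curve"))
  if (length(avg$times) != length(control$times) ||
      any(avg$times != control$times))
    stop("control must be on the same time grid as the averaged curve")
  averaged_curve(
    times = avg$times,
    mean_fluorescence = avg$mean_fluorescence - control$mean_fluorescence,
    n_replicates = avg$n_replicates, control_subtracted = TRUE,
    condition = avg$condition)
}

#' Min-max normalise an averaged curve
#'
#' `F_n = (F - F_min) / (F_max - F_min)`. For the tau-alone curve the
#' reference is the curve itself (`F_min` = its minimum, `F_max` = its
#' maximum); inhibitor curves are normalised against the tau-alone
#' reference so that a suppressed plateau reads as a final value below 1.
#' (The source protocol's min/max labels are read as min = initial,
#' max = plateau; the printed label order is a typo.)
#'
#' @param avg Curve to normalise.
#' @param reference Optional [averaged_curve()] supplying `(F_min, F_max)`;
#'   `NULL` means self-normalisation.
#' @return The normalised [averaged_curve()], with `norm_reference` set.
#' @export
normalize_curve <- function(avg, reference = NULL) {
  stopifnot(inherits(avg, "averaged_curve"))
  src <- if (is.null(reference)) avg else reference
  if (!is.null(reference)) stopifnot(inherits(reference, "averaged_curve"))
  fmin <- min(src$mean_fluorescence)
  fmax <- max(src$mean_fluorescence)
  if (fmax == fmin)
    stop("degenerate normalisation range: F_max == F_min")
  averaged_curve(
    times = avg$times,
    mean_fluorescence = (avg$mean_fluorescence - fmin) / (fmax - fmin),
    n_replicates = avg$n_replicates,
    control_subtracted = avg$control_subtracted,
    normalized = TRUE, norm_reference = c(fmin, fmax),
    condition = avg$condition)
}
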