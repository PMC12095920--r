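#' Fit every condition on a plate
#'
#' The standard analysis path: read plate + metadata, average replicates
#' per condition, subtract the matching heparin-free control when present,
#' normalise (tau-alone conditions against themselves; inhibitor
#' conditions against the tau-alone curve at the same tau concentration
#' when available), and fit the two-baseline sigmoid.
#'
#' @param plate_file,meta_file Paths as for [load_plate()].
#' @return Data frame: one row per heparin-positive condition with the
#'   condition metadata, fitted parameters, standard errors, `rmse`,
#'   `converged`, and `inv_k` (= 1/k; reported alongside k because the
#'   literature prints the transition parameter with hour units and either
#'   reading may be wanted).
#' @export
fit_plate <- function(plate_file, meta_file) {
  wells <- load_plate(plate_file, meta_file)
  keys <- vapply(wells, condition_key, character(1))
  groups <- split(wells, keys)
  avgs <- lapply(groups, average_replicates)
  is_hep <- vapply(avgs, function(a) isTRUE(a$condition$heparin),
                   logical(1))
  refs <- avgs[!is_hep]
  hep <- avgs[is_hep]

  find_control <- function(a) {
    for (ctrl in refs) {
      c1 <- a$condition; c2 <- ctrl$condition
      if (identical(c1$tau_conc, c2$tau_conc) &&
          identical(c1$inhibitor_id, c2$inhibitor_id) &&
          identical(c1$inhibitor_conc, c2$inhibitor_conc))
        return(ctrl)
    }
    NULL
  }
  find_reference <- function(a, processed) {
    for (p in processed) {
      if (is.na(p$condition$inhibitor_id) &&
          identical(p$condition$tau_conc, a$condition$tau_conc))
        return(p)
    }
    NULL
  }

  processed <- lapply(hep, function(a) {
    ctrl <- find_control(a)
    if (!is.null(ctrl)) a <- subtract_control(a, ctrl)
    a
  })
  rows <- lapply(processed, function(a) {
    ref <- if (is.na(a$condition$inhibitor_id)) NULL
           else find_reference(a, processed)
    norm <- normalize_curve(a, ref)
    fit <- fit_sigmoid(norm)
    data.frame(
      tau_conc_uM = a$condition$tau_conc,
      inhibitor = ifelse(is.na(a$condition$inhibitor_id), "none",
                         a$condition$inhibitor_id),
      inhibitor_conc_uM = a$condition$inhibitor_conc,
      n_replicates = a$n_replicates,
      m1 = fit$m1, n1 = fit$n1, m2 = fit$m2, n2 = fit$n2,
      k = fit$k, t05 = fit$t05,
      se_k = fit$se[["k"]], se_t05 = fit$se[["t05"]],
      inv_k = 1 / fit$k, rmse = fit$rmse, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$inhibitor, out$inhibitor_conc_uM, out$tau_conc_uM), ]
  rownames(out) <- NULL
  out
}

#' Half-time scaling per inhibitor series from a fit table
#'
#' Groups a [fit_plate()] table by inhibitor condition and regresses
#' `log10(t05)` on `log10(tau_conc)` within each group having at least 3
#' concentrations.
#'
#' @param fits Data frame from [fit_plate()] (or the CSV it was saved to).
#' @return Data frame: `inhibitor`, `inhibitor_conc_uM`, `n_conc`,
#'   `slope`, `slope_se`, `intercept`, `r_squared`.
#' @export
scaling_from_fits <- function(fits) {
  grp <- split(fits, paste(fits$inhibitor, fits$inhibitor_conc_uM))
  rows <- lapply(grp, function(g) {
    if (length(unique(g$tau_conc_uM)) < 3L) return(NULL)
    sc <- halftime_scaling(g$tau_conc_uM, g$t05)
    data.frame(inhibitor = g$inhibitor[1],
               inhibitor_conc_uM = g$inhibitor_conc_uM[1],
               n_conc = length(unique(g$tau_conc_uM)),
               slope = sc$slope, slope_se = sc$slope_se,
               intercept = sc$intercept, r_squared = sc$r_squared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a long-format curve table into global-fit input
#'
#' @param file CSV with columns `condition`, `m0_uM`, `time_h`,
#'   `mass_fraction`.
#' @return List of `list(m0, times, mass)` entries, one per condition.
#' @export
read_curves <- function(file) {
  df <- utils::read.csv(file)
  need <- c("m0_uM", "time_h", "mass_fraction")
  if (!all(need %in% names(df)))
    stop("curves file needs columns ", paste(need, collapse = ", "))
  lapply(split(df, df$m0_uM), function(g)
    list(m0 = g$m0_uM[1], times = g$time_h, mass = g$mass_fraction))
}
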