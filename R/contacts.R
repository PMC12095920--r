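#' Construct a contact map from an explicit probability matrix
#'
#' For hand-built maps (painted ground truths, tests). Rows are tau
#' residues, columns apical-domain residues, both in author numbering.
#'
#' @param matrix Probability matrix with entries in `[0, 1]`.
#' @param tau_numbering,api_numbering Author residue indices for rows /
#'   columns.
#' @param n_frames,n_replicas Provenance counts (informational).
#' @return A `contact_map` (unbinned).
#' @export
contact_map <- function(matrix, tau_numbering = seq_len(nrow(matrix)),
                        api_numbering = seq_len(ncol(matrix)),
                        n_frames = 0L, n_replicas = 0L) {
  if (any(matrix < 0) || any(matrix > 1))
    stop("probabilities must lie in [0, 1]")
  if (nrow(matrix) != length(tau_numbering) ||
      ncol(matrix) != length(api_numbering))
    stop("numbering lengths must match the matrix dimensions")
  dimnames(matrix) <- list(tau_numbering, api_numbering)
  new_contact_map(matrix, tau_numbering, api_numbering, 1L,
                  n_frames, n_replicas)
}

new_contact_map <- function(matrix, tau_numbering, api_numbering,
                            bin_size, n_frames, n_replicas,
                            tau_bins = NULL, api_bins = NULL) {
  structure(list(matrix = matrix, tau_numbering = tau_numbering,
                 api_numbering = api_numbering, bin_size = bin_size,
                 n_frames = n_frames, n_replicas = n_replicas,
                 tau_bins = tau_bins, api_bins = api_bins),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d (bin %d), %d frames / %d replicas, max %.3f\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size, x$n_frames,
              x$n_replicas, max(x$matrix)))
  invisible(x)
}

#' Residue-residue interaction probabilities from trajectories
#'
#' For every (disordered-chain residue, folded-chain residue) pair, the
#' fraction of frames — pooled over replicas, after discarding an
#' equilibration fraction per replica — in which the bead-bead distance is
#' under `cutoff` (minimum image when the system is periodic). Residue
#' centres are the C-alpha beads, the model's only coordinate per residue.
#'
#' @param trajs List of `cg_trajectory` objects sharing a system with one
#'   disordered (tau) and one folded (apical-domain) chain.
#' @param cutoff Interaction distance cutoff, Angstrom (6).
#' @param equil_frac Fraction of initial frames discarded per replica
#'   (0.1; set 0 for exact hand-built tests).
#' @return An unbinned `contact_map` (rows: tau residues, columns: apical
#'   domain residues, author numbering on both axes).
#' @export
contact_probabilities <- function(trajs, cutoff = 6, equil_frac = 0.1) {
  if (!length(trajs)) stop("empty trajectory list")
  stopifnot(all(vapply(trajs, inherits, logical(1), "cg_trajectory")))
  sys <- trajs[[1]]$system
  kinds <- vapply(sys$chains, function(ch) ch$kind, character(1))
  ti <- which(kinds == "disordered")[1]
  ai <- which(kinds == "folded")[1]
  if (is.na(ti) || is.na(ai))
    stop("system must contain one disordered and one folded chain")
  tau_idx <- sys$offset[ti] + seq_len(sys$n_per[ti])
  api_idx <- sys$offset[ai] + seq_len(sys$n_per[ai])
  box <- sys$topo$box
  pbc <- sys$topo$pbc
  counts <- matrix(0, length(tau_idx), length(api_idx))
  n_used <- 0L
  for (tr in trajs) {
    nf <- dim(tr$frames)[1]
    first <- floor(equil_frac * nf) + 1L
    for (f in seq(first, nf)) {
      xt <- matrix(tr$frames[f, tau_idx, , drop = TRUE],
                   ncol = 3)
      xa <- matrix(tr$frames[f, api_idx, , drop = TRUE],
                   ncol = 3)
      d2 <- matrix(0, nrow(xt), nrow(xa))
      for (a in 1:3) {
        dd <- outer(xt[, a], xa[, a], "-")
        if (pbc) dd <- dd - box * round(dd / box)
        d2 <- d2 + dd^2
      }
      counts <- counts + (d2 < cutoff^2)
      n_used <- n_used + 1L
    }
  }
  prob <- counts / n_used
  dimnames(prob) <- list(sys$chains[[ti]]$residue_numbering,
                         sys$chains[[ai]]$residue_numbering)
  new_contact_map(prob,
                  tau_numbering = sys$chains[[ti]]$residue_numbering,
                  api_numbering = sys$chains[[ai]]$residue_numbering,
                  bin_size = 1L, n_frames = n_used,
                  n_replicas = length(trajs))
}

bin_ranges <- function(numbering, bin_size) {
  n <- length(numbering)
  starts <- seq(1L, n, by = bin_size)
  lapply(starts, function(s) {
    idx <- s:min(s + bin_size - 1L, n)
    list(idx = idx, first = numbering[idx[1]],
         last = numbering[idx[length(idx)]])
  })
}

#' Bin a contact map into groups of consecutive residues
#'
#' Aggregates each (up to) `bin_size` x `bin_size` residue block; the
#' default operator is the block maximum (peak-preserving), with the block
#' mean as the alternative. Trailing partial bins are kept. `bin_size = 1`
#' is the identity.
#'
#' @param map An unbinned `contact_map`.
#' @param bin_size Residues per bin (3 is the conventional display).
#' @param rule `"max"` or `"mean"`.
#' @return A binned `contact_map`; axis labels carry the first residue of
#'   each bin, and `tau_bins`/`api_bins` the full ranges.
#' @export
bin_contacts <- function(map, bin_size = 3L, rule = c("max", "mean")) {
  stopifnot(inherits(map, "contact_map"))
  rule <- match.arg(rule)
  if (bin_size < 1L) stop("bin_size must be >= 1")
  if (map$bin_size != 1L) stop("map is already binned")
  if (bin_size == 1L) return(map)
  agg <- if (rule == "max") max else mean
  rb <- bin_ranges(map$tau_numbering, bin_size)
  cb <- bin_ranges(map$api_numbering, bin_size)
  out <- matrix(0, length(rb), length(cb))
  for (i in seq_along(rb))
    for (j in seq_along(cb))
      out[i, j] <- agg(map$matrix[rb[[i]]$idx, cb[[j]]$idx])
  dimnames(out) <- list(vapply(rb, function(b) b$first, numeric(1)),
                        vapply(cb, function(b) b$first, numeric(1)))
  new_contact_map(out,
                  tau_numbering = map$tau_numbering,
                  api_numbering = map$api_numbering,
                  bin_size = as.integer(bin_size),
                  n_frames = map$n_frames, n_replicas = map$n_replicas,
                  tau_bins = rb, api_bins = cb)
}

#' Contiguous tau segments above an interaction threshold
#'
#' Rows (tau residues or bins) whose maximum interaction probability
#' reaches `threshold` are merged into contiguous segments in author
#' numbering and ranked by their peak probability.
#'
#' @param map A `contact_map` (binned or not).
#' @param threshold Probability threshold in (0, 1].
#' @return Data frame `start`, `end` (author numbering, inclusive),
#'   `peak`, sorted by decreasing peak.
#' @export
interface_segments <- function(map, threshold = 0.2) {
  stopifnot(inherits(map, "contact_map"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  row_max <- apply(map$matrix, 1, max)
  hot <- which(row_max >= threshold)
  if (!length(hot))
    return(data.frame(start = integer(0), end = integer(0),
                      peak = numeric(0)))
  if (map$bin_size == 1L) {
    starts <- map$tau_numbering[hot]
    ends <- starts
  } else {
    starts <- vapply(map$tau_bins[hot], function(b) b$first, numeric(1))
    ends <- vapply(map$tau_bins[hot], function(b) b$last, numeric(1))
  }
  # merge rows that are adjacent in the map
  segs <- list()
  cur <- c(hot[1], hot[1])
  for (h in hot[-1]) {
    if (h == cur[2] + 1L) cur[2] <- h
    else { segs[[length(segs) + 1L]] <- cur; cur <- c(h, h) }
  }
  segs[[length(segs) + 1L]] <- cur
  res <- do.call(rbind, lapply(segs, function(sg) {
    rows <- sg[1]:sg[2]
    data.frame(
      start = if (map$bin_size == 1L) map$tau_numbering[sg[1]]
              else map$tau_bins[[sg[1]]]$first,
      end = if (map$bin_size == 1L) map$tau_numbering[sg[2]]
            else map$tau_bins[[sg[2]]]$last,
      peak = max(row_max[rows]))
  }))
  res <- res[order(-res$peak), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a contact map as TSV with author numbering
#'
#' @param map A `contact_map`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_contact_map <- function(map, file) {
  utils::write.table(map$matrix, file, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(file)
}

#' Write interface segments as BED-like text
#'
#' Three-plus columns: chain label, start, end (author numbering, 1-based
#' inclusive) and peak probability.
#'
#' @param segments Data frame from [interface_segments()].
#' @param file Output path.
#' @param chain_label Label for the first column (default "tau").
#' @return Invisibly, the path.
#' @export
write_segments_bed <- function(segments, file, chain_label = "tau") {
  df <- data.frame(chain = rep(chain_label, nrow(segments)),
                   start = segments$start, end = segments$end,
                   peak = segments$peak)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
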