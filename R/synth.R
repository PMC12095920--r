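#' The packaged tau 4R (K18) sequence
#'
#' The four microtubule-binding repeats of human tau, author residues
#' 244-372 (129 residues). With `c332a = TRUE` (the default, matching the
#' experimental construct) author position 332 carries Ala. Note the
#' discrepancy this mirrors: canonical 2N4R tau has Pro at 332 and its
#' cysteines at 291/322; the construct definition nevertheless specifies
#' C332A, and the packaged default follows the construct.
#'
#' @param c332a Apply the 332-Ala substitution (default TRUE).
#' @return One-letter sequence string, 129 residues (author numbering
#'   244-372 attached as the `numbering` attribute).
#' @export
tau4r_sequence <- function(c332a = TRUE) {
  s <- paste0(
    "QTAPVPMPDLKNVKSKIGSTENLKHQPGGGK",   # R1 244-274
    "VQIINKKLDLSNVQSKCGSKDNIKHVPGGGS",   # R2 275-305
    "VQIVYKPVDLSKVTSKCGSLGNIHHKPGGGQ",   # R3 306-336
    "VEVKSEKLDFKDRVQSKIGSLDNITHVPGGG",   # R4 337-367
    "NKKIE")                             # 368-372
  if (c332a) substr(s, 332 - 244 + 1, 332 - 244 + 1) <- "A"
  attr(s, "numbering") <- 244:372
  s
}

#' Generate a synthetic sigmoid plate (data + metadata + ground truth)
#'
#' Each condition row contributes `n_replicates` wells whose traces are
#' the two-baseline sigmoid [eval_sigmoid()] plus i.i.d. Gaussian noise;
#' optional heparin-free control wells carry the pre-transition baseline
#' only. Ground-truth parameters are written to a sidecar so recovery can
#' be scored without re-reading the generator.
#'
#' @param conditions Data frame with columns `name`, `m1`, `n1`, `m2`,
#'   `n2`, `k`, `t05`, `tau_conc_uM`, `inhibitor`, `inhibitor_conc_uM`.
#' @param times Time grid, hours (default 0-24 h at 5-minute intervals,
#'   the usual overnight plate run).
#' @param noise_sd Gaussian noise s.d., a.u. (>= 0).
#' @param n_replicates Wells per condition.
#' @param seed RNG seed; the plate is byte-reproducible.
#' @param dir Output directory; files `plate.csv`, `meta.csv`,
#'   `truth.csv` are created.
#' @param control_wells Also emit heparin-free baseline wells per
#'   condition?
#' @return Invisibly, a list of the three file paths.
#' @export
gen_sigmoid_plate <- function(conditions, times = seq(0, 24, by = 5 / 60),
                              noise_sd = 0, n_replicates = 1L, seed = 1L,
                              dir = ".", control_wells = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  need <- c("name", "m1", "n1", "m2", "n2", "k", "t05", "tau_conc_uM",
            "inhibitor", "inhibitor_conc_uM")
  missing <- setdiff(need, names(conditions))
  if (length(missing))
    stop("conditions lacks columns: ", paste(missing, collapse = ", "))
  set.seed(seed)
  plate <- data.frame(time_h = times)
  meta <- NULL
  for (ci in seq_len(nrow(conditions))) {
    cd <- conditions[ci, ]
    base <- eval_sigmoid(times, cd$m1, cd$n1, cd$m2, cd$n2, cd$k, cd$t05)
    for (r in seq_len(n_replicates)) {
      well <- sprintf("%s_r%d", cd$name, r)
      plate[[well]] <- base + if (noise_sd > 0)
        stats::rnorm(length(times), 0, noise_sd) else 0
      meta <- rbind(meta, data.frame(
        well = well, tau_conc_uM = cd$tau_conc_uM,
        inhibitor = cd$inhibitor, inhibitor_conc_uM = cd$inhibitor_conc_uM,
        heparin = TRUE, replicate = r))
    }
    if (control_wells) {
      for (r in seq_len(n_replicates)) {
        well <- sprintf("%s_ctrl_r%d", cd$name, r)
        plate[[well]] <- cd$m1 * times + cd$n1 + if (noise_sd > 0)
          stats::rnorm(length(times), 0, noise_sd) else 0
        meta <- rbind(meta, data.frame(
          well = well, tau_conc_uM = cd$tau_conc_uM,
          inhibitor = cd$inhibitor,
          inhibitor_conc_uM = cd$inhibitor_conc_uM,
          heparin = FALSE, replicate = r))
      }
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(plate = file.path(dir, "plate.csv"),
                meta = file.path(dir, "meta.csv"),
                truth = file.path(dir, "truth.csv"))
  utils::write.csv(plate, paths$plate, row.names = FALSE)
  utils::write.csv(meta, paths$meta, row.names = FALSE)
  truth <- conditions[need]
  truth$noise_sd <- noise_sd
  truth$n_replicates <- n_replicates
  truth$seed <- seed
  utils::write.csv(truth, paths$truth, row.names = FALSE)
  invisible(paths)
}

#' Generate a kinetic-model concentration series
#'
#' Forward-simulates one mechanism at several monomer concentrations and
#' (optionally) adds Gaussian noise, in the long format the global-fitting
#' interface reads: columns `condition`, `m0_uM`, `time_h`,
#' `mass_fraction`. Ground truth goes to a JSON sidecar.
#'
#' @param model A [kinetic_model()].
#' @param m0s Monomer concentrations, uM (>= 3 values).
#' @param times Time grid, hours.
#' @param noise_sd Gaussian noise s.d. on the normalised mass.
#' @param seed RNG seed.
#' @param file Optional CSV path (sidecar gets `.truth.json` appended).
#' @return Data frame of the curves (invisibly the paths if written).
#' @export
gen_model_series <- function(model, m0s, times = seq(0, 24, by = 0.1),
                             noise_sd = 0, seed = 1L, file = NULL) {
  if (length(m0s) < 3L) stop("need at least 3 monomer concentrations")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  rows <- lapply(seq_along(m0s), function(i) {
    mass <- simulate_model(model, m0s[i], times)
    if (noise_sd > 0) mass <- mass + stats::rnorm(length(mass), 0, noise_sd)
    data.frame(condition = sprintf("m0_%g", m0s[i]), m0_uM = m0s[i],
               time_h = times, mass_fraction = mass)
  })
  df <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    pn <- model_param_names(model$name)
    jsonlite::write_json(
      c(list(model = model$name, nc = model$nc, n2 = model$n2,
             noise_sd = noise_sd, seed = seed, m0s = m0s),
        model[pn]),
      paste0(file, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  df
}

helix_positions <- function(n, radius = 2.3, rise = 1.5, twist = 100,
                            phase = 0, descending = FALSE) {
  th <- (phase + twist * (seq_len(n) - 1L)) * pi / 180
  z <- rise * (seq_len(n) - 1L)
  if (descending) z <- -z
  cbind(radius * cos(th), radius * sin(th), z)
}

#' Generate a miniature folded-domain fixture (C-alpha PDB)
#'
#' Stand-in for a crystallographic apical domain: either a single
#' canonical alpha-helix (rise 1.5 A, 100 deg/residue, radius 2.3 A;
#' consecutive C-alpha spacing about 3.83 A) or a two-helix hairpin whose
#' inter-helix native contacts are hand-countable. The file is labelled
#' synthetic; it is geometry, not biology.
#'
#' @param n_residues At least 8.
#' @param geometry `"helix"` or `"helix_hairpin"`.
#' @param seed Seed for the (deterministic) sequence draw.
#' @param file Output PDB path; omit to just return the chain.
#' @param chain_id PDB chain id.
#' @return The folded `cg_chain` (invisibly if written to file).
#' @export
gen_mini_domain <- function(n_residues, geometry = c("helix",
                                                     "helix_hairpin"),
                            seed = 1L, file = NULL, chain_id = "A") {
  geometry <- match.arg(geometry)
  if (n_residues < 8L) stop("n_residues must be >= 8")
  set.seed(seed)
  seqs <- paste(sample(c("A", "L", "K", "E", "S", "G", "V", "T"),
                       n_residues, replace = TRUE), collapse = "")
  if (geometry == "helix") {
    pos <- helix_positions(n_residues)
  } else {
    nh1 <- (n_residues - 2L) %/% 2L
    nh2 <- n_residues - 2L - nh1
    d <- 9.5; r <- 2.3
    h1 <- helix_positions(nh1)
    end1 <- h1[nh1, ]
    h2 <- helix_positions(nh2, phase = 180, descending = TRUE)
    h2[, 1] <- h2[, 1] + d
    h2[, 2] <- h2[, 2] + end1[2]
    h2[, 3] <- h2[, 3] + end1[3]
    first2 <- h2[1, ]
    D <- sqrt(sum((first2 - end1)^2))
    xhat <- (first2 - end1) / D
    a1 <- (D - 3.8) / 2
    h <- sqrt(max(3.8^2 - a1^2, 0.01))
    zhat <- c(0, 0, 1)
    l1 <- end1 + a1 * xhat + h * zhat
    l2 <- first2 - a1 * xhat + h * zhat
    pos <- rbind(h1, l1, l2, h2)
  }
  chain <- cg_chain(seqs, pos, kind = "folded")
  if (!is.null(file)) {
    write_ca_pdb(chain, file, chain_id = chain_id)
    return(invisible(chain))
  }
  chain
}

#' Write a chain as a C-alpha-only PDB file
#'
#' @param chain A `cg_chain`.
#' @param file Output path.
#' @param chain_id PDB chain id character.
#' @return Invisibly, the path.
#' @export
write_ca_pdb <- function(chain, file, chain_id = "A") {
  lines <- c("REMARK   1 SYNTHETIC CA-ONLY FIXTURE (apichap)",
             vapply(seq_along(chain$aa), function(i) {
               sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                       i, AA1TO3[chain$aa[i]], chain_id,
                       chain$residue_numbering[i],
                       chain$positions[i, 1], chain$positions[i, 2],
                       chain$positions[i, 3])
             }, character(1)),
             "END")
  writeLines(lines, file)
  invisible(file)
}

#' Generate a random disordered-protein sequence with an exact net charge
#'
#' Draws K/R for positive and D/E for negative positions so that
#' `(#K + #R) - (#D + #E)` equals `net_charge` exactly; remaining
#' positions are neutral residues. The canonical tau 4R construct is
#' available separately via [tau4r_sequence()].
#'
#' @param length Sequence length.
#' @param net_charge Requested net charge, `|net_charge| <= length`.
#' @param seed RNG seed.
#' @return One-letter sequence string.
#' @export
gen_idp_sequence <- function(length, net_charge = 0, seed = 1L) {
  if (abs(net_charge) > length)
    stop("infeasible net charge for this length")
  set.seed(seed)
  n_base <- abs(net_charge)
  slots_left <- length - n_base
  n_pairs <- if (slots_left >= 2) sample.int(slots_left %/% 2 + 1L, 1) - 1L
             else 0L
  n_pos <- max(net_charge, 0) + n_pairs
  n_neg <- max(-net_charge, 0) + n_pairs
  n_neu <- length - n_pos - n_neg
  letters <- c(sample(c("K", "R"), n_pos, replace = TRUE),
               sample(c("D", "E"), n_neg, replace = TRUE),
               sample(c("G", "S", "A", "P", "T", "Q", "N", "V"), n_neu,
                      replace = TRUE))
  paste(sample(letters), collapse = "")
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(sequences, file) {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  aa <- Biostrings::AAStringSet(unlist(lapply(sequences, as.character)))
  Biostrings::writeXStringSet(aa, file)
  invisible(file)
}

#' Read sequences from FASTA
#'
#' @param file FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}
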