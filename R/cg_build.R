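AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))

#' Per-residue charge assignment
#'
#' Lys/Arg -> +1e, Asp/Glu -> -1e, all other residues 0 (His neutral).
#'
#' @param sequence One-letter amino-acid string or character vector.
#' @return Integer vector of charges in units of e.
#' @export
residue_charges <- function(sequence) {
  aa <- if (length(sequence) == 1L && nchar(sequence) > 1L)
    strsplit(sequence, "")[[1]] else sequence
  bad <- setdiff(unique(aa), unname(AA3TO1))
  if (length(bad))
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  ifelse(aa %in% c("K", "R"), 1L, ifelse(aa %in% c("D", "E"), -1L, 0L))
}

#' Load the packaged per-residue hydrophobicity scale
#'
#' The scale ships as a plain-text table
#' (`inst/extdata/hydrophobicity_scale_synthetic.tsv`). It is a *stand-in*:
#' a min-max normalisation of Kyte-Doolittle to `[0, 1]`, used in place of
#' the learned coarse-grained scale the model family employs (whose values
#' are published elsewhere and not redistributable here). Swap it by
#' passing any file with columns `residue`, `value` to
#' [force_field()].
#'
#' @param file Optional path to an alternative two-column TSV.
#' @return Named numeric vector keyed by one-letter residue code.
#' @export
hydrophobicity_scale <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "hydrophobicity_scale_synthetic.tsv",
                        package = "apichap", mustWork = TRUE)
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$value, tab$residue)
}

#' Coarse-grained bead chain
#'
#' One bead per residue at the C-alpha position. Folded chains carry
#' native geometry (and later native contacts); disordered chains carry
#' bonds only.
#'
#' @param sequence One-letter sequence.
#' @param positions N x 3 matrix of bead coordinates, Angstrom.
#' @param kind `"folded"` or `"disordered"`.
#' @param residue_numbering Author residue indices (e.g. tau 244-372).
#' @param hp_scale Hydrophobicity scale (named vector); defaults to the
#'   packaged stand-in scale.
#' @return A `cg_chain` object with `charges` and `hydrophobicity` filled.
#' @export
cg_chain <- function(sequence, positions, kind = c("folded", "disordered"),
                     residue_numbering = NULL, hp_scale = NULL) {
  kind <- match.arg(kind)
  aa <- strsplit(sequence, "")[[1]]
  positions <- as.matrix(positions)
  if (nrow(positions) != length(aa) || ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix matching the sequence length")
  if (is.null(residue_numbering)) residue_numbering <- seq_along(aa)
  if (length(residue_numbering) != length(aa))
    stop("residue_numbering length mismatch")
  if (is.null(hp_scale)) hp_scale <- hydrophobicity_scale()
  charges <- residue_charges(aa)
  structure(
    list(sequence = paste(aa, collapse = ""), aa = aa,
         positions = positions, kind = kind,
         charges = charges,
         hydrophobicity = unname(hp_scale[aa]),
         residue_numbering = residue_numbering),
    class = "cg_chain")
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("<cg_chain> %s, %d residues (%d..%d), net charge %+d\n",
              x$kind, length(x$aa), x$residue_numbering[1],
              x$residue_numbering[length(x$aa)], sum(x$charges)))
  invisible(x)
}

#' Read a C-alpha chain from a PDB file
#'
#' Minimal ATOM-record reader (no PDB package is available in this stack):
#' extracts CA atoms of one chain over a residue range and builds a folded
#' [cg_chain()].
#'
#' @param pdb_file Path to a PDB file with CA atoms.
#' @param chain_id PDB chain identifier (default `"A"`).
#' @param residue_range Length-2 integer vector `c(first, last)` in author
#'   numbering, or `NULL` for all residues of the chain.
#' @param hp_scale Optional hydrophobicity scale passed to [cg_chain()].
#' @return A folded `cg_chain`.
#' @export
load_structure <- function(pdb_file, chain_id = "A", residue_range = NULL,
                           hp_scale = NULL) {
  lines <- readLines(pdb_file)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (!length(atoms)) stop("no ATOM records in ", pdb_file)
  name <- trimws(substr(atoms, 13, 16))
  alt <- substr(atoms, 17, 17)
  keep <- name == "CA" & alt %in% c(" ", "A", "")
  atoms <- atoms[keep]
  ch <- substr(atoms, 22, 22)
  atoms <- atoms[ch == chain_id]
  if (!length(atoms)) stop("chain '", chain_id, "' not found or has no CA atoms")
  resno <- as.integer(substr(atoms, 23, 26))
  resna <- trimws(substr(atoms, 18, 20))
  xyz <- cbind(as.numeric(substr(atoms, 31, 38)),
               as.numeric(substr(atoms, 39, 46)),
               as.numeric(substr(atoms, 47, 54)))
  ord <- order(resno)
  resno <- resno[ord]; resna <- resna[ord]; xyz <- xyz[ord, , drop = FALSE]
  if (!is.null(residue_range)) {
    if (length(residue_range) != 2L || residue_range[2] < residue_range[1])
      stop("residue_range must be c(first, last) with first <= last")
    want <- seq(residue_range[1], residue_range[2])
    missing <- setdiff(want, resno)
    if (length(missing))
      stop("missing CA atoms for residues: ",
           paste(missing, collapse = ", "))
    sel <- resno %in% want
    resno <- resno[sel]; resna <- resna[sel]; xyz <- xyz[sel, , drop = FALSE]
  }
  seq1 <- AA3TO1[resna]
  if (anyNA(seq1))
    stop("unknown residue name(s): ",
         paste(unique(resna[is.na(seq1)]), collapse = ", "))
  cg_chain(paste(seq1, collapse = ""), xyz, kind = "folded",
           residue_numbering = resno, hp_scale = hp_scale)
}

#' Extract native contacts from a folded chain
#'
#' All residue pairs with sequence separation `|i - j| >= 4` whose
#' C-alpha distance in the reference structure is at most `cutoff` become
#' native contacts, each remembering its native distance `r0`.
#'
#' @param chain A folded `cg_chain` with reference coordinates.
#' @param cutoff Distance cutoff in Angstrom (default 9).
#' @return A `native_contacts` object: data frame `i`, `j` (chain-local,
#'   i < j), `r0`.
#' @export
build_native_contacts <- function(chain, cutoff = 9) {
  stopifnot(inherits(chain, "cg_chain"))
  if (chain$kind != "folded")
    stop("native contacts are only defined for folded chains")
  n <- nrow(chain$positions)
  dm <- as.matrix(stats::dist(chain$positions))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  sel <- idx[, 2] - idx[, 1] >= 4 & dm[idx] <= cutoff
  pairs <- data.frame(i = idx[sel, 1], j = idx[sel, 2], r0 = dm[idx][sel])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, cutoff = cutoff), class = "native_contacts")
}

#' @export
print.native_contacts <- function(x, ...) {
  cat(sprintf("<native_contacts> %d pairs (cutoff %.1f A)\n",
              nrow(x$pairs), x$cutoff))
  invisible(x)
}

#' Build a disordered chain with a self-avoiding initial conformation
#'
#' Grows a random walk with fixed 3.8 A bond lengths inside the box,
#' rejecting steps that approach previous beads closer than `min_sep`. No
#' angle or dihedral restraints are recorded: the chain samples its bond
#' and dihedral angles freely during dynamics.
#'
#' @param sequence One-letter sequence.
#' @param seed RNG seed (conformation is reproducible).
#' @param box Box edge, Angstrom; the walk starts near the box centre.
#' @param bond_length Bond length, Angstrom (3.8).
#' @param min_sep Self-avoidance distance, Angstrom.
#' @param residue_numbering Author numbering (e.g. `244:372`).
#' @param hp_scale Optional hydrophobicity scale.
#' @return A disordered `cg_chain`.
#' @export
build_idp_chain <- function(sequence, seed = 1L, box = 250,
                            bond_length = 3.8, min_sep = 3.5,
                            residue_numbering = NULL, hp_scale = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  residue_charges(aa)  # validates letters
  n <- length(aa)
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- rep(box / 2, 3)
  for (i in seq_len(n - 1L)) {
    placed <- FALSE
    for (try in 1:200) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pos[i, ] + bond_length * u
      prev <- pos[seq_len(max(i - 1L, 1L)), , drop = FALSE]
      d2 <- colSums((t(prev) - cand)^2)
      if (all(d2 >= min_sep^2) && all(cand > 0) && all(cand < box)) {
        pos[i + 1L, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("failed to grow a self-avoiding conformation; ",
                      "try another seed or a larger box")
  }
  cg_chain(sequence, pos, kind = "disordered",
           residue_numbering = residue_numbering, hp_scale = hp_scale)
}

#' Coarse-grained force field parameters
#'
#' Reduced-unit conventions: energies in units of the native-contact well
#' depth epsilon, lengths in Angstrom, kB = 1, bead mass = 1. The reduced
#' temperature 0.4 corresponds to about 300 K, which sets the
#' electrostatic prefactor `B_dh = 0.4 * Bjerrum length`.
#'
#' @param eps_native Native-contact well depth (reduced; 1).
#' @param eps_rep Excluded-volume strength (reduced).
#' @param sigma_rep Repulsion diameter, Angstrom.
#' @param dielectric Relative dielectric constant (80, water).
#' @param ionic_strength Ionic strength in mol/L (0.02).
#' @param temperature_K Physical temperature used for the Debye length and
#'   Bjerrum length (300 K).
#' @param t_reduced_room Reduced temperature corresponding to
#'   `temperature_K` (0.4); fixes the mapping of kBT to reduced energy.
#' @param lambda_hp Hydrophobic interaction strength (reduced).
#' @param sigma_hp Hydrophobic interaction length scale, Angstrom.
#' @param hp_scale_file Optional path to an alternative hydrophobicity
#'   scale table.
#' @param bond_k Bond force constant, reduced/A^2.
#' @param angle_k Angle force constant, reduced/rad^2 (folded chains).
#' @param dihedral_k Dihedral force constant, reduced (folded chains).
#' @param wall_k Reflecting-wall force constant (used when `pbc = FALSE`).
#' @return A `force_field` object, including derived `lambda_d` (Debye
#'   length, A) and `B_dh` (electrostatic prefactor, reduced * A).
#' @export
force_field <- function(eps_native = 1, eps_rep = 1, sigma_rep = 4,
                        dielectric = 80, ionic_strength = 0.02,
                        temperature_K = 300, t_reduced_room = 0.4,
                        lambda_hp = 0.5, sigma_hp = 5,
                        hp_scale_file = NULL,
                        bond_k = 100, angle_k = 20, dihedral_k = 1,
                        wall_k = 10) {
  if (ionic_strength <= 0) stop("ionic_strength must be positive")
  vals <- c(eps_native, eps_rep, lambda_hp, bond_k, angle_k, dihedral_k)
  if (any(vals < 0)) stop("interaction strengths must be >= 0")
  lB <- bjerrum_length(dielectric, temperature_K)
  structure(
    list(eps_native = eps_native, eps_rep = eps_rep, sigma_rep = sigma_rep,
         dielectric = dielectric, ionic_strength = ionic_strength,
         temperature_K = temperature_K, t_reduced_room = t_reduced_room,
         lambda_hp = lambda_hp, sigma_hp = sigma_hp,
         hp_scale = hydrophobicity_scale(hp_scale_file),
         bond_k = bond_k, angle_k = angle_k, dihedral_k = dihedral_k,
         wall_k = wall_k,
         bjerrum = lB,
         lambda_d = debye_length(ionic_strength, dielectric, temperature_K),
         B_dh = t_reduced_room * lB),
    class = "force_field")
}

#' Bjerrum length
#'
#' `l_B = e^2 / (4 pi eps0 eps_r kB T)`, in Angstrom (about 7.1 A for
#' water at 300 K).
#'
#' @param dielectric Relative dielectric constant.
#' @param temperature_K Temperature, K.
#' @return Bjerrum length in Angstrom.
#' @export
bjerrum_length <- function(dielectric = 80, temperature_K = 300) {
  # e^2/(4 pi eps0 kB) = 1.671009e5 A*K
  1.671009e5 / (dielectric * temperature_K)
}

#' Debye screening length
#'
#' `kappa^2 = 8 pi l_B n` for a 1:1 electrolyte with ion number density
#' `n = N_A * I`; about 21.5 A at 0.02 M in water at 300 K.
#'
#' @param ionic_strength mol/L (> 0).
#' @param dielectric Relative dielectric constant.
#' @param temperature_K Temperature, K.
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(ionic_strength = 0.02, dielectric = 80,
                         temperature_K = 300) {
  if (ionic_strength <= 0) stop("ionic_strength must be positive")
  lB <- bjerrum_length(dielectric, temperature_K)
  n_A3 <- ionic_strength * 6.02214076e-4  # ions per cubic Angstrom
  1 / sqrt(8 * pi * lB * n_A3)
}

#' Simulation run parameters
#'
#' @param t_reduced Reduced temperature (0.4, about 300 K).
#' @param dt Time step, reduced time units (0.005; stands in for the
#'   production models' 2 fs step — coarse-grained models have no literal
#'   femtoseconds).
#' @param friction Langevin friction, 1/reduced-time (0.1; low friction
#'   accelerates conformational sampling).
#' @param n_steps Number of integrator steps (production scale 1e8;
#'   desk-scale default 1e5).
#' @param save_interval Save a frame every this many steps.
#' @param box Cubic box edge, Angstrom (250).
#' @param pbc Periodic boundaries with minimum image (default) or, if
#'   `FALSE`, reflecting harmonic walls.
#' @param n_replicas Number of independent replicas (production scale 10).
#' @param seed Master seed; replica seeds are derived from it.
#' @return A `sim_params` object.
#' @export
sim_params <- function(t_reduced = 0.4, dt = 0.005, friction = 0.1,
                       n_steps = 1e5, save_interval = 100, box = 250,
                       pbc = TRUE, n_replicas = 1L, seed = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  structure(list(t_reduced = t_reduced, dt = dt, friction = friction,
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 box = box, pbc = isTRUE(pbc),
                 n_replicas = as.integer(n_replicas),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Assemble a simulation system from chains
#'
#' Builds the combined topology: harmonic bonds on consecutive beads of
#' every chain (at native distances for folded chains, 3.8 A for
#' disordered ones); angle and dihedral restraints to native values for
#' folded chains only; native Lennard-Jones 12-10 contacts within folded
#' chains; and a nonbonded pair list (all pairs except same-chain
#' neighbours with `|i - j| <= 3`) carrying charge and hydrophobicity
#' products for Debye-Hueckel and hydrophobic terms. Inter-chain pairs
#' never carry a native term.
#'
#' @param chains List of `cg_chain` objects.
#' @param ff A [force_field()].
#' @param contacts Optional list of `native_contacts`, parallel to
#'   `chains` (`NULL` entries for disordered chains). Built automatically
#'   (9 A cutoff) for folded chains when omitted.
#' @param box Box edge, Angstrom.
#' @param pbc Periodic boundaries flag.
#' @return A `cg_system`: chains, concatenated state, topology arrays
#'   ready for the C++ kernels.
#' @export
cg_system <- function(chains, ff = force_field(), contacts = NULL,
                      box = 250, pbc = TRUE) {
  stopifnot(all(vapply(chains, inherits, logical(1), "cg_chain")))
  n_per <- vapply(chains, function(ch) nrow(ch$positions), integer(1))
  offset <- c(0L, cumsum(n_per))[seq_along(chains)]
  n <- sum(n_per)
  pos <- do.call(rbind, lapply(chains, function(ch) ch$positions))
  charges <- unlist(lapply(chains, function(ch) ch$charges))
  hydro <- unlist(lapply(chains, function(ch) ch$hydrophobicity))
  chain_id <- rep(seq_along(chains), n_per)

  if (is.null(contacts)) {
    contacts <- lapply(chains, function(ch)
      if (ch$kind == "folded") build_native_contacts(ch) else NULL)
  }

  bonds <- NULL; bond_r0 <- numeric(0)
  angles <- NULL; angle_t0 <- numeric(0)
  dihedrals <- NULL; dihedral_p0 <- numeric(0)
  native <- NULL
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    off <- offset[ci]
    nb <- n_per[ci]
    if (nb >= 2L) {
      bi <- cbind(off + seq_len(nb - 1L), off + seq_len(nb - 1L) + 1L)
      r0 <- if (ch$kind == "folded")
        sqrt(rowSums((ch$positions[-1, , drop = FALSE] -
                      ch$positions[-nb, , drop = FALSE])^2))
      else rep(3.8, nb - 1L)
      bonds <- rbind(bonds, bi); bond_r0 <- c(bond_r0, r0)
    }
    if (ch$kind == "folded" && nb >= 3L) {
      ai <- cbind(off + seq_len(nb - 2L), off + seq_len(nb - 2L) + 1L,
                  off + seq_len(nb - 2L) + 2L)
      t0 <- vapply(seq_len(nb - 2L), function(i)
        bead_angle(ch$positions[i, ], ch$positions[i + 1L, ],
                   ch$positions[i + 2L, ]), numeric(1))
      angles <- rbind(angles, ai); angle_t0 <- c(angle_t0, t0)
    }
    if (ch$kind == "folded" && nb >= 4L) {
      di <- cbind(off + seq_len(nb - 3L), off + seq_len(nb - 3L) + 1L,
                  off + seq_len(nb - 3L) + 2L, off + seq_len(nb - 3L) + 3L)
      p0 <- vapply(seq_len(nb - 3L), function(i)
        bead_dihedral(ch$positions[i, ], ch$positions[i + 1L, ],
                      ch$positions[i + 2L, ], ch$positions[i + 3L, ]),
        numeric(1))
      dihedrals <- rbind(dihedrals, di); dihedral_p0 <- c(dihedral_p0, p0)
    }
    nc <- contacts[[ci]]
    if (!is.null(nc) && nrow(nc$pairs)) {
      native <- rbind(native, cbind(off + nc$pairs$i, off + nc$pairs$j,
                                    nc$pairs$r0))
    }
  }

  # nonbonded pair list: exclude same-chain |i-j| <= 3
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- chain_id[idx[, 1]] == chain_id[idx[, 2]]
  close <- same & (idx[, 2] - idx[, 1] <= 3L)
  pr <- idx[!close, , drop = FALSE]
  pkey <- pr[, 1] * (n + 1) + pr[, 2]
  is_native <- integer(nrow(pr))
  pr_r0 <- numeric(nrow(pr))
  if (!is.null(native)) {
    nkey <- native[, 1] * (n + 1) + native[, 2]
    m <- match(pkey, nkey)
    hit <- !is.na(m)
    is_native[hit] <- 1L
    pr_r0[hit] <- native[m[hit], 3]
  }

  structure(
    list(chains = chains, contacts = contacts, ff = ff,
         n = n, positions = pos, charges = charges, hydrophobicity = hydro,
         chain_id = chain_id, offset = offset, n_per = n_per,
         topo = list(
           n = n,
           bonds = matrix(as.integer((if (is.null(bonds)) integer(0)
                                      else bonds) - 1L), ncol = 2),
           bond_r0 = bond_r0, bond_k = ff$bond_k,
           angles = matrix(as.integer((if (is.null(angles)) integer(0)
                                       else angles) - 1L), ncol = 3),
           angle_t0 = angle_t0, angle_k = ff$angle_k,
           dihedrals = matrix(as.integer((if (is.null(dihedrals)) integer(0)
                                          else dihedrals) - 1L), ncol = 4),
           dihedral_p0 = dihedral_p0, dihedral_k = ff$dihedral_k,
           pairs = matrix(as.integer(pr - 1L), ncol = 2),
           pair_native = is_native, pair_r0 = pr_r0,
           pair_qq = as.numeric(charges[pr[, 1]] * charges[pr[, 2]]),
           pair_hh = as.numeric(hydro[pr[, 1]] * hydro[pr[, 2]]),
           eps_native = ff$eps_native, eps_rep = ff$eps_rep,
           sigma_rep = ff$sigma_rep, lambda_hp = ff$lambda_hp,
           sigma_hp = ff$sigma_hp, B_dh = ff$B_dh, lambda_d = ff$lambda_d,
           box = box, pbc = pbc, wall_k = ff$wall_k)),
    class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("<cg_system> %d chains, %d beads, %d native contacts, %d nonbonded pairs\n",
              length(x$chains), x$n, sum(x$topo$pair_native),
              nrow(x$topo$pairs)))
  invisible(x)
}

bead_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

bead_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}
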