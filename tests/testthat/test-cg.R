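test_that("load_structure reads CA beads with charges and numbering", {
  td <- withr::local_tempdir()
  pdb <- file.path(td, "helix.pdb")
  gen_mini_domain(20, "helix", seed = 1, file = pdb)
  ch <- load_structure(pdb)
  expect_length(ch$aa, 20)
  d <- sqrt(rowSums(diff(ch$positions)^2))
  expect_true(all(d > 3.7 & d < 3.9))
  expect_error(load_structure(pdb, residue_range = c(10, 9)), "first <= last")
  expect_error(load_structure(pdb, residue_range = c(15, 25)), "missing CA")
  expect_error(load_structure(pdb, chain_id = "Z"), "chain 'Z'")
  # charge rule on an explicit sequence
  kr <- cg_chain("KRDEG", helix_positions(5), kind = "disordered")
  expect_equal(kr$charges, c(1L, 1L, -1L, -1L, 0L))
})

test_that("build_native_contacts finds pairs by distance and separation", {
  # two beads 100 A apart padded into a chain: no contacts
  far <- cg_chain("AAAAAAAA",
                  cbind(c(0, 3.8, 7.6, 11.4, 100, 103.8, 107.6, 111.4),
                        0, 0), kind = "folded")
  expect_equal(nrow(build_native_contacts(far, cutoff = 8)$pairs), 0L)
  # hand-countable fixture: a chain bent so exactly 3 (i, i+4..) pairs
  # fall under the cutoff
  th <- seq(0, by = pi / 5, length.out = 10)
  pos <- cbind(6 * cos(th), 6 * sin(th), 0)   # arc, spacing ~3.7 A
  arc <- cg_chain(paste(rep("A", 10), collapse = ""), pos, kind = "folded")
  nc7 <- build_native_contacts(arc, cutoff = 7)
  dm <- as.matrix(dist(pos))
  want <- which(upper.tri(dm) & dm <= 7 &
                  abs(row(dm) - col(dm)) >= 4, arr.ind = TRUE)
  expect_equal(nrow(nc7$pairs), nrow(want))
  expect_equal(nc7$pairs$r0,
               dm[cbind(nc7$pairs$i, nc7$pairs$j)])
  # cutoff monotonicity: contacts(7) subset of contacts(9)
  nc9 <- build_native_contacts(arc, cutoff = 9)
  key <- function(p) paste(p$i, p$j)
  expect_true(all(key(nc7$pairs) %in% key(nc9$pairs)))
  expect_error(build_native_contacts(
    cg_chain("AAAA", helix_positions(4), kind = "disordered")), "folded")
})

test_that("build_idp_chain grows valid self-avoiding conformations", {
  tau <- tau4r_sequence()
  ch <- build_idp_chain(tau, seed = 5, residue_numbering = 244:372)
  expect_length(ch$aa, 129)
  expect_equal(sum(ch$charges),
               sum(strsplit(tau, "")[[1]] %in% c("K", "R")) -
                 sum(strsplit(tau, "")[[1]] %in% c("D", "E")))
  d <- sqrt(rowSums(diff(ch$positions)^2))
  expect_equal(d, rep(3.8, 128), tolerance = 1e-9)
  two <- build_idp_chain("GS", seed = 1)
  expect_equal(sqrt(sum(diff(two$positions)^2)), 3.8, tolerance = 1e-9)
  a <- build_idp_chain("GSGSGSGS", seed = 1)
  b <- build_idp_chain("GSGSGSGS", seed = 2)
  expect_false(isTRUE(all.equal(a$positions, b$positions)))
  expect_error(build_idp_chain("GSB", seed = 1), "invalid residue")
})

test_that("debye_huckel_energy matches the closed-form screening length", {
  ff <- force_field()
  expect_equal(debye_huckel_energy(0, 1, 5, ff), 0)
  expect_equal(debye_huckel_energy(1, 1, 5, ff),
               -debye_huckel_energy(1, -1, 5, ff))
  expect_error(debye_huckel_energy(1, 1, 0, ff), "positive")
  # independent closed-form oracle from physical constants:
  # lambda_D = sqrt(eps0*epsr*kB*T / (2*NA*e^2*I))
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23; e <- 1.602176634e-19
  NA_ <- 6.02214076e23
  lam <- sqrt(eps0 * 80 * kB * 300 / (2 * NA_ * e^2 * 0.02 * 1000)) * 1e10
  expect_equal(ff$lambda_d, lam, tolerance = 1e-4)
  # decay follows exp(-r/lambda)/r
  r <- c(5, 10, 20)
  u <- debye_huckel_energy(1, 1, r, ff)
  expect_equal(u / u[1], exp(-r / lam) / r / (exp(-5 / lam) / 5),
               tolerance = 1e-4)
})

test_that("forces are the exact negative gradient of the energy", {
  sys <- mini_system()
  set.seed(9)
  worst <- 0
  for (cfg in 1:10) {
    x <- sys$positions + matrix(rnorm(sys$n * 3, 0, 0.15), sys$n, 3)
    fe <- compute_forces(sys, x)
    idx <- cbind(sample(sys$n, 6, replace = TRUE), sample(3, 6, TRUE))
    num <- numeric_forces(sys, x, idx = idx)
    worst <- max(worst, max(abs(fe$forces[idx] - num)))
  }
  expect_lt(worst, 1e-4)
})

test_that("native configuration sits at the native-term minimum", {
  dom <- gen_mini_domain(24, "helix_hairpin", seed = 2)
  sys <- cg_system(list(dom), force_field(), box = 250, pbc = TRUE)
  e0 <- compute_forces(sys)$energies[["native"]]
  nc <- sys$contacts[[1]]$pairs
  set.seed(4)
  for (r in 1:5) {
    k <- sample(nrow(nc), 1)
    x <- sys$positions
    dirv <- x[nc$j[k], ] - x[nc$i[k], ]
    x[nc$j[k], ] <- x[nc$j[k], ] + 0.4 * dirv / sqrt(sum(dirv^2))
    expect_gt(compute_forces(sys, x)$energies[["native"]], e0)
  }
  # isolated neutral bead feels nothing
  lone <- cg_chain("G", matrix(c(10, 10, 10), 1), kind = "disordered")
  sys1 <- cg_system(list(lone), force_field(), contacts = list(NULL),
                    box = 100)
  expect_equal(compute_forces(sys1)$forces, matrix(0, 1, 3))
})

test_that("langevin_step is deterministic and inert at zero T/force", {
  lone <- cg_chain("G", matrix(c(10, 10, 10), 1), kind = "disordered")
  sys1 <- cg_system(list(lone), force_field(), contacts = list(NULL),
                    box = 100)
  st <- list(positions = lone$positions, velocities = matrix(0, 1, 3))
  out <- langevin_step(sys1, st, sim_params(t_reduced = 0, friction = 0))
  expect_equal(out$positions, st$positions)
  expect_equal(out$velocities, st$velocities)
  sys <- mini_system(idp = FALSE)
  st2 <- list(positions = sys$positions,
              velocities = matrix(0, sys$n, 3))
  set.seed(12); a <- langevin_step(sys, st2, sim_params())
  set.seed(12); b <- langevin_step(sys, st2, sim_params())
  expect_identical(a, b)
})

test_that("bonded dimer satisfies equipartition in kinetic and bond energy", {
  dim2 <- cg_chain("GG", rbind(c(50, 50, 50), c(53.8, 50, 50)),
                   kind = "disordered")
  sys <- cg_system(list(dim2), force_field(), contacts = list(NULL),
                   box = 100)
  # strong coupling + long run: the single vibrational mode equilibrates
  # slowly, so energy statistics need ~1e6 steps
  tr <- run_simulation(sys, sim_params(n_steps = 1e6, save_interval = 50,
                                       friction = 2, dt = 0.003,
                                       seed = 8))[[1]]
  nf <- nrow(tr$energies)
  late <- seq(nf %/% 5, nf)
  # <KE>/dof = T/2; <k(r-r0)^2> = T/2 (one quadratic dof)
  expect_equal(mean(tr$energies$kinetic[late]) / (3 * 2), 0.2,
               tolerance = 0.05)
  expect_equal(mean(tr$energies$bond[late]), 0.2, tolerance = 0.05)
})

test_that("run_simulation honours frames, seeds, stability and equipartition", {
  sys <- mini_system(idp = FALSE, box = 250)
  # n_steps = 0 records the initial frame only
  tr0 <- run_simulation(sys, sim_params(n_steps = 0))[[1]]
  expect_equal(dim(tr0$frames)[1], 1L)
  expect_equal(matrix(tr0$frames[1, , ], ncol = 3), unname(sys$positions))

  trajs <- run_simulation(sys, sim_params(n_steps = 1e5,
                                          save_interval = 100,
                                          n_replicas = 2, seed = 11))
  expect_length(trajs, 2)
  expect_equal(dim(trajs[[1]]$frames)[1], 1000L)
  # distinct replica seeds give distinct trajectories
  expect_false(isTRUE(all.equal(trajs[[1]]$frames, trajs[[2]]$frames)))
  tr <- trajs[[1]]
  late <- 500:1000
  # equipartition at T = 0.4
  expect_equal(mean(tr$energies$kinetic[late]) / (3 * sys$n), 0.2,
               tolerance = 0.05)
  # folded fixture stays folded: Q > 0.8 over the final half
  expect_gt(mean(native_fraction(tr)[late]), 0.8)
  # bond lengths stay within 1% of 3.8 A on average
  nb <- sys$n
  dlast <- sqrt(rowSums((tr$frames[1000, -1, ] - tr$frames[1000, -nb, ])^2))
  bmean <- mean(vapply(late, function(f)
    mean(sqrt(rowSums((tr$frames[f, -1, ] - tr$frames[f, -nb, ])^2))),
    numeric(1)))
  expect_equal(bmean / mean(sys$topo$bond_r0), 1, tolerance = 0.01)
  # byte determinism
  again <- run_simulation(sys, sim_params(n_steps = 1e5,
                                          save_interval = 100,
                                          n_replicas = 2, seed = 11))
  expect_identical(serialize(trajs[[1]]$frames, NULL),
                   serialize(again[[1]]$frames, NULL))
})

test_that("frictionless integration conserves energy to <0.1% over 1e4 steps", {
  sys <- mini_system(idp = FALSE)
  tr <- run_simulation(sys, sim_params(n_steps = 1e4, save_interval = 10,
                                       friction = 0, seed = 4))[[1]]
  tot <- tr$energies$total
  expect_lt(max(abs(tot - tot[1])) / abs(tot[1]), 0.001)
})

test_that("opposite charges end up closer than like charges", {
  mk <- function(aa2) {
    c1 <- cg_chain(substr(aa2, 1, 1), matrix(c(25, 30, 30), 1),
                   kind = "disordered")
    c2 <- cg_chain(substr(aa2, 2, 2), matrix(c(35, 30, 30), 1),
                   kind = "disordered")
    cg_system(list(c1, c2), force_field(), contacts = list(NULL, NULL),
              box = 60, pbc = TRUE)
  }
  msep <- function(sys) {
    tr <- run_simulation(sys, sim_params(n_steps = 3e4, save_interval = 20,
                                         box = 60, seed = 21))[[1]]
    dd <- tr$frames[, 1, ] - tr$frames[, 2, ]
    dd <- dd - 60 * round(dd / 60)
    mean(sqrt(rowSums(dd^2)))
  }
  expect_lt(msep(mk("KD")), msep(mk("KK")))
})
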