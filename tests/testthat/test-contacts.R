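# fixed two-chain system with hand-placeable frames
contact_fixture <- function() {
  api <- cg_chain("AAAA", cbind(c(0, 3.8, 7.6, 11.4), 0, 0),
                  kind = "folded", residue_numbering = 101:104)
  tau <- cg_chain("GGG", cbind(c(0, 3.8, 7.6), 5, 0),
                  kind = "disordered", residue_numbering = 245:247)
  cg_system(list(api, tau), force_field(), contacts = list(NULL, NULL),
            box = 250, pbc = FALSE)
}

frames_from <- function(sys, n_frames = 1) {
  fr <- array(0, c(n_frames, sys$n, 3))
  for (f in seq_len(n_frames)) fr[f, , ] <- sys$positions
  fr
}

test_that("contact probabilities count frames under the cutoff exactly", {
  sys <- contact_fixture()
  # beads fixed 5 A apart -> probability 1; 7 A apart -> 0 at 6 A cutoff
  tr <- trajectory_from_frames(frames_from(sys, 3), sys)
  cm <- contact_probabilities(list(tr), cutoff = 6, equil_frac = 0)
  expect_equal(unname(cm$matrix[1, 1]), 1)   # 245 vs 101: 5 A
  cm7 <- contact_probabilities(list(tr), cutoff = 5.0001, equil_frac = 0)
  expect_equal(unname(cm7$matrix[1, 2]),  0) # 245 vs 102: 6.3 A
  # hand-built 4-frame trajectory: pair under cutoff in 2 of 4 frames
  fr <- frames_from(sys, 4)
  fr[3, 5, 2] <- 100; fr[4, 5, 2] <- 100    # move tau bead 245 away
  tr4 <- trajectory_from_frames(fr, sys)
  cm4 <- contact_probabilities(list(tr4), cutoff = 6, equil_frac = 0)
  expect_equal(unname(cm4$matrix["245", "101"]), 0.5)
  expect_equal(unname(cm4$matrix["246", "102"]), 1)
  expect_error(contact_probabilities(list()), "empty")
})

test_that("probabilities are invariant to frame and replica order, pooling is frame-weighted", {
  sys <- contact_fixture()
  set.seed(44)
  fr1 <- frames_from(sys, 5) + array(rnorm(5 * sys$n * 3), c(5, sys$n, 3))
  fr2 <- frames_from(sys, 3) + array(rnorm(3 * sys$n * 3), c(3, sys$n, 3))
  t1 <- trajectory_from_frames(fr1, sys)
  t2 <- trajectory_from_frames(fr2, sys)
  pooled <- contact_probabilities(list(t1, t2), equil_frac = 0)
  swapped <- contact_probabilities(list(t2, t1), equil_frac = 0)
  expect_equal(pooled$matrix, swapped$matrix)
  # frame-weighted average of per-replica maps
  m1 <- contact_probabilities(list(t1), equil_frac = 0)$matrix
  m2 <- contact_probabilities(list(t2), equil_frac = 0)$matrix
  expect_equal(pooled$matrix, (5 * m1 + 3 * m2) / 8)
  # frame reordering
  t1r <- trajectory_from_frames(fr1[5:1, , , drop = FALSE], sys)
  expect_equal(contact_probabilities(list(t1r), equil_frac = 0)$matrix, m1)
  # cutoff monotonicity
  lo <- contact_probabilities(list(t1), cutoff = 5, equil_frac = 0)$matrix
  hi <- contact_probabilities(list(t1), cutoff = 8, equil_frac = 0)$matrix
  expect_true(all(hi >= lo))
})

test_that("bin_contacts aggregates 3x3 blocks with max or mean", {
  u <- contact_map(matrix(0.2, 6, 6))
  b <- bin_contacts(u, 3, rule = "mean")
  expect_equal(unname(b$matrix), matrix(0.2, 2, 2))
  expect_equal(bin_contacts(u, 1)$matrix, u$matrix)  # identity
  # constructed block separating the two rules: max 0.5, mean ~0.1722
  m <- matrix(0.1, 3, 3); m[2, 2] <- 0.5; m[1, 3] <- 0.15
  cmap <- contact_map(m)
  expect_equal(unname(bin_contacts(cmap, 3, "max")$matrix[1, 1]), 0.5)
  expect_equal(unname(bin_contacts(cmap, 3, "mean")$matrix[1, 1]), mean(m))
  expect_error(bin_contacts(u, 0), "bin_size")
  # binned entries bounded by their block for mean; equal block max for max
  set.seed(3)
  big <- contact_map(matrix(runif(81), 9, 9))
  bm <- bin_contacts(big, 3, "mean")$matrix
  bx <- bin_contacts(big, 3, "max")$matrix
  for (i in 1:3) for (j in 1:3) {
    blk <- big$matrix[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
    expect_gte(bm[i, j], min(blk)); expect_lte(bm[i, j], max(blk))
    expect_equal(bx[i, j], max(blk))
  }
  # trailing partial bins are kept
  odd <- bin_contacts(contact_map(matrix(0.3, 7, 5)), 3)
  expect_equal(dim(odd$matrix), c(3L, 2L))
})

test_that("interface_segments recovers painted tau regions exactly", {
  tau_no <- 244:372
  m <- matrix(0, 129, 30)
  m[match(245:272, tau_no), 5] <- 0.45
  m[match(331:339, tau_no), 12] <- 0.5
  cmap <- contact_map(m, tau_numbering = tau_no, api_numbering = 1:30)
  segs <- interface_segments(cmap, threshold = 0.2)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start[order(segs$start)], c(245, 331))
  expect_equal(segs$end[order(segs$start)], c(272, 339))
  expect_equal(segs$peak[1], 0.5)         # ranked by peak
  expect_equal(segs$start[1], 331)
  # all-zero map and single hot row
  expect_equal(nrow(interface_segments(
    contact_map(matrix(0, 129, 30), tau_no, 1:30), 0.2)), 0L)
  m1 <- matrix(0, 129, 30); m1[match(250, tau_no), 3] <- 0.9
  one <- interface_segments(contact_map(m1, tau_no, 1:30), 0.2)
  expect_equal(c(one$start, one$end), c(250, 250))
  expect_error(interface_segments(cmap, 0), "threshold")
  expect_error(interface_segments(cmap, 1.5), "threshold")
})

test_that("segments from a binned map carry bin-resolved author ranges", {
  tau_no <- 244:372
  m <- matrix(0, 129, 30)
  m[match(245:272, tau_no), 5] <- 0.45
  cmap <- bin_contacts(contact_map(m, tau_no, 1:30), 3)
  segs <- interface_segments(cmap, threshold = 0.2)
  expect_equal(nrow(segs), 1L)
  # bins are 3 residues wide so the call can overshoot by at most 2
  expect_lte(abs(segs$start - 245), 2)
  expect_lte(abs(segs$end - 272), 2)
})

test_that("contact map TSV and BED round-trip through text", {
  td <- withr::local_tempdir()
  m <- contact_map(matrix(c(0.1, 0.5, 0, 0.25), 2, 2), 244:245, 10:11)
  f <- file.path(td, "map.tsv")
  write_contact_map(m, f)
  back <- as.matrix(utils::read.delim(f, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(m$matrix))
  expect_equal(rownames(back), c("244", "245"))
  segs <- interface_segments(m, 0.2)
  bed <- file.path(td, "segs.bed")
  write_segments_bed(segs, bed)
  expect_match(readLines(bed)[1], "^tau\t")
})
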