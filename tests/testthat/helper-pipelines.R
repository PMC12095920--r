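run_kinetics_pipeline <- function(dir, seed = 5) {
  plate_dir <- file.path(dir, "plate")
  apichap_main(c("synth", "plate", "--out", plate_dir, "--noise", "0.02",
                 "--replicates", "6", "--seed", as.character(seed)))
  apichap_main(c("kinetics", "fit",
                 "--plate", file.path(plate_dir, "plate.csv"),
                 "--meta", file.path(plate_dir, "meta.csv"),
                 "--out", file.path(dir, "fits.csv")))
  apichap_main(c("kinetics", "scaling", "--fits", file.path(dir, "fits.csv"),
                 "--out", file.path(dir, "scaling.csv")))
  apichap_main(c("synth", "series", "--model", "fragmentation",
                 "--noise", "0.01", "--seed", as.character(seed),
                 "--out", file.path(dir, "curves.csv")))
  suppressMessages(
    apichap_main(c("mech", "compare", "--curves", file.path(dir, "curves.csv"),
                   "--seed", "3", "--out", file.path(dir, "mre.csv"))))
  invisible(dir)
}

run_cg_pipeline <- function(dir, steps = 2e4, seed = 7) {
  apichap_main(c("synth", "domain", "--n", "24", "--geometry",
                 "helix_hairpin", "--seed", "2",
                 "--out", file.path(dir, "domain.pdb")))
  apichap_main(c("synth", "idp", "--length", "20", "--charge", "2",
                 "--seed", "3", "--out", file.path(dir, "idp.fasta")))
  apichap_main(c("cg", "run", "--structure", file.path(dir, "domain.pdb"),
                 "--idp", file.path(dir, "idp.fasta"),
                 "--out", file.path(dir, "runs"),
                 "--steps", format(steps, scientific = FALSE),
                 "--replicas", "2", "--seed", as.character(seed),
                 "--box", "80"))
  apichap_main(c("contacts", "--trajs", file.path(dir, "runs"),
                 "--out", file.path(dir, "heatmap.tsv"),
                 "--segments", file.path(dir, "segs.bed"),
                 "--threshold", "0.2"))
  invisible(dir)
}

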