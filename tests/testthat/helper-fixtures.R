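# shared fixtures, all generated in code

# small marker panel with exact dosages
toy_markers <- function() {
  m <- matrix(
    c(0, 2, 1,
      2, 0, 1,
      0, 1, 2,
      1, 1, 0),
    nrow = 3, ncol = 4,
    dimnames = list(c("A", "B", "C"), paste0("M", 1:4))
  )
  marker_matrix(m, platform = "G2")
}

# complete env x line phenotype grid with arbitrary deterministic values
toy_pheno <- function(n_lines = 4, n_env = 3, trait = "PH") {
  envs <- paste0("E", seq_len(n_env))
  lines <- paste0("L", seq_len(n_lines))
  grid <- tidyr::expand_grid(env = envs, line = lines)
  grid$trait <- trait
  grid$value <- sin(seq_len(nrow(grid))) * 2 + 10
  grid
}

# identity GRM over the given lines
identity_grm <- function(lines) {
  g <- diag(length(lines))
  dimnames(g) <- list(lines, lines)
  structure(list(G = g, lines = lines, p = length(lines)),
            class = "genomic_relationship")
}

# small simulated dataset for fitting tests
small_sim_config <- function(n_lines = 30, n_env = 5, seed = 7,
                             n_markers = 300, ...) {
  design <- tidyr::expand_grid(
    year = 2012L + seq_len(ceiling(n_env / 2)),
    location = c("IARI", "ICRISAT")
  )[seq_len(n_env), ]
  design$management <- "Irrigated"
  sim_config(
    n_lines = n_lines,
    n_markers = c(G2 = n_markers),
    missing_rate = c(G2 = 0),
    trial_design = design,
    traits = "PH",
    seed = seed,
    ...
  )
}

small_dataset <- function(...) {
  simulate_dataset(small_sim_config(...))
}

# write a small VCF fixture with one triallelic site among five
write_vcf_fixture <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t0/1\t./.\t0/0",
    "1\t300\t.\tA\tC,G\t.\tPASS\t.\tGT\t0/1\t1/2\t0/0",
    "2\t100\t.\tT\tA\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1",
    "2\t250\t.\tC\tG\t.\tPASS\t.\tGT\t0|1\t0/0\t.|.",
    NULL
  )
  writeLines(lines, path)
  path
}
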