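# Helpers to build small FASTA fixtures in code.
write_fasta <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(h)
    c(paste0(">", h), records[[h]]))), path)
  path
}

gene_from_codons <- function(...) paste0(c(...), collapse = "")

test_that("genome loading filters CDS and flags ribosomal proteins", {
  good <- gene_from_codons("ATG", rep(c("AAA", "TTT", "GGT", "CTG"), 6), "TAA")
  recs <- c(
    setNames(rep(good, 12),
             sprintf("r%02d 30S ribosomal protein S%d", 1:12, 1:12)),
    setNames(rep(good, 5), sprintf("g%02d hypothetical protein", 1:5)),
    badlen = substr(good, 1, 76),                                   # not /3
    amb = gene_from_codons("ATG", "AAN", "TTT", "TAA"),             # ambiguity
    stopmid = gene_from_codons("ATG", "TAA", "TTT", "TAA")          # premature stop
  )
  tf <- withr::local_tempfile(fileext = ".fna")
  write_fasta(recs, tf)
  expect_message(g <- load_genome(tf, genome_id = "toy"), "dropped 3")
  expect_length(g$cds, 17)
  expect_equal(sum(g$ribosomal), 12)
  expect_equal(g$n_dropped, 3)

  empty <- withr::local_tempfile(fileext = ".fna")
  writeLines(character(0), empty)
  expect_error(load_genome(empty), class = "phygrow_format_error")
})

test_that("ribosomal annotation can come from a GFF3 product table", {
  good <- gene_from_codons("ATG", rep(c("AAA", "TTT"), 10), "TAA")
  tf <- withr::local_tempfile(fileext = ".fna")
  write_fasta(setNames(rep(good, 3), c("c1", "c2", "c3")), tf)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tCDS\t1\t42\t.\t+\t0\tID=c1;product=50S ribosomal protein L1",
    "chr\tsrc\tCDS\t50\t90\t.\t+\t0\tID=c2;product=DNA polymerase",
    "chr\tsrc\tCDS\t95\t130\t.\t+\t0\tID=c3;product=30S Ribosomal Protein S4"
  ), gff)
  g <- load_genome(tf, annotations = gff)
  expect_equal(unname(g$ribosomal), c(TRUE, FALSE, TRUE))
})

test_that("MILC matches its defining formula", {
  # reference: two-codon families at 50/50 usage
  ref <- c(AAA = 0.5, AAG = 0.5, TTT = 0.5, TTC = 0.5)
  # gene usage identical to the reference -> MILC reduces to -C
  counts_eq <- c(AAA = 5, AAG = 5, TTT = 10, TTC = 10)
  L <- 30
  C_corr <- ((2 - 1) + (2 - 1)) / L
  expect_equal(milc(counts_eq, ref), -C_corr, tolerance = 1e-12)

  # biased family: counts (9, 1) against (0.5, 0.5), second family even.
  # Independent direct evaluation of M = 2 * sum o_c ln(f_c / g_c):
  counts_bias <- c(AAA = 9, AAG = 1, TTT = 10, TTC = 10)
  M_lys <- 2 * (9 * log((9 / 10) / 0.5) + 1 * log((1 / 10) / 0.5))
  expect_equal(milc(counts_bias, ref), M_lys / 30 - C_corr, tolerance = 1e-12)

  # gene of only single-codon families has no degenerate information
  expect_error(milc(c(ATG = 5, TGG = 3), ref), class = "phygrow_domain_error")
  # observed codon with zero reference frequency is rejected
  expect_error(milc(c(AAA = 3, AAG = 1), c(AAA = 1, AAG = 0)),
               class = "phygrow_domain_error")
})

test_that("MILC is insensitive to gene length by construction", {
  # sample genes of very different lengths from one fixed codon usage and
  # compare mean MILC: the length correction keeps them aligned
  fams <- list(c("AAA", "AAG"), c("TTT", "TTC"), c("GGT", "GGC", "GGA", "GGG"),
               c("CTT", "CTC", "CTA", "CTG", "TTA", "TTG"))
  freqs <- unlist(lapply(fams, function(cs)
    setNames(rep(1 / length(cs), length(cs)), cs)))
  draw_gene <- function(n_codons) {
    cods <- unlist(lapply(fams, function(cs)
      sample(cs, n_codons / 4, replace = TRUE)))
    table(cods)
  }
  set.seed(71)
  m300 <- replicate(150, milc(draw_gene(300), freqs))
  m3000 <- replicate(150, milc(draw_gene(3000), freqs))
  expect_lt(abs(mean(m300) - mean(m3000)), 0.05)
})

test_that("CUB profiles demand 10 ribosomal genes and track generator bias", {
  cfg <- benchmark_config(n_species = 10, seed = 9)
  g <- simulate_genome(1, cfg, seed = 91, genome_id = "ok")
  prof <- cub_profile(g)
  expect_equal(prof$n_ribosomal, cfg$ribosomal_per_genome)
  expect_equal(prof$cub_he, median(prof$milc_ribosomal))
  # background frequencies normalize within every synonymous family
  fam <- split(names(prof$background_freqs),
               Biostrings::GENETIC_CODE[names(prof$background_freqs)])
  sums <- vapply(fam, function(cs) sum(prof$background_freqs[cs]), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))

  g9 <- g
  g9$ribosomal[1:(sum(g$ribosomal) - 9)] <- FALSE
  expect_error(cub_profile(g9), class = "phygrow_quality_error")

  suppressWarnings(cfg9 <- benchmark_config(n_species = 10,
                                            ribosomal_per_genome = 9, seed = 9))
  g_neg <- simulate_genome(1, cfg9, seed = 92)
  expect_error(cub_profile(g_neg), class = "phygrow_quality_error")

  # a genome whose "ribosomal" genes carry no differential bias sits near
  # the no-bias baseline; a biased genome sits clearly above it
  slow <- cub_profile(simulate_genome(100, cfg, seed = 93, genome_id = "slow"))
  fast <- cub_profile(simulate_genome(0.2, cfg, seed = 94, genome_id = "fast"))
  expect_gt(fast$cub_he, slow$cub_he)
})

test_that("cub_he increases monotonically with generator bias strength", {
  cfg <- benchmark_config(n_species = 10, seed = 10, cub_noise_sd = 0)
  d_levels <- exp(seq(log(100), log(0.2), length.out = 20))  # bias ascending
  cub <- vapply(seq_along(d_levels), function(i)
    cub_profile(simulate_genome(d_levels[i], cfg, seed = 500 + i))$cub_he,
    numeric(1))
  rho <- cor(seq_along(d_levels), cub, method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("the CUB regression recovers a noise-free linear relation", {
  mk_prof <- function(id, cub) structure(
    list(genome_id = id, n_ribosomal = 12, milc_ribosomal = rep(cub, 12),
         cub_he = cub, background_freqs = NULL, metagenome_mode = FALSE),
    class = "cub_profile")
  cubs <- seq(0.05, 0.6, length.out = 30)
  profs <- lapply(seq_along(cubs), function(i) mk_prof(paste0("g", i), cubs[i]))
  names(profs) <- paste0("g", seq_along(cubs))
  traits <- data.frame(species = names(profs),
                       doubling_h = exp(2 - 3 * cubs))
  fit <- fit_cub_model(profs, traits)
  expect_equal(unname(fit$coefficients[1]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["cub_he"]), -3, tolerance = 1e-6)
  # round trip: every training label reproduced
  preds <- vapply(profs, function(p) predict_cub(fit, p), numeric(1))
  expect_equal(unname(preds), traits$doubling_h, tolerance = 1e-3)

  expect_error(fit_cub_model(profs[1:5], traits), class = "phygrow_fit_error")
  const <- lapply(names(profs), function(id) mk_prof(id, 0.3))
  names(const) <- names(profs)
  expect_error(fit_cub_model(const, traits), class = "phygrow_fit_error")
})

test_that("the OGT covariate is recovered and required at prediction time", {
  set.seed(81)
  n <- 200
  cubs <- runif(n, 0.05, 0.6)
  ogt <- runif(n, 10, 80)
  ln_d <- 2 - 3 * cubs - 0.02 * ogt + rnorm(n, 0, 0.1)
  profs <- lapply(seq_len(n), function(i) structure(
    list(genome_id = paste0("g", i), n_ribosomal = 12,
         milc_ribosomal = rep(cubs[i], 12), cub_he = cubs[i],
         background_freqs = NULL, metagenome_mode = FALSE),
    class = "cub_profile"))
  names(profs) <- paste0("g", seq_len(n))
  traits <- data.frame(species = names(profs), doubling_h = exp(ln_d),
                       ogt = ogt)
  fit <- fit_cub_model(profs, traits, use_ogt = TRUE)
  expect_lt(abs(fit$coefficients[["ogt"]] - (-0.02)), 2 * fit$se[["ogt"]])
  expect_error(predict_cub(fit, profs[[1]]), class = "phygrow_domain_error")
  expect_gt(predict_cub(fit, profs[[1]], ogt = 37), 0)
})

test_that("an intercept-only model predicts its constant for any profile", {
  m <- structure(list(coefficients = c("(Intercept)" = log(4), cub_he = 0),
                      use_ogt = FALSE, n = 10, sigma2 = 0.1),
                 class = "cub_model")
  p <- cub_profile(simulate_genome(2, benchmark_config(n_species = 5, seed = 1),
                                   seed = 7))
  expect_equal(predict_cub(m, p), 4)
})

test_that("CUB models serialize to text and back", {
  m <- structure(list(coefficients = c("(Intercept)" = 1.234567891234,
                                       cub_he = -5.4321, ogt = -0.0213),
                      use_ogt = TRUE, n = 42, sigma2 = 0.3141),
                 class = "cub_model")
  tf <- withr::local_tempfile()
  write_cub_model(m, tf)
  m2 <- read_cub_model(tf)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$use_ogt, TRUE)
  expect_equal(m2$n, 42L)
})
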