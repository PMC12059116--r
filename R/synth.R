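# Synthetic-data generator: Yule trees, traits with tunable phylogenetic
# signal, and codon-biased genomes whose ribosomal codon bias strengthens
# with maximum growth rate. Every operation is deterministic under its seed,
# so benchmark bundles are reproducible byte for byte.

#' Benchmark configuration
#'
#' Collects the knobs of the synthetic benchmark. Defaults emulate the
#' study conditions the pipeline targets: ultrametric species trees, ln
#' doubling times with moderate-to-strong phylogenetic signal spanning
#' roughly 0.2-100 h, and genomes whose ribosomal-protein codon bias
#' increases with growth rate.
#'
#' @param n_species Number of tips (default 120).
#' @param birth_rate Yule birth rate (default 1).
#' @param bm_sigma2 Brownian-motion variance of ln doubling time per unit
#'   tree depth (default 0.5).
#' @param lambda_true Pagel's lambda of the simulated traits in \[0, 1\]
#'   (default 1: pure BM).
#' @param base_doubling_hours Root state (default 4.5 h, the geometric
#'   midpoint of 0.2-100 h).
#' @param cub_noise_sd SD of the lognormal noise decoupling a genome's
#'   codon bias from its true doubling time (default 0.3).
#' @param genes_per_genome Background (non-ribosomal) genes (default 30).
#' @param ribosomal_per_genome Ribosomal genes (default 14; values below 10
#'   warn, since such genomes fail the CUB quality filter and serve only as
#'   negative controls).
#' @param gene_length_codons Codons per gene including start and stop
#'   (default 120).
#' @param bias_floor,bias_ceiling Range of the preferred-codon bias
#'   probability in \[0, 1\] (defaults 0.05 and 0.8).
#' @param d_min_hours,d_max_hours Doubling-time range the bias gradient is
#'   anchored to (defaults 0.2 and 100 h).
#' @param seed Integer seed (default 1).
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_species = 120, birth_rate = 1,
                             bm_sigma2 = 0.5, lambda_true = 1,
                             base_doubling_hours = 4.5,
                             cub_noise_sd = 0.3,
                             genes_per_genome = 30,
                             ribosomal_per_genome = 14,
                             gene_length_codons = 120,
                             bias_floor = 0.05, bias_ceiling = 0.8,
                             d_min_hours = 0.2, d_max_hours = 100,
                             seed = 1) {
  cfg <- as.list(environment())
  if (cfg$ribosomal_per_genome < 10)
    warning("ribosomal_per_genome < 10: genomes will fail the CUB quality filter",
            call. = FALSE)
  if (cfg$bias_floor < 0 || cfg$bias_ceiling > 1 ||
      cfg$bias_floor > cfg$bias_ceiling)
    stop_domain("need 0 <= bias_floor <= bias_ceiling <= 1")
  if (cfg$lambda_true < 0 || cfg$lambda_true > 1)
    stop_domain("lambda_true must lie in [0, 1]")
  if (cfg$bm_sigma2 < 0) stop_domain("bm_sigma2 must be non-negative")
  if (cfg$n_species < 2) stop_domain("n_species must be >= 2")
  class(cfg) <- "benchmark_config"
  cfg
}

#' Simulate an ultrametric Yule tree
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Pure-birth rate (default 1).
#' @param seed Integer seed.
#' @return A `phylo` object with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop_domain("n_species must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate doubling times with tunable phylogenetic signal
#'
#' ln doubling time is drawn from a multivariate normal with mean
#' `ln(base_doubling_hours)` and covariance `bm_sigma2 * C(lambda)`, where
#' C is the BM tip covariance of the tree and `C(lambda)` scales its
#' off-diagonal by `lambda_true`. `lambda_true = 1` gives pure Brownian
#' motion; 0 gives independent tips.
#'
#' @param tree A `phylo` object.
#' @param bm_sigma2 BM variance per unit depth (>= 0).
#' @param lambda_true Signal strength in \[0, 1\].
#' @param base_doubling_hours Root state in hours.
#' @param seed Integer seed.
#' @return Data frame with columns `species`, `doubling_h`.
#' @export
simulate_traits <- function(tree, bm_sigma2, lambda_true = 1,
                            base_doubling_hours = 4.5, seed = NULL) {
  validate_phylogeny(tree)
  if (bm_sigma2 < 0) stop_domain("bm_sigma2 must be non-negative")
  if (lambda_true < 0 || lambda_true > 1)
    stop_domain("lambda_true must lie in [0, 1]")
  n <- ape::Ntip(tree)
  if (bm_sigma2 == 0) {
    return(data.frame(species = tree$tip.label,
                      doubling_h = rep(base_doubling_hours, n)))
  }
  C <- ape::vcv(tree) * lambda_true
  diag(C) <- diag(ape::vcv(tree))
  ch <- chol(bm_sigma2 * C + diag(1e-12, n))
  z <- with_seed(seed, rnorm(n))
  ln_d <- log(base_doubling_hours) + drop(crossprod(ch, z))
  data.frame(species = colnames(C), doubling_h = exp(ln_d))
}

# Preferred codon per synonymous family: alphabetically first (arbitrary
# but deterministic and configurable upstream).
preferred_codons <- function() {
  vapply(codon_families(), function(cs) sort(cs)[1], character(1))
}

# Bias probability for a genome: linear in ln doubling time between the
# anchor range, clipped to [bias_floor, bias_ceiling]; fast growers
# (small d) get the strongest ribosomal codon bias.
bias_for_doubling <- function(doubling_hours, config) {
  span <- log(config$d_max_hours) - log(config$d_min_hours)
  slope <- (config$bias_ceiling - config$bias_floor) / span
  b <- config$bias_floor + slope * (log(config$d_max_hours) - log(doubling_hours))
  min(max(b, config$bias_floor), config$bias_ceiling)
}

# One gene: ATG + (L - 2) sense codons + TAA. Ribosomal genes pick each
# family's preferred codon with probability `bias`, otherwise uniform
# within the family; background genes are uniform within families.
random_gene <- function(n_codons, bias = 0) {
  fams <- codon_families()
  pref <- preferred_codons()
  aas <- names(fams)  # degenerate-family amino acids only
  L <- n_codons - 2L
  aa_seq <- sample(aas, L, replace = TRUE)
  codons <- character(L)
  for (a in unique(aa_seq)) {
    idx <- which(aa_seq == a)
    cs <- fams[[a]]
    pick <- sample(cs, length(idx), replace = TRUE)
    if (bias > 0) {
      hit <- runif(length(idx)) < bias
      pick[hit] <- pref[[a]]
    }
    codons[idx] <- pick
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Simulate a codon-biased genome
#'
#' Generates a `genome_record` whose background genes use synonymous codons
#' uniformly and whose ribosomal genes prefer one designated codon per
#' family with probability increasing as doubling time decreases, so faster
#' growers show stronger ribosomal codon usage bias.
#'
#' @param doubling_hours True doubling time driving the bias (> 0).
#' @param config A `benchmark_config`.
#' @param seed Integer seed.
#' @param genome_id Identifier (default "genome").
#' @return A `genome_record` (see [load_genome()]).
#' @export
simulate_genome <- function(doubling_hours, config = benchmark_config(),
                            seed = NULL, genome_id = "genome") {
  if (doubling_hours <= 0) stop_domain("doubling_hours must be positive")
  b <- bias_for_doubling(doubling_hours, config)
  with_seed(seed, {
    n_bg <- config$genes_per_genome
    n_rb <- config$ribosomal_per_genome
    L <- config$gene_length_codons
    genes <- c(
      vapply(seq_len(n_rb), function(i) random_gene(L, bias = b), character(1)),
      vapply(seq_len(n_bg), function(i) random_gene(L, bias = 0), character(1))
    )
    nm <- c(sprintf("%s_r%02d 50S ribosomal protein L%d", genome_id,
                    seq_len(n_rb), seq_len(n_rb)),
            sprintf("%s_g%03d hypothetical protein", genome_id, seq_len(n_bg)))
    cds <- Biostrings::DNAStringSet(genes)
    names(cds) <- nm
    structure(list(genome_id = genome_id, cds = cds,
                   ribosomal = c(rep(TRUE, n_rb), rep(FALSE, n_bg)),
                   ogt = NULL, psi = NULL, n_dropped = 0L),
              class = "genome_record")
  })
}

#' Write a genome record as FASTA
#'
#' @param genome A `genome_record`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$cds, path)
  invisible(path)
}

#' Build a complete synthetic benchmark bundle
#'
#' Simulates a tree, traits and one genome per species under a single
#' configuration, optionally writing the bundle to disk (`tree.nwk`,
#' `traits.tsv`, `genomes/<species>.fna`, `manifest.json`). Genomes are
#' generated from a noisy copy of the trait (lognormal, `cub_noise_sd`), so
#' the CUB signal is informative but imperfect.
#'
#' @param config A `benchmark_config`.
#' @param dir Output directory; NULL (default) keeps the bundle in memory.
#' @return A list: `config`, `tree`, `traits` (with the genome-generation
#'   doubling time in `doubling_h_genome`), `genomes` (named list of
#'   `genome_record`s), and `dir` when written.
#' @export
make_benchmark <- function(config = benchmark_config(), dir = NULL) {
  tree <- simulate_tree(config$n_species, config$birth_rate, seed = config$seed)
  traits <- simulate_traits(tree, config$bm_sigma2, config$lambda_true,
                            config$base_doubling_hours,
                            seed = config$seed + 1)
  noise <- with_seed(config$seed + 2,
                     rnorm(nrow(traits), 0, config$cub_noise_sd))
  traits$doubling_h_genome <- traits$doubling_h * exp(noise)
  genomes <- lapply(seq_len(nrow(traits)), function(i)
    simulate_genome(traits$doubling_h_genome[i], config,
                    seed = config$seed + 10L + i,
                    genome_id = traits$species[i]))
  names(genomes) <- traits$species

  if (!is.null(dir)) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
    if (!ok || file.access(dir, 2) != 0)
      stop_io(sprintf("cannot write to %s", dir))
    write_newick(tree, file.path(dir, "tree.nwk"))
    write.table(traits, file.path(dir, "traits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    gdir <- file.path(dir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    for (sp in names(genomes))
      write_genome_fasta(genomes[[sp]], file.path(gdir, paste0(sp, ".fna")))
    manifest <- c(list(package = "phygrow",
                       version = as.character(packageVersion("phygrow"))),
                  unclass(config))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(config = config, tree = tree, traits = traits, genomes = genomes,
       dir = dir)
}

#' Named benchmark regimes
#'
#' Three preset configurations spanning the qualitative regimes the gated
#' ensemble must handle:
#'
#' * `"cub_dominant"`: no phylogenetic signal (`lambda_true = 0`),
#'   noise-free genomes with long genes and a large clean background gene
#'   pool, and the codon-bias range anchored to a narrow doubling-time
#'   window. The codon-usage regression is sharp while relatives are
#'   uninformative, so the CUB predictor wins at every cutting depth.
#' * `"phylo_dominant"`: pure Brownian-motion trait with large variance and
#'   severely noisy genomes (`cub_noise_sd = 4`): the phylogenetic
#'   predictor wins once clades are cut finely enough.
#' * `"mixed"`: heritable trait, moderate genome noise and a denser tree:
#'   the two error curves cross within the default sweep, the regime the
#'   gated ensemble is designed for.
#'
#' @param regime One of `"cub_dominant"`, `"phylo_dominant"`, `"mixed"`.
#' @param seed Integer seed stored in the configuration.
#' @return A `benchmark_config`.
#' @export
regime_config <- function(regime = c("mixed", "cub_dominant", "phylo_dominant"),
                          seed = 1) {
  switch(match.arg(regime),
    cub_dominant = benchmark_config(
      n_species = 60, lambda_true = 0, bm_sigma2 = 0.25, cub_noise_sd = 0,
      gene_length_codons = 600, ribosomal_per_genome = 20,
      genes_per_genome = 120, bias_floor = 0.3, bias_ceiling = 0.9,
      d_min_hours = 0.5, d_max_hours = 40, seed = seed),
    phylo_dominant = benchmark_config(
      n_species = 100, lambda_true = 1, bm_sigma2 = 2, cub_noise_sd = 4,
      seed = seed),
    mixed = benchmark_config(
      n_species = 120, birth_rate = 2.5, lambda_true = 1, bm_sigma2 = 0.45,
      cub_noise_sd = 1.1, gene_length_codons = 450,
      ribosomal_per_genome = 20, genes_per_genome = 80, bias_floor = 0.3,
      bias_ceiling = 0.9, d_min_hours = 0.5, d_max_hours = 40, seed = seed))
}
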