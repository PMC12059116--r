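# Codon-usage-bias growth prediction: MILC of ribosomal proteins against the
# genome-wide codon background, and an OLS regression of ln doubling time on
# that summary (optionally with optimal growth temperature as a covariate).

# Synonymous-family tables under the standard genetic code: families with
# >= 2 codons, stops excluded (so Met and Trp drop out).
codon_families <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      aa <- gc[gc != "*"]
      fam <- split(names(aa), unname(aa))
      tab <<- fam[vapply(fam, length, integer(1)) >= 2L]
    }
    tab
  }
})

# codon -> family name lookup (degenerate families only)
codon_family_of <- function() {
  fam <- codon_families()
  setNames(rep(names(fam), lengths(fam)), unlist(fam))
}

#' Load a genome's coding sequences
#'
#' Reads a nucleotide CDS FASTA, drops sequences whose length is not a
#' multiple of 3, that contain ambiguity codes, or that contain a premature
#' stop codon, and flags ribosomal proteins by a case-insensitive pattern
#' match on the annotation (FASTA description lines by default, or a
#' supplied product table).
#'
#' @param cds_fasta Path to a nucleotide FASTA of coding sequences.
#' @param annotations Optional: a data frame with columns `id` and `product`
#'   (ids matching the first token of the FASTA headers), or a path to a
#'   GFF3 file whose CDS features carry `ID`/`locus_tag` and `product`
#'   attributes.
#' @param genome_id Identifier; defaults to the FASTA file name.
#' @param ribosomal_pattern Regex matched (case-insensitively) against
#'   products to flag ribosomal proteins. Default `"ribosomal protein"`.
#' @param ogt Optional optimal growth temperature (degrees C).
#' @param psi Optional contamination score in \[0, 1\].
#' @return A `genome_record` list: `genome_id`, `cds` (a `DNAStringSet`),
#'   `ribosomal` (logical per CDS), `ogt`, `psi`, `n_dropped`.
#' @export
load_genome <- function(cds_fasta, annotations = NULL, genome_id = NULL,
                        ribosomal_pattern = "ribosomal protein",
                        ogt = NULL, psi = NULL) {
  if (!file.exists(cds_fasta)) stop_io(sprintf("FASTA not found: %s", cds_fasta))
  seqs <- tryCatch(Biostrings::readDNAStringSet(cds_fasta),
                   error = function(e) stop_format(conditionMessage(e)))
  if (length(seqs) == 0) stop_format("no CDS parsed from FASTA")
  if (!is.null(psi) && (psi < 0 || psi > 1))
    stop_validation("psi must lie in [0, 1]")

  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  products <- sub("^\\S+\\s*", "", headers)
  if (!is.null(annotations)) {
    ann <- if (is.character(annotations)) read_gff3_products(annotations)
           else annotations
    if (!all(c("id", "product") %in% names(ann)))
      stop_validation("annotations need columns 'id' and 'product'")
    m <- match(ids, ann$id)
    products <- ifelse(is.na(m), products, ann$product[m])
  }
  ribosomal <- grepl(ribosomal_pattern, products, ignore.case = TRUE)

  w <- Biostrings::width(seqs)
  ok_len <- w %% 3L == 0L & w >= 3L
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  ok_alpha <- af[, "other"] == 0
  ok <- ok_len & ok_alpha
  # premature (internal) stop check on the survivors
  if (any(ok)) {
    aa <- suppressWarnings(Biostrings::translate(
      seqs[ok], if.fuzzy.codon = "X"))
    internal_stop <- vapply(seq_along(aa), function(i) {
      s <- as.character(aa[[i]])
      n <- nchar(s)
      n > 1 && grepl("\\*", substr(s, 1, n - 1))
    }, logical(1))
    ok[ok] <- !internal_stop
  }
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(sprintf("%s: dropped %d CDS (length/ambiguity/premature stop)",
                    cds_fasta, n_drop))
  if (!any(ok)) stop_format("no CDS passed filtering")

  structure(list(
    genome_id = genome_id %||% sub("\\.(fna|fa|fasta)$", "", basename(cds_fasta)),
    cds = seqs[ok], ribosomal = ribosomal[ok],
    ogt = ogt, psi = psi, n_dropped = n_drop
  ), class = "genome_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal GFF3 reader for CDS product attributes.
read_gff3_products <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("GFF3 not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[vapply(fields, length, integer(1)) == 9L]
  fields <- fields[vapply(fields, function(f) f[3] == "CDS", logical(1))]
  if (!length(fields)) stop_format("no CDS features in GFF3")
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  attrs <- vapply(fields, `[`, character(1), 9)
  id <- attr_get(attrs, "ID")
  lt <- attr_get(attrs, "locus_tag")
  id <- ifelse(is.na(id), lt, id)
  data.frame(id = id, product = attr_get(attrs, "product"),
             stringsAsFactors = FALSE)
}

# Per-gene codon counts (genes x 64 matrix).
codon_count_matrix <- function(cds) {
  Biostrings::trinucleotideFrequency(cds, step = 3)
}

#' MILC of one gene against a reference codon usage
#'
#' Measure Independent of Length and Composition: for each synonymous
#' family a, `M_a = 2 * sum_c o_c * ln(f_c / g_c)` with `o_c` the codon
#' count, `f_c` the observed within-family frequency and `g_c` the reference
#' within-family frequency; MILC = `sum_a M_a / L - C` with L the number of
#' codons in degenerate families and the length-correction
#' `C = sum_a (r_a - 1) / L` over families present (`r_a` = family size).
#' Single-codon families (Met, Trp) and stop codons are excluded.
#'
#' @param gene_codon_counts Named codon counts (names are codons, e.g. from
#'   [codon_count_matrix()] rows).
#' @param reference_freqs Named within-family codon frequencies, strictly
#'   positive for every observed codon (see [cub_profile()], which builds
#'   them with a pseudocount).
#' @return A scalar MILC value.
#' @export
milc <- function(gene_codon_counts, reference_freqs) {
  fam_of <- codon_family_of()
  fams <- codon_families()
  cod <- intersect(names(gene_codon_counts), names(fam_of))
  o <- gene_codon_counts[cod]
  o <- o[o > 0]
  if (!length(o)) stop_domain("gene has no codons in degenerate families")
  L <- sum(o)
  present <- unique(fam_of[names(o)])
  Msum <- 0
  for (a in present) {
    codons_a <- fams[[a]]
    oa <- o[intersect(names(o), codons_a)]
    tot <- sum(oa)
    f <- oa / tot
    g <- reference_freqs[names(oa)]
    if (anyNA(g) || any(g <= 0))
      stop_domain("observed codon with zero/missing reference frequency; build the reference with a pseudocount")
    Msum <- Msum + 2 * sum(oa * log(f / g))
  }
  Ccorr <- sum(vapply(present, function(a) length(fams[[a]]) - 1L, integer(1))) / L
  unname(Msum / L - Ccorr)
}

#' Codon-usage-bias profile of a genome
#'
#' Computes per-ribosomal-gene MILC values against the genome-wide codon
#' background (pooled counts of all retained CDS plus a 0.5 pseudocount per
#' codon, normalized within each synonymous family) and summarizes them as
#' their median (`cub_he`, the codon-usage bias of the highly expressed gene
#' set). Genomes with fewer than 10 ribosomal proteins fail the quality
#' filter and raise a `phygrow_quality_error`. In metagenome mode
#' (contaminated assemblies, psi above threshold) the background is the
#' within-family uniform usage rather than the possibly mixed genome-wide
#' pool.
#'
#' @param genome A `genome_record` from [load_genome()] or
#'   [simulate_genome()].
#' @param min_ribosomal Quality filter: minimum ribosomal genes (default 10).
#' @param pseudocount Added to every codon when estimating background
#'   frequencies (default 0.5).
#' @param metagenome_mode Use a family-uniform background (default FALSE).
#' @return A `cub_profile` list: `genome_id`, `n_ribosomal`,
#'   `milc_ribosomal`, `cub_he`, `background_freqs`, `metagenome_mode`.
#' @export
cub_profile <- function(genome, min_ribosomal = 10, pseudocount = 0.5,
                        metagenome_mode = FALSE) {
  if (!inherits(genome, "genome_record")) stop_validation("not a genome_record")
  n_ribo <- sum(genome$ribosomal)
  if (n_ribo < min_ribosomal)
    stop_quality(sprintf(
      "genome %s has %d annotated ribosomal proteins (< %d): fails the CUB quality filter",
      genome$genome_id, n_ribo, min_ribosomal))
  counts <- codon_count_matrix(genome$cds)
  fam_of <- codon_family_of()
  fams <- codon_families()

  if (metagenome_mode) {
    g <- unlist(lapply(fams, function(cs) setNames(rep(1 / length(cs),
                                                       length(cs)), cs)))
    names(g) <- unlist(fams)
  } else {
    pooled <- colSums(counts)[names(fam_of)] + pseudocount
    g <- pooled
    for (a in names(fams)) {
      cs <- fams[[a]]
      g[cs] <- g[cs] / sum(g[cs])
    }
  }

  ribo_idx <- which(genome$ribosomal)
  milc_r <- vapply(ribo_idx, function(i) milc(counts[i, ], g), numeric(1))
  names(milc_r) <- names(genome$cds)[ribo_idx]
  structure(list(genome_id = genome$genome_id, n_ribosomal = n_ribo,
                 milc_ribosomal = milc_r, cub_he = median(milc_r),
                 background_freqs = g, metagenome_mode = metagenome_mode),
            class = "cub_profile")
}

#' @export
print.cub_profile <- function(x, ...) {
  cat(sprintf("CUB profile %s: %d ribosomal genes, cub_he = %.4g%s\n",
              x$genome_id, x$n_ribosomal, x$cub_he,
              if (x$metagenome_mode) " (metagenome mode)" else ""))
  invisible(x)
}

#' Fit the codon-usage growth regression
#'
#' Ordinary least squares of ln doubling time on the ribosomal codon-usage
#' summary `cub_he`, optionally with optimal growth temperature as a second
#' covariate. This is the trainable CUB component of the hybrid predictor;
#' it is re-fit on each training set (e.g. per cross-validation fold).
#'
#' @param profiles List of `cub_profile` objects.
#' @param traits Trait table (data frame with `species`, `doubling_h`,
#'   optional `ogt`) or a named doubling-time vector.
#' @param use_ogt Include OGT as a covariate; genomes lacking it are dropped
#'   with a warning.
#' @param min_n Minimum training genomes (default 10).
#' @return A `cub_model` list with `coefficients`, `use_ogt`, `n`, `sigma2`.
#' @export
fit_cub_model <- function(profiles, traits, use_ogt = FALSE, min_n = 10) {
  if (inherits(profiles, "cub_profile")) profiles <- list(profiles)
  ids <- vapply(profiles, `[[`, character(1), "genome_id")
  cub <- vapply(profiles, `[[`, numeric(1), "cub_he")
  y <- as_trait_vector(traits)
  ogt <- NULL
  if (use_ogt) {
    if (!is.data.frame(traits) || !"ogt" %in% names(traits))
      stop_validation("use_ogt = TRUE needs an 'ogt' column in the trait table")
    ogt <- setNames(as.numeric(traits$ogt), as.character(traits$species))
  }
  keep <- ids %in% names(y)
  df <- data.frame(ln_d = log(y[ids[keep]]), cub_he = cub[keep])
  if (use_ogt) {
    df$ogt <- ogt[ids[keep]]
    miss <- is.na(df$ogt)
    if (any(miss)) {
      warning(sprintf("dropping %d genomes without OGT", sum(miss)),
              call. = FALSE)
      df <- df[!miss, ]
    }
  }
  if (nrow(df) < min_n)
    stop_fit(sprintf("only %d training genomes with traits (need >= %d)",
                     nrow(df), min_n))
  if (sd(df$cub_he) == 0) stop_fit("cub_he is constant: rank-deficient design")
  fml <- if (use_ogt) ln_d ~ cub_he + ogt else ln_d ~ cub_he
  fit <- lm(fml, data = df)
  structure(list(coefficients = coef(fit), use_ogt = use_ogt,
                 n = nrow(df), sigma2 = sum(fit$residuals^2) / fit$df.residual,
                 # noise-free designs make summary() warn about a perfect fit
                 se = sqrt(diag(suppressWarnings(vcov(fit))))),
            class = "cub_model")
}

#' @importFrom stats vcov
#' @export
print.cub_model <- function(x, ...) {
  cat(sprintf("CUB growth model (n = %d%s): ln(d) = %.4g %+.4g * cub_he",
              x$n, if (x$use_ogt) ", with OGT" else "",
              x$coefficients[1], x$coefficients["cub_he"]))
  if (x$use_ogt) cat(sprintf(" %+.4g * OGT", x$coefficients["ogt"]))
  cat("\n")
  invisible(x)
}

#' Predict doubling time from a CUB profile
#'
#' @param model A `cub_model`.
#' @param profile A `cub_profile`.
#' @param ogt Optimal growth temperature; required when the model was fit
#'   with `use_ogt = TRUE`.
#' @return Doubling time in hours (strictly positive).
#' @export
predict_cub <- function(model, profile, ogt = NULL) {
  if (!inherits(model, "cub_model")) stop_validation("not a cub_model")
  if (!inherits(profile, "cub_profile")) stop_validation("not a cub_profile")
  b <- model$coefficients
  eta <- b[1] + b["cub_he"] * profile$cub_he
  if (model$use_ogt) {
    if (is.null(ogt) || is.na(ogt))
      stop_domain("model uses OGT but none supplied for this genome")
    eta <- eta + b["ogt"] * ogt
  }
  unname(exp(eta))
}

#' Serialize a CUB model to a plain-text key/value file
#'
#' @param model A `cub_model`.
#' @param path Output path.
#' @export
write_cub_model <- function(model, path) {
  lines <- c(
    sprintf("format=phygrow_cub_model/1"),
    sprintf("version=%s", as.character(packageVersion("phygrow"))),
    sprintf("use_ogt=%s", model$use_ogt),
    sprintf("n=%d", model$n),
    sprintf("sigma2=%.17g", model$sigma2),
    sprintf("coef.%s=%.17g", names(model$coefficients), model$coefficients)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized CUB model
#'
#' @param path Path written by [write_cub_model()].
#' @return A `cub_model`.
#' @export
read_cub_model <- function(path) {
  kv <- read_kv(path, "phygrow_cub_model/1")
  cf <- kv[startsWith(names(kv), "coef.")]
  structure(list(
    coefficients = setNames(as.numeric(cf), sub("^coef\\.", "", names(cf))),
    use_ogt = as.logical(kv[["use_ogt"]]),
    n = as.integer(kv[["n"]]), sigma2 = as.numeric(kv[["sigma2"]])),
    class = "cub_model")
}

read_kv <- function(path, expect_format) {
  if (!file.exists(path)) stop_io(sprintf("model file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  kv <- setNames(vapply(parts, `[`, character(1), 2),
                 vapply(parts, `[`, character(1), 1))
  if (!identical(unname(kv[["format"]]), expect_format))
    stop_format(sprintf("%s is not a %s file", path, expect_format))
  kv
}
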