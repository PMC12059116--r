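#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm logLik median optimize plogis pchisq predict
#'   quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table packageVersion
NULL

# Run code under a fixed RNG state without disturbing the caller's stream.
# seed = NULL means "use the current stream" (still advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_domain("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Named-vector trait coercion: accepts a named numeric vector or a data frame
# with columns (species, doubling_h) or (species, trait).
as_trait_vector <- function(traits) {
  if (is.data.frame(traits)) {
    sp_col <- intersect(c("species", "tip", "id"), names(traits))[1]
    val_col <- intersect(c("doubling_h", "trait", "value"), names(traits))[1]
    if (is.na(sp_col) || is.na(val_col))
      stop_validation("trait data frame needs a species column and a doubling_h/trait column")
    out <- setNames(as.numeric(traits[[val_col]]), as.character(traits[[sp_col]]))
  } else if (is.numeric(traits) && !is.null(names(traits))) {
    out <- traits
  } else {
    stop_validation("traits must be a named numeric vector or a data frame")
  }
  if (anyDuplicated(names(out)))
    stop_validation("duplicate species in trait table")
  out[!is.na(out)]
}

#' Read a trait table
#'
#' Reads a tab-separated trait table with columns `species`, `doubling_h`
#' (doubling time in hours) and optional `ogt` (optimal growth temperature,
#' degrees C) and `psi` (contamination score in \[0, 1\]).
#'
#' @param path Path to a TSV file.
#' @return A data frame with at least columns `species` and `doubling_h`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("trait table not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("species", "doubling_h") %in% names(df)))
    stop_format("trait table must have columns 'species' and 'doubling_h'")
  if (any(df$doubling_h <= 0, na.rm = TRUE))
    stop_validation("doubling times must be strictly positive")
  df
}
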