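#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; summary percentages here use
#' conventional half-up rounding so that printed count pairs reproduce their
#' printed percentages exactly.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Orthologue-coverage percentage
#'
#' The percentage rule used by the per-mechanism summary stage:
#' \code{100 * n_with_orth / n}, rounded half-up to one decimal place.
#' With \code{n = 0} the percentage is defined as 0.
#'
#' @param n_with_orth count of annotated genes having at least one orthologue.
#' @param n total count of annotated genes.
#' @return numeric percentage on the 0-100 scale with one decimal.
#' @export
#' @examples
#' orth_percentage(259, 507) # 51.1
orth_percentage <- function(n_with_orth, n) {
  stopifnot(length(n_with_orth) == length(n))
  if (any(n_with_orth > n)) {
    stop("n_with_orth exceeds n: inconsistent inputs")
  }
  ifelse(n == 0, 0, round_half_up(100 * n_with_orth / n, 1))
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-stream child seed from a corpus seed; kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) %% 1009L
}

# Tab-separated writer with the conventions used for all pipeline outputs:
# header, no quoting, no row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

trim <- function(x) gsub("^\\s+|\\s+$", "", x)
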