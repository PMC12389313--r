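#' Normalize a drug name
#'
#' Standardizes free-text drug names so that the mining, risk-lookup and
#' recommendation stages all speak the same vocabulary: lowercase
#' conversion, elimination of bracketed content (round, square or curly,
#' including the brackets; nested brackets are removed outside-in), removal
#' of every character outside lowercase letters, digits, space and hyphen,
#' collapsing of repeated whitespace, and trimming.
#'
#' The operation is idempotent: normalizing an already-normalized name is
#' the identity.
#'
#' @param raw character vector of raw drug names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name("Hydroxychloroquine (Plaquenil)")
#' normalize_drug_name("Valproic Acid*")
normalize_drug_name <- function(raw) {
  if (length(raw) == 0L) stop("no drug name supplied")
  if (!is.character(raw)) raw <- as.character(raw)
  if (anyNA(raw) || any(!nzchar(trimws(raw)))) {
    stop("empty drug name cannot be normalized")
  }
  x <- tolower(raw)
  ## strip innermost bracketed groups until none remain; equivalent to
  ## removing every outermost group together with anything nested in it
  repeat {
    y <- gsub("\\([^()]*\\)|\\[[^][]*\\]|\\{[^{}]*\\}", "", x, perl = TRUE)
    if (identical(y, x)) break
    x <- y
  }
  x <- gsub("[^a-z0-9 -]", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  if (any(!nzchar(x))) {
    bad <- unique(raw[!nzchar(x)])
    stop("drug name empty after normalization: ",
         paste(sQuote(bad), collapse = ", "))
  }
  x
}
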