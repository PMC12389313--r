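## Readers/writers for the tabular inputs. Canonical dialect: CSV with
## header, UTF-8; `sep = "\t"` accepts the TSV variant. Writers emit the
## same dialect bit-exactly given fixed input order.

read_table_checked <- function(path, required, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fill = FALSE)
  names(df) <- toupper(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read a prescriptions table into admission drug sets
#'
#' Expects columns SUBJECT_ID, HADM_ID, DRUG (header required; extra
#' columns ignored). Drug names are normalized and de-duplicated within
#' each admission; one [admission_drug_set()] is returned per distinct
#' (SUBJECT_ID, HADM_ID), ordered by subject then admission id.
#'
#' @param path path to a delimited file.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return List of `admission_drug_set` objects (empty list for a file
#'   with a header only).
#' @export
read_prescriptions <- function(path, sep = ",") {
  df <- read_table_checked(path, c("SUBJECT_ID", "HADM_ID", "DRUG"), sep)
  if (nrow(df) == 0L) return(list())
  drug <- normalize_drug_name(df$DRUG)
  id <- paste(df$SUBJECT_ID, df$HADM_ID, sep = "\r")
  groups <- split(drug, id)
  groups <- groups[sort_c(names(groups))]
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    parts <- strsplit(names(groups)[i], "\r", fixed = TRUE)[[1L]]
    out[[i]] <- admission_drug_set(parts[1L], parts[2L], groups[[i]],
                                   normalize = FALSE)
  }
  out
}

#' Write admission drug sets as a prescriptions table
#'
#' Inverse of [read_prescriptions()] on the canonical dialect: the
#' round-trip read(write(x)) reproduces x exactly.
#'
#' @param admissions list of `admission_drug_set` objects.
#' @param path output path.
#' @param sep field separator.
#' @export
write_prescriptions <- function(admissions, path, sep = ",") {
  rows <- do.call(rbind, lapply(admissions, function(a) {
    data.frame(SUBJECT_ID = a$subject_id, HADM_ID = a$hadm_id,
               DRUG = a$drugs, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(SUBJECT_ID = character(), HADM_ID = character(),
                       DRUG = character())
  }
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a symmetric drug-pair risk table
#'
#' @param drug_a,drug_b character vectors of drug names (normalized unless
#'   `normalize = FALSE`).
#' @param level character vector of risk levels (case-insensitive;
#'   must be High, Moderate, Low, Unknown or None).
#' @param normalize apply [normalize_drug_name()]? Default `TRUE`.
#' @return Object of class `risk_table`. Lookup via [risk_lookup()] is
#'   symmetric; absent pairs return `"Unknown"`.
#' @export
risk_table <- function(drug_a = character(), drug_b = character(),
                       level = character(), normalize = TRUE) {
  stopifnot(length(drug_a) == length(drug_b),
            length(drug_a) == length(level))
  canon <- risk_levels()
  idx <- match(tolower(level), tolower(canon))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("unrecognized risk level ", sQuote(level[bad]), " in row ", bad,
         " (expected one of ", paste(canon, collapse = ", "), ")")
  }
  if (normalize && length(drug_a) > 0L) {
    drug_a <- normalize_drug_name(drug_a)
    drug_b <- normalize_drug_name(drug_b)
  }
  key <- mapply(function(a, b) paste(sort_c(c(a, b)), collapse = "|"),
                drug_a, drug_b, USE.NAMES = FALSE)
  levels <- canon[idx]
  ## last occurrence wins on duplicate pairs
  tab <- stats::setNames(levels, key)
  tab <- tab[!duplicated(names(tab), fromLast = TRUE)]
  structure(list(levels = tab), class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat("<risk_table> ", length(x$levels), " pair(s)\n", sep = "")
  invisible(x)
}

#' Look up the risk level of a drug pair
#'
#' Symmetric in its two arguments; a pair absent from the table returns
#' `"Unknown"` (the pair cannot be assessed from the available data).
#'
#' @param risks a [risk_table()].
#' @param a,b normalized drug names (vectorized in parallel).
#' @return Character vector of risk levels.
#' @export
risk_lookup <- function(risks, a, b) {
  stopifnot(inherits(risks, "risk_table"), length(a) == length(b))
  if (length(a) == 0L) return(character(0))
  key <- mapply(function(x, y) paste(sort_c(c(x, y)), collapse = "|"),
                a, b, USE.NAMES = FALSE)
  out <- unname(risks$levels[key])
  out[is.na(out)] <- "Unknown"
  out
}

#' Read a drug-pair risk table
#'
#' Expects columns DRUG_A, DRUG_B, LEVEL; LEVEL is case-insensitive and
#' must be one of High, Moderate, Low, Unknown, None. Names are
#' normalized; lookup is symmetric.
#'
#' @inheritParams read_prescriptions
#' @return A [risk_table()].
#' @export
read_risk_table <- function(path, sep = ",") {
  df <- read_table_checked(path, c("DRUG_A", "DRUG_B", "LEVEL"), sep)
  risk_table(df$DRUG_A, df$DRUG_B, df$LEVEL)
}

#' Write a risk table
#'
#' @param risks a [risk_table()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_risk_table <- function(risks, path, sep = ",") {
  pairs <- combo_drugs(names(risks$levels))
  df <- data.frame(DRUG_A = vapply(pairs, `[`, "", 1L),
                   DRUG_B = vapply(pairs, function(p) p[min(2L, length(p))], ""),
                   LEVEL = unname(risks$levels))
  df <- df[order_c(df$DRUG_A, df$DRUG_B), , drop = FALSE]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a drug to target-gene map
#'
#' @param drug character vector of drug names (one row per drug-gene link).
#' @param gene character vector of gene symbols (upper-cased, trimmed).
#' @param normalize apply [normalize_drug_name()] to drugs? Default `TRUE`.
#' @return Object of class `drug_gene_map`: a named list of sorted unique
#'   gene-symbol vectors. Query with [gene_targets()]; unmapped drugs have
#'   an empty gene set.
#' @export
drug_gene_map <- function(drug = character(), gene = character(),
                          normalize = TRUE) {
  stopifnot(length(drug) == length(gene))
  if (length(drug) > 0L && normalize) drug <- normalize_drug_name(drug)
  gene <- toupper(trimws(gene))
  map <- lapply(split(gene, drug), function(g) sort_c(unique(g)))
  map <- map[sort_c(names(map))]
  structure(list(genes = map), class = "drug_gene_map")
}

#' @export
print.drug_gene_map <- function(x, ...) {
  cat("<drug_gene_map> ", length(x$genes), " drug(s), ",
      length(unique(unlist(x$genes))), " gene(s)\n", sep = "")
  invisible(x)
}

#' Target genes of a drug
#'
#' @param map a [drug_gene_map()].
#' @param drug a single normalized drug name.
#' @return Character vector of gene symbols; `character(0)` if unmapped.
#' @export
gene_targets <- function(map, drug) {
  stopifnot(inherits(map, "drug_gene_map"))
  g <- map$genes[[drug]]
  if (is.null(g)) character(0) else g
}

#' Read a drug to target-gene map
#'
#' Expects columns DRUG, GENE; genes are aggregated per normalized drug
#' with set semantics (duplicate rows collapse).
#'
#' @inheritParams read_prescriptions
#' @return A [drug_gene_map()].
#' @export
read_drug_gene_map <- function(path, sep = ",") {
  df <- read_table_checked(path, c("DRUG", "GENE"), sep)
  drug_gene_map(df$DRUG, df$GENE)
}

#' Write a drug-gene map
#'
#' @param map a [drug_gene_map()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_drug_gene_map <- function(map, path, sep = ",") {
  df <- data.frame(
    DRUG = rep(names(map$genes), lengths(map$genes)),
    GENE = unlist(map$genes, use.names = FALSE)
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a docking-mode table
#'
#' Expects columns MODE, AFFINITY, RMSD: one row per ranked docking pose,
#' affinity the binding free energy in kcal/mol (more negative = stronger
#' binding), RMSD in Angstrom relative to the reference conformation.
#' Modes are returned sorted by index; mode 1 (the optimal pose) must be
#' present, mode indices must be unique and RMSD non-negative.
#'
#' @inheritParams read_prescriptions
#' @return `data.frame` of class `docking_modes` with columns
#'   `mode`, `affinity`, `rmsd`.
#' @export
read_docking_modes <- function(path, sep = ",") {
  df <- read_table_checked(path, c("MODE", "AFFINITY", "RMSD"), sep)
  docking_modes(as.integer(df$MODE), as.numeric(df$AFFINITY),
                as.numeric(df$RMSD))
}

#' Construct a docking-mode table
#'
#' @param mode positive integer pose indices (mode 1 = optimal pose).
#' @param affinity binding free energies, kcal/mol.
#' @param rmsd deviations from the reference conformation, Angstrom.
#' @return `data.frame` of class `docking_modes`, sorted by mode index.
#' @export
docking_modes <- function(mode, affinity, rmsd) {
  stopifnot(length(mode) == length(affinity), length(mode) == length(rmsd))
  if (length(mode) < 1L) stop("a docking run needs at least one mode")
  if (anyNA(mode) || any(mode < 1L)) stop("mode indices must be positive")
  if (anyDuplicated(mode)) stop("duplicate mode index in docking run")
  if (anyNA(rmsd) || any(rmsd < 0)) {
    stop("negative RMSD in docking run (RMSD must be >= 0)")
  }
  if (!1L %in% mode) stop("docking run lacks mode 1 (the optimal pose)")
  df <- data.frame(mode = as.integer(mode), affinity = as.numeric(affinity),
                   rmsd = as.numeric(rmsd))
  df <- df[order(df$mode), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("docking_modes", "data.frame")
  df
}

#' Write a docking-mode table
#'
#' @param modes a [docking_modes()] table.
#' @param path output path.
#' @param sep field separator.
#' @export
write_docking_modes <- function(modes, path, sep = ",") {
  df <- data.frame(MODE = modes$mode, AFFINITY = modes$affinity,
                   RMSD = modes$rmsd)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a diagnoses table to subjects with given ICD-9 codes
#'
#' Plumbing helper for cohort assembly: given a DIAGNOSES-style table with
#' columns SUBJECT_ID and ICD9_CODE, returns the subject ids carrying any
#' of the requested codes (default: the systemic lupus erythematosus and
#' antiphospholipid syndrome codes 7100 and 28981). Makes no clinical
#' claim; identifiers are opaque strings.
#'
#' @param path path to a delimited diagnoses file.
#' @param codes ICD-9 codes to keep.
#' @param sep field separator.
#' @return Character vector of subject ids (sorted, unique).
#' @export
filter_subjects_by_icd9 <- function(path, codes = c("7100", "28981"),
                                    sep = ",") {
  df <- read_table_checked(path, c("SUBJECT_ID", "ICD9_CODE"), sep)
  sort_c(unique(df$SUBJECT_ID[trimws(df$ICD9_CODE) %in% codes]))
}
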